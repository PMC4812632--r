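# Independent oracles used to validate the package's algorithms.

# Brute-force cluster oracle: enumerate every contiguous run of family
# member ordinals; keep runs of >= min_genes where every adjacent gap is
# within the threshold and that cannot be extended on either side.
oracle_max_gap_clusters <- function(member_ordinals, gap_threshold,
                                    min_genes = 3) {
  o <- sort(member_ordinals)
  n <- length(o)
  res <- list()
  if (n < min_genes) return(res)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_genes) next
      gaps <- diff(o[i:j]) - 1
      if (length(gaps) && any(gaps > gap_threshold)) next
      left_max <- i == 1 || (o[i] - o[i - 1] - 1) > gap_threshold
      right_max <- j == n || (o[j + 1] - o[j] - 1) > gap_threshold
      if (left_max && right_max) res[[length(res) + 1]] <- o[i:j]
    }
  }
  res
}

# Brute-force maximal-scoring subsequences: repeatedly extract the best
# subsequence and recurse into the flanks. Tie conventions follow the
# defining properties of maximal subsequences: the left cumulative must be
# a strict minimum (rightmost minimizing start), and a zero-sum right
# extension is excluded (earliest maximizing end).
oracle_max_segments <- function(scores, tol = 1e-9) {
  out <- list()
  rec <- function(lo, hi) {
    if (lo > hi) return()
    cs <- cumsum(scores[lo:hi])
    pre <- c(0, cs[-length(cs)])
    m <- cummin(pre)
    gain <- cs - m
    j <- which.max(gain)
    if (gain[j] <= tol) return()
    i <- max(which(pre[seq_len(j)] <= m[j] + tol))
    out[[length(out) + 1]] <<- c(start = lo + i - 2, end = lo + j - 1,
                                 score = gain[j])
    rec(lo, lo + i - 2)
    rec(lo + j, hi)
  }
  rec(1, length(scores))
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(),
                      score = numeric()))
  d <- as.data.frame(do.call(rbind, out))
  d[order(d$start), ]
}

# High-precision Welch oracle: hand-coded statistic and Satterthwaite df,
# p-value by numerical integration of the t density.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  upper <- stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                            rel.tol = 1e-12)$value
  list(t = t_stat, df = df, p = 2 * upper)
}

# Brute-force scan for tandem arrays of a unit anywhere in a sequence.
oracle_tandem_arrays <- function(seq, unit) {
  u <- nchar(unit)
  L <- nchar(seq)
  res <- list()
  i <- 1
  while (i <= L - u + 1) {
    if (substr(seq, i, i + u - 1) == unit) {
      n <- 1
      while (substr(seq, i + n * u, i + (n + 1) * u - 1) == unit) n <- n + 1
      res[[length(res) + 1]] <- c(start = i - 1, n_copies = n)
      i <- i + n * u
    } else i <- i + 1
  }
  res
}

# sequence with an exact AT-base count (composition fixed, order random)
exact_at_dna <- function(n, at_fraction) {
  n_at <- round(n * at_fraction)
  paste(sample(c(sample(c("A", "T"), n_at, replace = TRUE),
                 sample(c("G", "C"), n - n_at, replace = TRUE))),
        collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
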