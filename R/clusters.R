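## Density-based detection of clusters of functionally related genes.
## All rules operate on gene ordinals (rank along the chromosome), not bp.

#' Average distribution number of a gene family
#'
#' The expected ordinal spacing of family genes under uniform placement:
#' total ORFs divided by family size. For a family occurring once per D
#' genes, a run of members much denser than D betrays clustering.
#'
#' @param n_genes_total total number of ORFs in the genome.
#' @param n_members number of genes in the family.
#' @return The exact quotient D (not rounded).
#' @export
average_distribution_number <- function(n_genes_total, n_members) {
  if (n_members <= 0) stop("n_members must be positive")
  if (n_genes_total <= 0) stop("n_genes_total must be positive")
  n_genes_total / n_members
}

#' Average genomic spacing of a family in kb
#'
#' Under a completely random distribution each family gene is expected once
#' per `genome_size_kb / n_members` kilobases.
#'
#' @param genome_size_kb genome size in kb.
#' @param n_members family size.
#' @return kb per family gene (exact quotient; print at 3 decimals).
#' @export
average_spacing_kb <- function(genome_size_kb, n_members) {
  if (n_members <= 0) stop("n_members must be positive")
  if (genome_size_kb <= 0) stop("genome_size_kb must be positive")
  genome_size_kb / n_members
}

#' Sliding-window parameters from the average distribution number
#'
#' The cluster rule demands a fivefold excess over the expected density: the
#' maximal number of intervening non-family ORFs between consecutive members
#' is `floor(D/5)`, and the implied window length is `min_genes` times that
#' (e.g. D = 50 with at least 3 member genes gives a stretch of 30 genes).
#'
#' @param D average distribution number.
#' @param min_genes minimum member genes per cluster (default 3).
#' @return list with `gap_threshold` and `window_length`.
#' @export
window_parameters <- function(D, min_genes = 3) {
  if (D <= 0) stop("D must be positive")
  if (min_genes < 2) stop("min_genes must be at least 2")
  gap <- floor(D / 5)
  list(gap_threshold = gap, window_length = min_genes * gap)
}

#' Define a gene family and its clustering parameters
#'
#' @param ann a [genome_annotation] (used for totals); or `NULL` if
#'   `n_genes_total` is given.
#' @param label category tag selecting the members.
#' @param min_genes minimum member genes per reported cluster (default 3).
#' @param mode `"max_gap"` (every adjacent member pair separated by at most
#'   `gap_threshold` non-family ORFs) or `"mean_gap"` (mean intervening gap
#'   below D/5 across the run).
#' @param gap_threshold override for the max-gap bound; default
#'   `floor(D/5)`.
#' @param n_genes_total,n_members overrides when `ann` is `NULL`.
#' @return An object of class `family_spec` with fields `name`, `label`,
#'   `n_members`, `D`, `gap_threshold`, `mean_gap_bound`, `min_genes`,
#'   `mode`.
#' @export
family_spec <- function(ann = NULL, label, min_genes = 3,
                        mode = c("max_gap", "mean_gap"),
                        gap_threshold = NULL,
                        n_genes_total = NULL, n_members = NULL) {
  mode <- match.arg(mode)
  if (!is.null(ann)) {
    n_genes_total <- n_genes(ann)
    n_members <- length(genes_with_label(ann, label))
  }
  if (is.null(n_genes_total) || is.null(n_members))
    stop("supply either an annotation or n_genes_total and n_members")
  D <- average_distribution_number(n_genes_total, n_members)
  if (is.null(gap_threshold)) gap_threshold <- floor(D / 5)
  structure(list(name = label, label = label, n_members = n_members,
                 D = D, gap_threshold = gap_threshold,
                 mean_gap_bound = D / 5, min_genes = min_genes, mode = mode),
            class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  cat(sprintf(
    "family_spec '%s': %d members, D = %.2f, mode = %s, %s, min %d genes\n",
    x$label, x$n_members, x$D, x$mode,
    if (x$mode == "max_gap")
      sprintf("gap <= %d", x$gap_threshold)
    else sprintf("mean gap < %.2f", x$mean_gap_bound),
    x$min_genes))
  invisible(x)
}

# Split sorted member ordinals of one chromosome into cluster runs.
# Returns a list of integer vectors (ordinals), each of length >= min_genes.
cluster_runs <- function(ordinals, spec) {
  o <- sort(ordinals)
  if (length(o) < spec$min_genes) return(list())
  gaps <- diff(o) - 1
  if (spec$mode == "max_gap") {
    grp <- cumsum(c(1, gaps > spec$gap_threshold))
    runs <- split(o, grp)
  } else {
    # mean-gap: grow greedily left-to-right while the running mean gap stays
    # below the bound, then trim from the worse end while it does not
    runs <- list()
    run_start <- 1L
    gap_sum <- 0
    for (i in seq_along(gaps)) {
      k <- i - run_start + 1L  # gaps in run if we accept gap i
      if ((gap_sum + gaps[i]) / k < spec$mean_gap_bound) {
        gap_sum <- gap_sum + gaps[i]
      } else {
        runs[[length(runs) + 1L]] <- o[run_start:i]
        run_start <- i + 1L
        gap_sum <- 0
      }
    }
    runs[[length(runs) + 1L]] <- o[run_start:length(o)]
    runs <- lapply(runs, function(r) {
      while (length(r) >= 2) {
        g <- diff(r) - 1
        if (mean(g) < spec$mean_gap_bound) break
        r <- if (g[1] >= g[length(g)]) r[-1] else r[-length(r)]
      }
      r
    })
  }
  unname(runs[lengths(runs) >= spec$min_genes])
}

cluster_frame <- function(family, chrom, runs, genes_chr, extra = NULL) {
  if (!length(runs))
    return(empty_cluster_frame())
  rows <- lapply(runs, function(r) {
    idx <- match(r, genes_chr$ordinal)
    data.frame(family = family, chrom = chrom,
               first_ordinal = min(r), last_ordinal = max(r),
               start = min(genes_chr$start[idx]),
               end = max(genes_chr$end[idx]),
               n_members = length(r),
               member_ids = paste(genes_chr$gene_id[idx], collapse = ","),
               positional_class = "UNSET")
  })
  do.call(rbind, rows)
}

empty_cluster_frame <- function() {
  data.frame(family = character(), chrom = character(),
             first_ordinal = integer(), last_ordinal = integer(),
             start = numeric(), end = numeric(), n_members = integer(),
             member_ids = character(), positional_class = character())
}

#' Detect clusters of a gene family
#'
#' A cluster is a maximal run of at least `min_genes` family genes that are
#' denser along the chromosome than a fivefold excess over their expected
#' spacing: in `max_gap` mode every adjacent member pair is separated by at
#' most `gap_threshold` non-family ORFs; in `mean_gap` mode the mean
#' intervening gap of the run stays below D/5. Clusters never span
#' chromosomes and no reported cluster can be extended.
#'
#' @param ann a [genome_annotation].
#' @param spec a [family_spec].
#' @return data.frame, one row per cluster: `family`, `chrom`,
#'   `first_ordinal`, `last_ordinal`, `start`, `end` (bp envelope from first
#'   member start to last member end), `n_members`, `member_ids`
#'   (comma-separated), `positional_class` (`UNSET` until classified).
#' @seealso [clustered_fraction()], [permutation_test()],
#'   [classify_clusters()]
#' @export
detect_clusters <- function(ann, spec) {
  members <- genes_with_label(ann, spec$label)
  if (length(members) < spec$min_genes) return(empty_cluster_frame())
  g <- ann$genes
  res <- lapply(names(ann$chrom_lengths), function(ch) {
    genes_chr <- g[g$chrom == ch, , drop = FALSE]
    mo <- genes_chr$ordinal[genes_chr$gene_id %in% members]
    cluster_frame(spec$label, ch, cluster_runs(mo, spec), genes_chr)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect secretome clusters (stringent adjacency rule)
#'
#' Reports (a) maximal runs of at least three strictly adjacent genes
#' encoding secreted proteins, and (b) maximal groups of at least four
#' secreted genes interrupted by exactly one interior non-secreted gene.
#' Group boundaries are always secreted genes; adjacent runs separated by a
#' single non-secreted gene are merged greedily left-to-right.
#'
#' @param ann a [genome_annotation].
#' @param label label marking secreted genes (default `"SECRETED"`).
#' @return Cluster data.frame as in [detect_clusters()], with an extra
#'   `n_interruptions` column (0 or 1).
#' @export
detect_secretome_clusters <- function(ann, label = "SECRETED") {
  members <- genes_with_label(ann, label)
  g <- ann$genes
  res <- lapply(names(ann$chrom_lengths), function(ch) {
    genes_chr <- g[g$chrom == ch, , drop = FALSE]
    is_s <- genes_chr$gene_id %in% members
    if (!any(is_s)) return(NULL)
    r <- rle(is_s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    s_idx <- which(r$values)  # indices of secreted runs in the rle
    groups <- list()  # each: list(idx = gene row indices, interruptions)
    i <- 1L
    while (i <= length(s_idx)) {
      ri <- s_idx[i]
      merged <- FALSE
      if (i < length(s_idx)) {
        rj <- s_idx[i + 1L]
        # one run of exactly one non-secreted gene between the two runs
        if (rj == ri + 2L && r$lengths[ri + 1L] == 1L &&
            r$lengths[ri] + r$lengths[rj] >= 4L) {
          groups[[length(groups) + 1L]] <-
            list(idx = c(starts[ri]:ends[ri], starts[rj]:ends[rj]),
                 interruptions = 1L)
          i <- i + 2L
          merged <- TRUE
        }
      }
      if (!merged) {
        if (r$lengths[ri] >= 3L)
          groups[[length(groups) + 1L]] <-
            list(idx = starts[ri]:ends[ri], interruptions = 0L)
        i <- i + 1L
      }
    }
    if (!length(groups)) return(NULL)
    rows <- lapply(groups, function(gr) {
      idx <- gr$idx  # secreted member rows only
      data.frame(family = label, chrom = ch,
                 first_ordinal = min(genes_chr$ordinal[idx]),
                 last_ordinal = max(genes_chr$ordinal[idx]),
                 start = min(genes_chr$start[idx]),
                 end = max(genes_chr$end[idx]),
                 n_members = length(idx),
                 member_ids = paste(genes_chr$gene_id[idx], collapse = ","),
                 positional_class = "UNSET",
                 n_interruptions = gr$interruptions)
    })
    do.call(rbind, rows)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- empty_cluster_frame()
    out$n_interruptions <- integer()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of family genes found in clusters
#'
#' @param ann a [genome_annotation].
#' @param spec a [family_spec].
#' @param clusters optional precomputed result of [detect_clusters()].
#' @return Percentage of family members that sit in a detected cluster.
#' @export
clustered_fraction <- function(ann, spec, clusters = NULL) {
  if (is.null(clusters)) clusters <- detect_clusters(ann, spec)
  100 * sum(clusters$n_members) / spec$n_members
}

# Fast count of clustered members for shuffled ordinals (max_gap mode).
count_clustered <- function(ordinals_sorted, gap_threshold, min_genes) {
  n <- length(ordinals_sorted)
  if (n < min_genes) return(0L)
  grp <- cumsum(c(1, diff(ordinals_sorted) - 1 > gap_threshold))
  runs <- tabulate(grp)
  sum(runs[runs >= min_genes])
}

#' Permutation test for family clustering
#'
#' Shuffles the family label over all gene positions genome-wide (chromosome
#' structure fixed) and recomputes the clustered fraction per permutation.
#' The p-value is `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param ann a [genome_annotation].
#' @param spec a [family_spec].
#' @param n_perm number of permutations (at least 99; default 999).
#' @param seed integer seed for reproducibility.
#' @return An object of class `cluster_permutation_result` with fields
#'   `family`, `observed_clustered_fraction`, `null_fractions`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(ann, spec, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  observed <- clustered_fraction(ann, spec)
  g <- ann$genes
  chrom_f <- factor(g$chrom, levels = names(ann$chrom_lengths))
  ord <- g$ordinal
  m <- spec$n_members
  n <- nrow(g)
  null_fractions <- numeric(n_perm)
  use_fast <- spec$mode == "max_gap"
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    pick <- sample.int(n, m)
    by_chr <- split(ord[pick], chrom_f[pick])
    clustered <- sum(vapply(by_chr, function(o) {
      if (use_fast)
        count_clustered(sort(o), spec$gap_threshold, spec$min_genes)
      else
        sum(lengths(cluster_runs(o, spec)))
    }, numeric(1)))
    null_fractions[p] <- 100 * clustered / m
  }
  p_value <- (1 + sum(null_fractions >= observed)) / (n_perm + 1)
  structure(list(family = spec$label,
                 observed_clustered_fraction = observed,
                 null_fractions = null_fractions,
                 p_value = p_value, n_perm = n_perm, seed = seed),
            class = "cluster_permutation_result")
}

#' @export
print.cluster_permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test '%s': observed %.1f%% clustered, p = %.4g (%d perms)\n",
    x$family, x$observed_clustered_fraction, x$p_value, x$n_perm))
  invisible(x)
}
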