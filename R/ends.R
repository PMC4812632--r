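## Chromosome termini: telomere tandem repeats, window-less GC disparity
## curves, AT-rich subtelomeric tracts, positional classes and GC controls.

# per-base code vector: 1 = A/T, -1 = G/C, 0 = N; error on anything else
base_codes <- function(sequence) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 1L; lut[utf8ToInt("a") + 1L] <- 1L
  lut[utf8ToInt("T") + 1L] <- 1L; lut[utf8ToInt("t") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- -1L; lut[utf8ToInt("g") + 1L] <- -1L
  lut[utf8ToInt("C") + 1L] <- -1L; lut[utf8ToInt("c") + 1L] <- -1L
  lut[utf8ToInt("N") + 1L] <- 0L; lut[utf8ToInt("n") + 1L] <- 0L
  codes <- lut[as.integer(charToRaw(sequence)) + 1L]
  if (anyNA(codes)) stop("sequence contains non-IUPAC characters ",
                         "(only A/C/G/T/N are supported)")
  codes
}

#' AT/GC disparity curve (window-less GC profile)
#'
#' The cumulative AT-excess curve, the GC-relevant component of the Z-curve
#' decomposition of a sequence: each A or T steps the curve by +1, each G or
#' C by -1, each N by 0. Rising stretches are AT-rich, falling stretches
#' GC-rich, with no window size to choose.
#'
#' @param sequence nucleotide string (A/C/G/T/N, case-insensitive).
#' @return Numeric vector `c` of cumulative sums, one per base. The GC
#'   fraction of any slice `[i, j)` (0-based half-open) is recoverable as
#'   `((j - i) - (c[j] - c[i])) / 2 / (j - i)`, exact when the slice has no
#'   N (an N contributes half weight to each side).
#' @export
gc_disparity_curve <- function(sequence) {
  if (!nchar(sequence)) stop("sequence must be non-empty")
  cumsum(base_codes(sequence))
}

#' GC fraction of a slice, from a disparity curve
#' @param curve result of [gc_disparity_curve()].
#' @param start,end 0-based half-open slice bounds.
#' @return GC fraction of the slice.
#' @export
gc_from_curve <- function(curve, start, end) {
  if (start < 0 || end > length(curve) || start >= end)
    stop("slice out of range")
  c_i <- if (start == 0) 0 else curve[start]
  ((end - start) - (curve[end] - c_i)) / 2 / (end - start)
}

revcomp_unit <- function(unit) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
}

#' Find telomere tandem-repeat tracts at chromosome termini
#'
#' Searches for the longest exact tandem array of the repeat unit near each
#' terminus: the unit itself (e.g. `TTAGGG`) read on the forward strand at
#' the 3' terminus, and its reverse complement (`CCCTAA`) at the 5'
#' terminus. A tract is reported when it has at least `min_copies` copies
#' and its outer edge lies within `max_offset` bp of the terminus.
#'
#' @param ann a [genome_annotation] with sequences, or a single nucleotide
#'   string.
#' @param chrom chromosome name when `ann` is an annotation; `NULL` scans
#'   all chromosomes.
#' @param unit repeat unit (default `TTAGGG`, the fungal/vertebrate telomere
#'   repeat).
#' @param min_copies minimum copy number N (default 4).
#' @param max_offset maximal distance of the tract's outer edge from the
#'   terminus (default 1000 bp).
#' @return data.frame with one row per detected tract: `chrom`, `terminus`
#'   (`five_prime`/`three_prime`), `unit`, `n_copies`, `start`, `end`
#'   (0-based half-open; `end - start = n_copies * nchar(unit)`),
#'   `orientation` (`forward`/`revcomp`).
#' @export
find_telomere_tracts <- function(ann, chrom = NULL, unit = "TTAGGG",
                                 min_copies = 4, max_offset = 1000) {
  if (inherits(ann, "genome_annotation")) {
    if (is.null(ann$sequences))
      stop("no sequences loaded; supply a FASTA to read_annotation()")
    chroms <- if (is.null(chrom)) names(ann$chrom_lengths) else chrom
    res <- lapply(chroms, function(ch)
      telomere_scan(chrom_sequence(ann, ch), ch, unit, min_copies,
                    max_offset))
    out <- do.call(rbind, res)
  } else if (is.character(ann) && length(ann) == 1) {
    out <- telomere_scan(toupper(ann), if (is.null(chrom)) "seq" else chrom,
                         unit, min_copies, max_offset)
  } else stop("ann must be a genome_annotation or a nucleotide string")
  rownames(out) <- NULL
  out
}

telomere_scan <- function(seq, chrom, unit, min_copies, max_offset) {
  u <- nchar(unit)
  L <- nchar(seq)
  slice_len <- min(L, max_offset + 1000)
  empty <- data.frame(chrom = character(), terminus = character(),
                      unit = character(), n_copies = integer(),
                      start = numeric(), end = numeric(),
                      orientation = character())
  scan_one <- function(pattern, terminus, orientation) {
    if (terminus == "five_prime") {
      slice <- substr(seq, 1, slice_len)
      offset0 <- 0
    } else {
      slice <- substr(seq, L - slice_len + 1, L)
      offset0 <- L - slice_len
    }
    m <- gregexpr(paste0("(", pattern, ")+"), slice)[[1]]
    if (m[1] == -1) return(empty)
    start0 <- offset0 + as.integer(m) - 1
    len <- attr(m, "match.length")
    end0 <- start0 + len
    n_copies <- len %/% u
    dist <- if (terminus == "five_prime") start0 else L - end0
    keep <- n_copies >= min_copies & dist <= max_offset
    if (!any(keep)) return(empty)
    # longest array wins; ties broken by proximity to the terminus
    i <- which(keep)[order(-len[keep], dist[keep])][1]
    data.frame(chrom = chrom, terminus = terminus, unit = unit,
               n_copies = n_copies[i], start = start0[i], end = end0[i],
               orientation = orientation)
  }
  rbind(scan_one(revcomp_unit(unit), "five_prime", "revcomp"),
        scan_one(unit, "three_prime", "forward"))
}

#' Find AT-rich segments by maximal-scoring subsequences
#'
#' Scores each base `+(1 - theta)` for A/T, `-theta` for G/C and 0 for N, so
#' that a segment has positive score exactly when its AT fraction (over
#' non-N bases) exceeds `theta`; all maximal-scoring subsequences are then
#' extracted by the linear-time Ruzzo-Tompa algorithm and filtered to
#' `min_length`. No window size or tuning is involved: segment positivity is
#' tied analytically to the AT threshold.
#'
#' @param sequence nucleotide string.
#' @param at_threshold AT-fraction threshold theta (default 0.80).
#' @param min_length minimal segment length in bp (default 1000).
#' @return data.frame of disjoint segments ordered 5'->3': `start`, `end`
#'   (0-based half-open), `length`, `at_fraction` (over non-N bases),
#'   `score`.
#' @export
find_at_rich_segments <- function(sequence, at_threshold = 0.80,
                                  min_length = 1000) {
  codes <- base_codes(sequence)
  # integer scores (theta taken to 4 decimals) keep the scan arithmetic
  # exact, so zero-sum boundary extensions cannot flip on rounding noise
  t_int <- round(at_threshold * 10000)
  scores <- numeric(length(codes))
  scores[codes == 1L] <- 10000 - t_int
  scores[codes == -1L] <- -t_int
  seg <- .maximal_scoring_subsequences(scores)
  seg[, "score"] <- seg[, "score"] / 10000
  if (!nrow(seg)) return(empty_at_frame())
  keep <- (seg[, "end"] - seg[, "start"]) >= min_length
  seg <- seg[keep, , drop = FALSE]
  if (!nrow(seg)) return(empty_at_frame())
  cum_at <- cumsum(codes == 1L)
  cum_gc <- cumsum(codes == -1L)
  n_at <- cum_at[seg[, "end"]] - ifelse(seg[, "start"] == 0, 0,
                                        cum_at[seg[, "start"]])
  n_gc <- cum_gc[seg[, "end"]] - ifelse(seg[, "start"] == 0, 0,
                                        cum_gc[seg[, "start"]])
  data.frame(start = seg[, "start"], end = seg[, "end"],
             length = seg[, "end"] - seg[, "start"],
             at_fraction = n_at / (n_at + n_gc),
             score = seg[, "score"])
}

empty_at_frame <- function() {
  data.frame(start = numeric(), end = numeric(), length = numeric(),
             at_fraction = numeric(), score = numeric())
}

#' Configuration of the positional classes
#'
#' Distances are measured from a feature's envelope edge nearest to a
#' chromosome terminus. CEC (chromosome-end) features lie within `cec_max`
#' of a terminus; NCEC (near-chromosome-end) between `ncec_min` and
#' `ncec_max`; everything further in is MCC (middle of the chromosome).
#' Features falling in the gap `(cec_max, ncec_min)` are assigned per
#' `gap_policy` so the three classes partition the chromosome.
#'
#' @param cec_max CEC boundary, bp from the nearest end (default 50,000).
#' @param ncec_min,ncec_max NCEC band, bp (defaults 65,000 and 150,000).
#' @param gap_policy class for features in `(cec_max, ncec_min)`:
#'   `"NCEC"` (default), `"CEC"` or `"MCC"`.
#' @return An object of class `positional_class_config`.
#' @export
positional_class_config <- function(cec_max = 50000, ncec_min = 65000,
                                    ncec_max = 150000,
                                    gap_policy = c("NCEC", "CEC", "MCC")) {
  gap_policy <- match.arg(gap_policy)
  if (!(cec_max <= ncec_min && ncec_min < ncec_max))
    stop("require cec_max <= ncec_min < ncec_max")
  structure(list(cec_max = cec_max, ncec_min = ncec_min,
                 ncec_max = ncec_max, gap_policy = gap_policy),
            class = "positional_class_config")
}

#' Classify a feature span relative to the chromosome ends
#'
#' @param start,end feature span, 0-based half-open (vectorized).
#' @param chrom_length chromosome length in bp (recycled).
#' @param config a [positional_class_config()].
#' @return Character vector in `{"CEC", "NCEC", "MCC"}`.
#' @export
classify_position <- function(start, end, chrom_length,
                              config = positional_class_config()) {
  if (any(start < 0 | end > chrom_length | start >= end))
    stop("feature span outside chromosome")
  dist <- pmin(start, chrom_length - end)
  cls <- rep("MCC", length(dist))
  cls[dist >= config$ncec_min & dist <= config$ncec_max] <- "NCEC"
  cls[dist > config$cec_max & dist < config$ncec_min] <- config$gap_policy
  cls[dist <= config$cec_max] <- "CEC"
  cls
}

#' Positional class of every gene
#'
#' @param ann a [genome_annotation].
#' @param config a [positional_class_config()].
#' @return data.frame: `gene_id`, `chrom`, `distance_bp` (envelope edge to
#'   nearest terminus), `class`.
#' @export
classify_genes <- function(ann, config = positional_class_config()) {
  g <- ann$genes
  len <- ann$chrom_lengths[g$chrom]
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             distance_bp = pmin(g$start, len - g$end),
             class = classify_position(g$start, g$end, len, config),
             row.names = NULL)
}

#' Set the positional class of detected clusters
#'
#' @param clusters cluster table from [detect_clusters()].
#' @param ann a [genome_annotation].
#' @param config a [positional_class_config()].
#' @return The cluster table with `positional_class` filled in.
#' @export
classify_clusters <- function(clusters, ann,
                              config = positional_class_config()) {
  if (!nrow(clusters)) return(clusters)
  len <- ann$chrom_lengths[clusters$chrom]
  clusters$positional_class <-
    classify_position(clusters$start, clusters$end, len, config)
  clusters
}

#' Class assignment of family genes by their cluster (with RANDOM group)
#'
#' Genes belonging to a classified cluster inherit the cluster's positional
#' class; family members outside any cluster form the `RANDOM` group
#' (randomly distributed genes).
#'
#' @param ann a [genome_annotation].
#' @param clusters classified cluster table (see [classify_clusters()]).
#' @param label the family label whose members are being grouped.
#' @return data.frame: `gene_id`, `class`.
#' @export
cluster_class_assignment <- function(ann, clusters, label) {
  members <- genes_with_label(ann, label)
  cls <- rep("RANDOM", length(members))
  names(cls) <- members
  if (nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      ids <- strsplit(clusters$member_ids[i], ",", fixed = TRUE)[[1]]
      ids <- intersect(ids, members)
      cls[ids] <- clusters$positional_class[i]
    }
  }
  data.frame(gene_id = names(cls), class = unname(cls))
}

#' GC statistics of randomly sampled non-terminal regions
#'
#' Samples fixed-length windows uniformly from the parts of the genome more
#' than `exclude_terminal` bp away from any chromosome end, as a background
#' control for the terminal AT-rich tracts. Two AT statistics are reported:
#' the fraction of windows whose overall AT content exceeds
#' `at_threshold`, and the fraction containing at least one AT-rich segment
#' (per [find_at_rich_segments()]).
#'
#' @param ann a [genome_annotation] with sequences.
#' @param n_regions number of windows (default 100).
#' @param region_length window length in bp (default 20,000).
#' @param exclude_terminal terminal exclusion zone in bp (default 50,000).
#' @param at_threshold AT threshold (default 0.80).
#' @param min_length minimal AT-segment length (default 1000).
#' @param seed integer seed; the sampled coordinates are reproducible.
#' @return An object of class `region_gc_stats`: `n_regions`,
#'   `region_length`, `mean_gc` and `sd_gc` (percent), `fraction_at_above_threshold`,
#'   `fraction_with_at_segment`, `regions` (data.frame of sampled windows
#'   with their GC), `seed`.
#' @export
sample_region_gc <- function(ann, n_regions = 100, region_length = 20000,
                             exclude_terminal = 50000, at_threshold = 0.80,
                             min_length = 1000, seed = 1L) {
  if (is.null(ann$sequences)) stop("no sequences loaded")
  lens <- ann$chrom_lengths
  n_valid <- lens - 2 * exclude_terminal - region_length + 1
  n_valid[n_valid < 0] <- 0
  short <- names(lens)[n_valid == 0]
  if (length(short))
    warning("chromosome(s) too short for non-terminal sampling, skipped: ",
            paste(short, collapse = ", "))
  if (all(n_valid == 0)) stop("no chromosome admits a non-terminal window")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  chroms <- sample(names(lens), n_regions, replace = TRUE,
                   prob = n_valid / sum(n_valid))
  starts <- exclude_terminal +
    floor(runif(n_regions) * n_valid[chroms])
  gc <- numeric(n_regions)
  at_whole <- logical(n_regions)
  has_segment <- logical(n_regions)
  for (i in seq_len(n_regions)) {
    slice <- substr(chrom_sequence(ann, chroms[i]), starts[i] + 1,
                    starts[i] + region_length)
    codes <- base_codes(slice)
    n_at <- sum(codes == 1L); n_gc <- sum(codes == -1L)
    gc[i] <- 100 * n_gc / (n_at + n_gc)
    at_whole[i] <- n_at / (n_at + n_gc) > at_threshold
    has_segment[i] <- nrow(find_at_rich_segments(
      slice, at_threshold = at_threshold, min_length = min_length)) > 0
  }
  structure(list(n_regions = n_regions, region_length = region_length,
                 mean_gc = mean(gc), sd_gc = sd(gc),
                 fraction_at_above_threshold = mean(at_whole),
                 fraction_with_at_segment = mean(has_segment),
                 regions = data.frame(chrom = chroms, start = starts,
                                      end = starts + region_length,
                                      gc_percent = gc),
                 seed = seed),
            class = "region_gc_stats")
}

#' @export
print.region_gc_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "region_gc_stats: %d x %.0f kb non-terminal windows\n",
    "  GC %.1f%% [+-%.1f]; AT>threshold whole-window: %.0f%%; ",
    "containing an AT-rich segment: %.0f%%\n"),
    x$n_regions, x$region_length / 1000, x$mean_gc, x$sd_gc,
    100 * x$fraction_at_above_threshold,
    100 * x$fraction_with_at_segment))
  invisible(x)
}
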