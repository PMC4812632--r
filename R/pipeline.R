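## End-to-end pipeline: ends -> clusters -> classification -> expression and
## marks, with per-stage TSV/BED outputs and a consolidated summary.

#' Run configuration for the full pipeline
#'
#' @param annotation path to GFF3/TSV, or a [genome_annotation].
#' @param fasta optional FASTA path (needed for the sequence stages).
#' @param expression optional expression TSV path or [expression_table].
#' @param marks optional marks TSV path or data.frame.
#' @param families labels to analyse; `NULL` uses every label present.
#' @param class_config a [positional_class_config()].
#' @param reference reference condition for induction calls
#'   (default `"glucose"`).
#' @param fold induction threshold (default 2).
#' @param min_genes,mode,gap_threshold cluster-rule settings (see
#'   [family_spec()]).
#' @param at_threshold,min_length AT-segment settings.
#' @param telomere_unit,min_copies,max_offset telomere settings.
#' @param n_perm permutations for per-family significance (0 disables).
#' @param seed seed for the permutation stage.
#' @param value_kind expression value kind (see [expression_table()]).
#' @param out_dir output directory; `NULL` suppresses file output.
#' @param quiet suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(annotation, fasta = NULL, expression = NULL,
                       marks = NULL, families = NULL,
                       class_config = positional_class_config(),
                       reference = "glucose", fold = 2, min_genes = 3,
                       mode = "max_gap", gap_threshold = NULL,
                       at_threshold = 0.80, min_length = 1000,
                       telomere_unit = "TTAGGG", min_copies = 4,
                       max_offset = 1000, n_perm = 0, seed = 1L,
                       value_kind = "rpkm", out_dir = NULL, quiet = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(quiet, ...) if (!quiet) message("[chromarch] ", ...)

#' Run the full chromosome-architecture pipeline
#'
#' Executes, in order: annotation loading, chromosome-end characterization
#' (telomere tracts, AT-rich segments, positional gene classes), family
#' cluster detection with positional classification (plus the stringent
#' secretome rule when a `SECRETED` label is present), and - when
#' expression/mark tables are supplied - induction calls, per-class
#' summaries, enrichment tables, mark counts and pairwise Welch tests.
#' Every threshold used is logged; missing optional inputs degrade to
#' skipped sections rather than failures.
#'
#' @param config a [run_config()].
#' @return A report bundle (list) with elements `annotation`, `telomeres`,
#'   `at_segments`, `gene_classes`, `clusters`, `family_summary`,
#'   `secretome_clusters`, `expression` (or `NULL`), `enrichment`,
#'   `mark_counts`, `welch`, `summary` (named list of headline numbers) and
#'   `config`. When `config$out_dir` is set, per-stage TSV/BED files plus
#'   `summary.json` and a config echo are written there.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  q <- config$quiet

  ## stage: annotation
  ann <- tryCatch({
    if (inherits(config$annotation, "genome_annotation")) {
      if (!is.null(config$fasta) && is.null(config$annotation$sequences))
        stop("pass the FASTA to read_annotation() instead")
      config$annotation
    } else read_annotation(config$annotation, fasta = config$fasta)
  }, error = function(e) stop("stage annotation: ", conditionMessage(e),
                              call. = FALSE))
  pipeline_log(q, "annotation: ", n_genes(ann), " genes on ",
               length(ann$chrom_lengths), " chromosomes")

  ## stage: chromosome ends
  telomeres <- NULL
  at_segments <- NULL
  if (!is.null(ann$sequences)) {
    telomeres <- find_telomere_tracts(ann, unit = config$telomere_unit,
                                      min_copies = config$min_copies,
                                      max_offset = config$max_offset)
    seg <- lapply(names(ann$chrom_lengths), function(ch) {
      s <- find_at_rich_segments(chrom_sequence(ann, ch),
                                 at_threshold = config$at_threshold,
                                 min_length = config$min_length)
      if (nrow(s)) cbind(chrom = ch, s) else NULL
    })
    seg <- seg[!vapply(seg, is.null, logical(1))]
    at_segments <- if (length(seg)) do.call(rbind, seg) else
      cbind(chrom = character(), empty_at_frame())
    pipeline_log(q, "ends: ", NROW(telomeres), " telomere tract(s) (unit ",
                 config$telomere_unit, ", min_copies ", config$min_copies,
                 "), ", NROW(at_segments), " AT-rich segment(s) (theta ",
                 config$at_threshold, ", min_length ", config$min_length,
                 ")")
  } else {
    pipeline_log(q, "ends: skipped (no sequences)")
  }
  gene_classes <- classify_genes(ann, config$class_config)

  ## stage: clusters
  families <- config$families
  if (is.null(families)) families <- sort(unique(ann$labels$label))
  clusters <- empty_cluster_frame()
  fam_rows <- list()
  for (fam in families) {
    spec <- tryCatch(
      family_spec(ann, fam, min_genes = config$min_genes,
                  mode = config$mode, gap_threshold = config$gap_threshold),
      error = function(e) stop("stage clusters (", fam, "): ",
                               conditionMessage(e), call. = FALSE))
    cl <- classify_clusters(detect_clusters(ann, spec), ann,
                            config$class_config)
    clusters <- rbind(clusters, cl)
    p_val <- NA_real_
    if (config$n_perm > 0 && spec$n_members >= spec$min_genes)
      p_val <- permutation_test(ann, spec, n_perm = config$n_perm,
                                seed = config$seed)$p_value
    fam_rows[[fam]] <- data.frame(
      family = fam, n_members = spec$n_members, D = spec$D,
      gap_threshold = spec$gap_threshold, n_clusters = nrow(cl),
      n_clustered = sum(cl$n_members),
      pct_clustered = round(clustered_fraction(ann, spec, cl), 1),
      perm_p = p_val)
  }
  family_summary <- do.call(rbind, fam_rows)
  rownames(family_summary) <- NULL
  secretome <- NULL
  if ("SECRETED" %in% ann$labels$label)
    secretome <- classify_clusters(detect_secretome_clusters(ann), ann,
                                   config$class_config)
  pipeline_log(q, "clusters: ", nrow(clusters), " cluster(s) across ",
               length(families), " famil(ies), min_genes ",
               config$min_genes, ", mode ", config$mode)

  ## stage: expression / marks
  expr <- NULL; enrichment <- NULL; welch <- NULL; mark_counts <- NULL
  group_means <- NULL; induction <- NULL
  if (!is.null(config$expression)) {
    expr <- if (inherits(config$expression, "expression_table"))
      config$expression
    else read_expression_table(config$expression,
                               value_kind = config$value_kind)
    conds <- setdiff(expr$conditions, config$reference)
    enrichment <- condition_enrichment_table(
      expr, gene_classes, conds, config$reference, fold = config$fold)
    group_means <- group_mean_expression(expr, gene_classes,
                                         config$reference)
    induction <- do.call(rbind, lapply(conds, function(cond)
      cbind(condition = cond,
            induction_ratio(expr, gene_classes, cond, config$reference))))
    welch <- compare_classes(expr, gene_classes, config$reference)
    pipeline_log(q, "expression: ", length(expr$genes), " genes, fold > ",
                 config$fold, " vs ", config$reference)
  } else {
    pipeline_log(q, "expression: skipped (no table)")
  }
  if (!is.null(config$marks)) {
    marks <- if (is.data.frame(config$marks)) config$marks else
      read_marks_table(config$marks)
    mark_counts <- mark_counts_by_class(marks, gene_classes)
    pipeline_log(q, "marks: ", nrow(marks), " call(s)")
  } else {
    pipeline_log(q, "marks: skipped (no table)")
  }

  summary <- list(
    n_genes = n_genes(ann),
    genome_size = genome_size(ann),
    n_chromosomes = length(ann$chrom_lengths),
    n_telomere_tracts = NROW(telomeres),
    n_at_segments = NROW(at_segments),
    gene_class_counts = as.list(table(gene_classes$class)),
    n_clusters = nrow(clusters),
    cluster_class_counts = as.list(table(clusters$positional_class)),
    n_secretome_clusters = NROW(secretome),
    pct_clustered_by_family = stats::setNames(
      as.list(family_summary$pct_clustered), family_summary$family),
    expression_analysed = !is.null(expr),
    marks_analysed = !is.null(mark_counts))

  bundle <- list(annotation = ann, telomeres = telomeres,
                 at_segments = at_segments, gene_classes = gene_classes,
                 clusters = clusters, family_summary = family_summary,
                 secretome_clusters = secretome, expression = expr,
                 group_means = group_means, induction = induction,
                 enrichment = enrichment, mark_counts = mark_counts,
                 welch = welch, summary = summary, config = config)

  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- bundle$config
  if (!is.null(bundle$telomeres))
    write_tsv(bundle$telomeres, file.path(dir, "telomeres.tsv"))
  if (!is.null(bundle$at_segments))
    write_clusters_bed(
      if (nrow(bundle$at_segments))
        data.frame(chrom = bundle$at_segments$chrom,
                   start = bundle$at_segments$start,
                   end = bundle$at_segments$end,
                   family = "AT_RICH",
                   n_members = round(bundle$at_segments$length))
      else empty_cluster_frame(),
      file.path(dir, "at_segments.bed"))
  write_tsv(bundle$gene_classes, file.path(dir, "gene_classes.tsv"))
  write_tsv(bundle$clusters, file.path(dir, "clusters.tsv"))
  write_clusters_bed(bundle$clusters, file.path(dir, "clusters.bed"))
  write_tsv(bundle$family_summary, file.path(dir, "family_summary.tsv"))
  if (!is.null(bundle$secretome_clusters))
    write_tsv(bundle$secretome_clusters,
              file.path(dir, "secretome_clusters.tsv"))
  if (!is.null(bundle$enrichment))
    write_tsv(bundle$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(bundle$group_means))
    write_tsv(bundle$group_means, file.path(dir, "group_means.tsv"))
  if (!is.null(bundle$induction))
    write_tsv(bundle$induction, file.path(dir, "induction.tsv"))
  if (!is.null(bundle$mark_counts))
    write_tsv(bundle$mark_counts, file.path(dir, "mark_counts.tsv"))
  if (!is.null(bundle$welch))
    write_tsv(bundle$welch, file.path(dir, "welch_tests.tsv"))
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  echo <- cfg[!vapply(cfg, function(x)
    is.environment(x) || inherits(x, c("genome_annotation",
                                       "expression_table")) ||
      is.data.frame(x), logical(1))]
  echo$class_config <- unclass(echo$class_config)
  jsonlite::write_json(echo, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(dir)
}
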