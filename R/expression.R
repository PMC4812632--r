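## Gene-level expression and histone-mark integration: induction calls,
## class-wise summaries, enrichment tables and Welch tests.

SUPPORTED_MARKS <- c("H3K4me2", "H3K4me3", "H3K9me3")

#' Build an expression table
#'
#' @param values numeric gene x condition matrix (rownames = gene ids,
#'   colnames = condition names).
#' @param value_kind `"rpkm"` (linear, non-negative) or `"log_intensity"`
#'   (log hybridization intensity; ratios are computed after de-logging).
#' @param log_base base used to de-log `log_intensity` values (default 2).
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, value_kind = c("rpkm", "log_intensity"),
                             log_base = 2) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene ids as rownames and conditions as colnames")
  drop_n <- sum(!stats::complete.cases(values))
  if (drop_n) {
    message("dropping ", drop_n, " gene(s) with missing values")
    values <- values[stats::complete.cases(values), , drop = FALSE]
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (value_kind == "rpkm" && any(values < 0))
    stop("rpkm values must be non-negative")
  structure(list(values = values, genes = rownames(values),
                 conditions = colnames(values), value_kind = value_kind,
                 log_base = log_base),
            class = "expression_table")
}

#' Read a gene-level expression TSV
#'
#' Expected layout: header row, first column `gene_id`, one column per
#' condition. Genes with missing values in any condition are dropped (the
#' count is logged).
#'
#' @param path TSV file.
#' @inheritParams expression_table
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path, value_kind = c("rpkm",
                                                        "log_intensity"),
                                  log_base = 2) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  expression_table(m, value_kind = value_kind, log_base = log_base)
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d conditions (%s)\n",
              length(x$genes), length(x$conditions), x$value_kind))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene-level histone-mark call table
#'
#' @param path TSV with columns `gene_id`, `mark`, one row per call; marks
#'   restricted to H3K4me2, H3K4me3 and H3K9me3.
#' @return data.frame of calls.
#' @export
read_marks_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "mark") %in% names(d)))
    stop("marks table needs columns gene_id, mark")
  bad <- setdiff(unique(d$mark), SUPPORTED_MARKS)
  if (length(bad))
    stop("unsupported mark(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(SUPPORTED_MARKS, collapse = ", "), ")")
  unique(d[c("gene_id", "mark")])
}

linear_values <- function(expr, condition) {
  if (!condition %in% expr$conditions)
    stop("unknown condition: ", condition)
  v <- expr$values[, condition]
  if (expr$value_kind == "log_intensity") expr$log_base^v else v
}

#' Genes induced relative to a reference condition
#'
#' A gene is induced when its (linear-scale) value on `condition` exceeds
#' `fold` times its value on `reference` (strictly greater than). For
#' `log_intensity` data the ratio is computed after de-logging with the
#' table's `log_base`. When zeros are present on either side a pseudo-count
#' (default 0.1 RPKM) is added to numerator and denominator, and a message
#' is logged.
#'
#' @param expr an [expression_table].
#' @param condition,reference condition names.
#' @param fold induction threshold (default 2).
#' @param pseudo_count pseudo-count used when zeros occur (default 0.1).
#' @return Character vector of induced gene ids.
#' @export
induced_genes <- function(expr, condition, reference, fold = 2,
                          pseudo_count = 0.1) {
  num <- linear_values(expr, condition)
  den <- linear_values(expr, reference)
  if (any(num == 0) || any(den == 0)) {
    message("zero values present; adding pseudo-count ", pseudo_count,
            " to both sides of the ratio")
    num <- num + pseudo_count
    den <- den + pseudo_count
  }
  expr$genes[num / den > fold]
}

#' Per-class mean expression summary
#'
#' Arithmetic mean and standard deviation of a condition's values within
#' each class of a gene-class assignment, after removing named exclusions
#' (e.g. extreme outlier genes whose expression would corrupt the class
#' statistics).
#'
#' @param expr an [expression_table].
#' @param class_assignment data.frame with columns `gene_id`, `class`
#'   (see [classify_genes()] or [cluster_class_assignment()]).
#' @param condition condition name.
#' @param exclusions character vector of gene ids to omit.
#' @return data.frame, one row per class: `group`, `condition`, `n`,
#'   `mean`, `sd` (`mean`/`sd` are `NA` for empty classes), plus an
#'   `excluded_genes` attribute.
#' @export
group_mean_expression <- function(expr, class_assignment, condition,
                                  exclusions = NULL) {
  if (!condition %in% expr$conditions)
    stop("unknown condition: ", condition)
  v <- expr$values[, condition]
  ca <- class_assignment[class_assignment$gene_id %in% expr$genes, ]
  ca <- ca[!ca$gene_id %in% exclusions, ]
  classes <- sort(unique(class_assignment$class))
  rows <- lapply(classes, function(cl) {
    ids <- ca$gene_id[ca$class == cl]
    x <- v[ids]
    data.frame(group = cl, condition = condition, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) sd(x) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded_genes") <-
    intersect(exclusions, class_assignment$gene_id)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class induction ratio ("fold" increase over a reference condition)
#'
#' Class mean on `condition` divided by class mean on `reference`, per
#' class. A zero reference mean yields `NA` (flagged undefined).
#'
#' @inheritParams group_mean_expression
#' @param reference reference condition name.
#' @return data.frame: `group`, `n`, `mean_condition`, `mean_reference`,
#'   `fold`.
#' @export
induction_ratio <- function(expr, class_assignment, condition, reference,
                            exclusions = NULL) {
  a <- group_mean_expression(expr, class_assignment, condition, exclusions)
  b <- group_mean_expression(expr, class_assignment, reference, exclusions)
  fold <- ifelse(is.na(b$mean) | b$mean == 0, NA_real_, a$mean / b$mean)
  data.frame(group = a$group, n = a$n, mean_condition = a$mean,
             mean_reference = b$mean, fold = fold)
}

#' Welch's two-sample t test (unequal variances)
#'
#' Two-sided t test without the equal-variance assumption, with
#' Welch-Satterthwaite degrees of freedom; the standard test for comparing
#' group mean expression between classes of unequal spread.
#'
#' @param sample_a,sample_b numeric vectors, each of length at least 2.
#' @return An object of class `welch_result`: `t`, `df`, `p_two_sided`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 observations")
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b)))
    stop("samples must be finite")
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_two_sided = ht$p.value),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, two-sided p = %.4g\n",
              x$t, x$df, x$p_two_sided))
  invisible(x)
}

#' Histone-mark counts and percentages per class
#'
#' @param marks data.frame of calls (`gene_id`, `mark`), see
#'   [read_marks_table()].
#' @param class_assignment data.frame (`gene_id`, `class`) covering the
#'   genes of interest; class sizes are the percentage denominators.
#' @return data.frame: `class`, `mark`, `n_class` (genes in the class),
#'   `n_marked`, `percent` (share of class genes carrying the mark).
#' @export
mark_counts_by_class <- function(marks, class_assignment) {
  classes <- sort(unique(class_assignment$class))
  out <- expand.grid(class = classes, mark = SUPPORTED_MARKS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_class <- vapply(out$class, function(cl)
    sum(class_assignment$class == cl), numeric(1))
  out$n_marked <- mapply(function(cl, mk) {
    ids <- class_assignment$gene_id[class_assignment$class == cl]
    sum(marks$gene_id %in% ids & marks$mark == mk)
  }, out$class, out$mark)
  out$percent <- ifelse(out$n_class > 0,
                        100 * out$n_marked / out$n_class, NA_real_)
  out[order(out$class, out$mark), ]
}

#' Per-class induced-gene enrichment table
#'
#' For each class and condition: the number of genes induced over the
#' reference (greater than `fold`-fold) and the percentage of the class
#' that number represents.
#'
#' @inheritParams induced_genes
#' @param class_assignment data.frame (`gene_id`, `class`).
#' @param conditions condition names to tabulate.
#' @return data.frame: `class`, `condition`, `n_class`, `n_induced`,
#'   `percent` (1 decimal).
#' @export
condition_enrichment_table <- function(expr, class_assignment, conditions,
                                       reference, fold = 2,
                                       pseudo_count = 0.1) {
  classes <- sort(unique(class_assignment$class))
  rows <- list()
  for (cond in conditions) {
    ind <- induced_genes(expr, cond, reference, fold = fold,
                         pseudo_count = pseudo_count)
    for (cl in classes) {
      ids <- class_assignment$gene_id[class_assignment$class == cl]
      n_cl <- length(ids)
      n_ind <- length(intersect(ids, ind))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, condition = cond, n_class = n_cl, n_induced = n_ind,
        percent = if (n_cl > 0) round(100 * n_ind / n_cl, 1) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise Welch comparisons between classes, with FDR control
#'
#' Welch tests of a condition's values between every pair of classes;
#' Benjamini-Hochberg adjustment is applied when more than five comparisons
#' are made in one report.
#'
#' @inheritParams group_mean_expression
#' @return data.frame: `group_a`, `group_b`, `t`, `df`, `p`, `p_adj`.
#' @export
compare_classes <- function(expr, class_assignment, condition,
                            exclusions = NULL) {
  if (!condition %in% expr$conditions)
    stop("unknown condition: ", condition)
  v <- expr$values[, condition]
  ca <- class_assignment[class_assignment$gene_id %in% expr$genes, ]
  ca <- ca[!ca$gene_id %in% exclusions, ]
  classes <- sort(unique(ca$class))
  pairs <- if (length(classes) >= 2) utils::combn(classes, 2) else
    matrix(character(), 2, 0)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- v[ca$gene_id[ca$class == pairs[1, i]]]
    b <- v[ca$gene_id[ca$class == pairs[2, i]]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
                        t = NA_real_, df = NA_real_, p = NA_real_))
    w <- welch_t_test(a, b)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               t = w$t, df = w$df, p = w$p_two_sided)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(group_a = character(),
                                      group_b = character(), t = numeric(),
                                      df = numeric(), p = numeric())
  out$p_adj <- if (nrow(out) > 5) p.adjust(out$p, method = "BH") else out$p
  out
}
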