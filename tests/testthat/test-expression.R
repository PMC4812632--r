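# Expression induction calls, class summaries, Welch tests and mark counts.

make_expr <- function(values) expression_table(values, value_kind = "rpkm")

test_that("induction calls use a strict fold threshold on linear values", {
  v <- matrix(c(10, 5, 8,
                25, 5, 16), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"),
                              c("glucose", "cellulose")))
  expr <- make_expr(v[, c("glucose", "cellulose")])
  ind <- induced_genes(expr, "cellulose", "glucose")
  expect_setequal(ind, "g1")          # 2.5-fold in; exactly 2-fold out
  expect_error(induced_genes(expr, "xylose", "glucose"), "unknown")
})

test_that("log-intensity tables de-log before forming ratios", {
  v <- matrix(c(3, 3,
                4.5, 3.5), ncol = 2,
              dimnames = list(c("g1", "g2"), c("glucose", "lactose")))
  expr <- expression_table(v, value_kind = "log_intensity", log_base = 2)
  # 2^(4.5-3) = 2.83-fold vs 2^(0.5) = 1.41-fold
  expect_equal(induced_genes(expr, "lactose", "glucose"), "g1")
})

test_that("zeros trigger the pseudo-count and a log message", {
  v <- matrix(c(0, 1,
                5, 1.5), ncol = 2,
              dimnames = list(c("g1", "g2"), c("glucose", "cellulose")))
  expr <- make_expr(v)
  expect_message(ind <- induced_genes(expr, "cellulose", "glucose"),
                 "pseudo-count")
  # (5 + 0.1) / (0 + 0.1) = 51-fold
  expect_setequal(ind, "g1")
})

test_that("planted induced genes are recovered exactly from a synthetic
           table", {
  sim <- simulate_genome(synthetic_genome_config(seed = 5))
  for (cond in c("cellulose", "lactose", "sophorose", "conidiation")) {
    got <- induced_genes(sim$expression, cond, "glucose")
    expect_setequal(got, sim$manifest$induced_genes[[cond]])
  }
})

test_that("group means, exclusions and the single-class identity", {
  v <- matrix(c(1, 2, 3, 10), ncol = 1,
              dimnames = list(sprintf("g%d", 1:4), "glucose"))
  expr <- make_expr(v)
  ca <- data.frame(gene_id = sprintf("g%d", 1:4),
                   class = c("A", "A", "A", "B"))
  gm <- group_mean_expression(expr, ca, "glucose")
  expect_equal(gm$mean[gm$group == "A"], 2)
  expect_equal(gm$sd[gm$group == "A"], 1)
  # excluding an outlier changes the mean by the closed-form amount
  ca2 <- data.frame(gene_id = sprintf("g%d", 1:4), class = "A")
  with_out <- group_mean_expression(expr, ca2, "glucose")
  without <- group_mean_expression(expr, ca2, "glucose",
                                   exclusions = "g4")
  expect_equal(without$mean, (4 * with_out$mean - 10) / 3)
  expect_equal(without$n, 3)
  # single class equals the global mean
  expect_equal(with_out$mean, mean(v))
  # empty class is flagged, not an error
  ca3 <- data.frame(gene_id = "g1", class = "A")
  gm3 <- group_mean_expression(expr, ca3, "glucose", exclusions = "g1")
  expect_equal(gm3$n, 0)
  expect_true(is.na(gm3$mean))
})

test_that("induction ratio is the ratio of class means", {
  v <- matrix(c(1, 2, 2, 4), ncol = 2,
              dimnames = list(c("g1", "g2"), c("glucose", "cellulose")))
  expr <- make_expr(v)
  ca <- data.frame(gene_id = c("g1", "g2"), class = "X")
  ir <- induction_ratio(expr, ca, "cellulose", "glucose")
  expect_equal(ir$fold, 2)
  ir_same <- induction_ratio(expr, ca, "glucose", "glucose")
  expect_equal(ir_same$fold, 1)
})

test_that("Welch test agrees with the numerical-integration oracle", {
  w <- welch_t_test(1:5, 2:6)
  o <- oracle_welch(1:5, 2:6)
  # frozen reference: t = -1, df = 8, p = 0.346594
  expect_equal(w$t, -1)
  expect_equal(w$df, 8)
  expect_equal(round(w$p_two_sided, 6), 0.346594)
  expect_lt(abs(w$p_two_sided - o$p), 1e-6)

  set.seed(61)
  for (rep in 1:50) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    w <- welch_t_test(a, b)
    o <- oracle_welch(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_lt(abs(w$p_two_sided - o$p), 1e-6)
    # symmetry: swapping samples negates t, preserves p
    ws <- welch_t_test(b, a)
    expect_equal(ws$t, -w$t)
    expect_equal(ws$p_two_sided, w$p_two_sided)
  }
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  expect_error(welch_t_test(1, 1:5), "at least 2")
})

test_that("mark counts and percentages per class", {
  ca <- data.frame(gene_id = sprintf("g%d", 1:10),
                   class = rep(c("CEC", "MCC"), each = 5))
  none <- mark_counts_by_class(data.frame(gene_id = character(),
                                          mark = character()), ca)
  expect_true(all(none$n_marked == 0))
  all_marked <- do.call(rbind, lapply(c("H3K4me2", "H3K4me3", "H3K9me3"),
                                      function(m)
                                        data.frame(gene_id = ca$gene_id,
                                                   mark = m)))
  mc <- mark_counts_by_class(all_marked, ca)
  expect_true(all(mc$percent == 100))
  some <- data.frame(gene_id = c("g1", "g2", "g6"), mark = "H3K9me3")
  mc2 <- mark_counts_by_class(some, ca)
  expect_equal(mc2$percent[mc2$class == "CEC" & mc2$mark == "H3K9me3"], 40)
  expect_equal(mc2$percent[mc2$class == "MCC" & mc2$mark == "H3K9me3"], 20)
})

test_that("enrichment table reports class-wise induced counts and
           percentages", {
  set.seed(71)
  n <- 148
  ids <- sprintf("g%03d", 1:n)
  glu <- runif(n, 1, 10)
  cel <- glu * 1.1
  cel[1:64] <- glu[1:64] * 3    # 64 induced
  con <- glu * 1.1
  con[1:120] <- glu[1:120] * 4  # 120 induced
  v <- cbind(glucose = glu, cellulose = cel, conidiation = con)
  rownames(v) <- ids
  expr <- make_expr(v)
  ca <- data.frame(gene_id = ids, class = "SSCP")
  tab <- condition_enrichment_table(expr, ca, c("cellulose", "conidiation"),
                                    "glucose")
  expect_equal(tab$n_induced[tab$condition == "cellulose"], 64)
  expect_equal(tab$percent[tab$condition == "cellulose"], 43.2)
  expect_equal(tab$n_induced[tab$condition == "conidiation"], 120)
  expect_equal(round(tab$percent[tab$condition == "conidiation"]), 81)
  # counts over a partition sum to the total induced
  ca2 <- data.frame(gene_id = ids,
                    class = rep(c("A", "B"), length.out = n))
  tab2 <- condition_enrichment_table(expr, ca2, "cellulose", "glucose")
  expect_equal(sum(tab2$n_induced),
               length(induced_genes(expr, "cellulose", "glucose")))
})

test_that("class comparisons apply BH adjustment only beyond five tests", {
  set.seed(81)
  ids <- sprintf("g%d", 1:60)
  v <- matrix(rnorm(60, 10), ncol = 1, dimnames = list(ids, "glucose"))
  expr <- make_expr(abs(v))
  ca4 <- data.frame(gene_id = ids, class = rep(c("A", "B", "C", "D"), 15))
  cc <- compare_classes(expr, ca4, "glucose")
  expect_equal(nrow(cc), 6)  # 4 choose 2 -> BH applies
  expect_true(all(cc$p_adj >= cc$p - 1e-12))
  ca2 <- data.frame(gene_id = ids, class = rep(c("A", "B"), 30))
  cc2 <- compare_classes(expr, ca2, "glucose")
  expect_equal(cc2$p_adj, cc2$p)
})

test_that("expression tables validate and round-trip through TSV", {
  v <- matrix(c(1.5, 2.5, 3.5, 4.5), 2,
              dimnames = list(c("g1", "g2"), c("glucose", "lactose")))
  expr <- make_expr(v)
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = rownames(v), v, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression_table(path)
  expect_equal(back$values, expr$values)
  v_bad <- v; v_bad[1, 1] <- -1
  expect_error(make_expr(v_bad), "non-negative")
  v_na <- v; v_na[1, 1] <- NA
  expect_message(dropped <- make_expr(v_na), "dropping 1")
  expect_equal(dropped$genes, "g2")
})
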