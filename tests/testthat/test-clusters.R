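# Density-based cluster detection and its significance assessment.

test_that("average distribution number and spacing follow the arithmetic", {
  expect_equal(average_distribution_number(100, 100), 1)
  expect_equal(average_distribution_number(9194, 228), 9194 / 228)
  expect_equal(round(average_distribution_number(9194, 228), 2), 40.32)
  expect_error(average_distribution_number(9194, 0), "positive")
  expect_equal(average_spacing_kb(1000, 10), 100)
  expect_error(average_spacing_kb(1000, 0), "positive")
  # kb spacing and ordinal spacing agree through the genome-wide gene pitch:
  # 146.052 kb per family gene at 3.56 kb per gene is one per 41 ORFs
  expect_equal(round(average_spacing_kb(33300, 228) / 3.56), 41)
})

test_that("window parameters implement the fivefold-excess rule", {
  expect_equal(window_parameters(50, 3),
               list(gap_threshold = 10, window_length = 30))
  expect_equal(window_parameters(41, 3)$gap_threshold, 8)
  expect_equal(window_parameters(5, 3),
               list(gap_threshold = 1, window_length = 3))
  expect_error(window_parameters(0, 3), "positive")
  expect_error(window_parameters(50, 1), "at least 2")
})

test_that("max-gap detection matches hand-enumerated examples", {
  ann <- make_annotation(40, labelled = list(c(1, 5, 9)))
  spec <- family_spec(ann, "FAM", gap_threshold = 8)
  cl <- detect_clusters(ann, spec)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 3)
  expect_equal(member_ordinal_sets(ann, cl)[[1]], c(1, 5, 9))

  ann2 <- make_annotation(40, labelled = list(c(1, 15, 30)))
  spec2 <- family_spec(ann2, "FAM", gap_threshold = 8)
  expect_equal(nrow(detect_clusters(ann2, spec2)), 0)

  ann3 <- make_annotation(40)  # no members at all
  expect_error(family_spec(ann3, "FAM"), "unknown label")
})

test_that("families below min_genes return no clusters", {
  ann <- make_annotation(40, labelled = list(c(3, 4)))
  spec <- family_spec(ann, "FAM", gap_threshold = 8)
  expect_equal(nrow(detect_clusters(ann, spec)), 0)
})

test_that("max-gap detection equals the brute-force window oracle", {
  set.seed(402)
  for (rep in 1:30) {
    n <- sample(30:200, 1)
    m <- sample(5:min(25, n), 1)
    thr <- sample(1:10, 1)
    ann <- random_family_annotation(n, m)
    spec <- family_spec(ann, "FAM", gap_threshold = thr)
    got <- member_ordinal_sets(ann, detect_clusters(ann, spec))
    want <- oracle_max_gap_clusters(
      ann$genes$ordinal[ann$genes$gene_id %in% genes_with_label(ann, "FAM")],
      thr)
    expect_equal(got, want)
  }
})

test_that("clusters are ordinal-based: bp coordinates do not matter", {
  set.seed(7)
  ords <- sort(sample.int(60, 12) - 1)
  a1 <- make_annotation(60, labelled = list(ords), spacing = 1000)
  a2 <- make_annotation(60, labelled = list(ords), spacing = 12345,
                        gene_len = 3000)
  s1 <- family_spec(a1, "FAM", gap_threshold = 4)
  s2 <- family_spec(a2, "FAM", gap_threshold = 4)
  expect_equal(member_ordinal_sets(a1, detect_clusters(a1, s1)),
               member_ordinal_sets(a2, detect_clusters(a2, s2)))
})

test_that("clusters never span a chromosome junction", {
  # the same ordinals on one chromosome form a cluster; split across two
  # chromosomes at the junction they must not
  one <- make_annotation(20, labelled = list(c(8, 9, 10, 11)))
  spec <- family_spec(one, "FAM", gap_threshold = 2)
  expect_equal(nrow(detect_clusters(one, spec)), 1)
  two <- make_annotation(c(10, 10), labelled = list(c(8, 9), c(0, 1)))
  spec2 <- family_spec(two, "FAM", gap_threshold = 2)
  expect_equal(nrow(detect_clusters(two, spec2)), 0)
})

test_that("raising the gap threshold never declusters genes", {
  set.seed(11)
  for (rep in 1:10) {
    ann <- random_family_annotation(150, 20)
    counts <- vapply(1:12, function(thr) {
      spec <- family_spec(ann, "FAM", gap_threshold = thr)
      sum(detect_clusters(ann, spec)$n_members)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("mean-gap mode accepts runs the max-gap rule rejects", {
  # gaps 0,0,9: mean 3 < 5 but the last pair exceeds a max-gap bound of 5
  ann <- make_annotation(60, labelled = list(c(10, 11, 12, 22)))
  spec_mean <- family_spec(ann, "FAM", mode = "mean_gap")
  spec_mean$mean_gap_bound <- 5
  spec_max <- family_spec(ann, "FAM", gap_threshold = 5)
  got_mean <- member_ordinal_sets(ann, detect_clusters(ann, spec_mean))
  got_max <- member_ordinal_sets(ann, detect_clusters(ann, spec_max))
  expect_equal(got_mean, list(c(10, 11, 12, 22)))
  expect_equal(got_max, list(c(10, 11, 12)))
  # every reported mean-gap run satisfies its defining bound
  gaps <- diff(got_mean[[1]]) - 1
  expect_lt(mean(gaps), 5)
})

test_that("secretome rule: adjacency triples, single interruptions, and
           rejected alternating patterns", {
  # S S S -> one cluster of 3, no interruption
  a <- make_annotation(10, labelled = list(c(3, 4, 5)), label = "SECRETED")
  cl <- detect_secretome_clusters(a)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 3)
  expect_equal(cl$n_interruptions, 0L)

  # S S N S S -> one cluster, 4 secreted members, 1 interruption
  b <- make_annotation(10, labelled = list(c(2, 3, 5, 6)),
                       label = "SECRETED")
  cl_b <- detect_secretome_clusters(b)
  expect_equal(nrow(cl_b), 1)
  expect_equal(cl_b$n_members, 4)
  expect_equal(cl_b$n_interruptions, 1L)
  expect_equal(member_ordinal_sets(b, cl_b)[[1]], c(2, 3, 5, 6))

  # S N S N S -> no cluster (two interruptions, no adjacent triple)
  c_ <- make_annotation(10, labelled = list(c(2, 4, 6)), label = "SECRETED")
  expect_equal(nrow(detect_secretome_clusters(c_)), 0)

  # S N S S -> merged group of 4 with one interruption
  d <- make_annotation(10, labelled = list(c(2, 4, 5, 6)),
                       label = "SECRETED")
  cl_d <- detect_secretome_clusters(d)
  expect_equal(cl_d$n_members, 4)
  expect_equal(cl_d$n_interruptions, 1L)

  # S N S: too small under either reading
  e <- make_annotation(10, labelled = list(c(2, 4)), label = "SECRETED")
  expect_equal(nrow(detect_secretome_clusters(e)), 0)
})

test_that("clustered fraction is the member share, in percent", {
  ann <- make_annotation(40, labelled = list(c(1, 2, 3)))
  spec <- family_spec(ann, "FAM", gap_threshold = 2)
  expect_equal(clustered_fraction(ann, spec), 100)
  ann2 <- make_annotation(40, labelled = list(c(1, 2, 3, 20, 30, 39)))
  spec2 <- family_spec(ann2, "FAM", gap_threshold = 2)
  expect_equal(clustered_fraction(ann2, spec2), 50)
})

test_that("permutation test is deterministic and maximal packing gives the
           smallest attainable p", {
  set.seed(5)
  ann <- make_annotation(300, labelled = list(100:109))
  spec <- family_spec(ann, "FAM", gap_threshold = 3)
  r1 <- permutation_test(ann, spec, n_perm = 199, seed = 42)
  r2 <- permutation_test(ann, spec, n_perm = 199, seed = 42)
  expect_equal(r1$null_fractions, r2$null_fractions)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$observed_clustered_fraction, 100)
  expect_equal(r1$p_value, 1 / 200)
  expect_error(permutation_test(ann, spec, n_perm = 50), "at least 99")
})
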