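# Telomere tracts, GC disparity curves, AT-rich segments, positional
# classes and non-terminal GC controls.

test_that("a planted 3' telomere array is recovered with exact copy number", {
  set.seed(21)
  s <- plant_telomere(random_dna(10000), "three_prime", 17)
  tr <- find_telomere_tracts(s)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$terminus, "three_prime")
  expect_equal(tr$n_copies, 17)
  expect_equal(tr$end - tr$start, 102)  # 17 x 6 nt
  expect_equal(tr$orientation, "forward")
  expect_equal(tr$end, 10000)
})

test_that("a 5' terminus carries the reverse-complement unit", {
  set.seed(22)
  s <- plant_telomere(random_dna(10000), "five_prime", 5)
  tr <- find_telomere_tracts(s)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$terminus, "five_prime")
  expect_equal(tr$n_copies, 5)
  expect_equal(tr$orientation, "revcomp")
  expect_equal(tr$start, 0)
})

test_that("tracts below min_copies or too far from the terminus are not
           reported", {
  set.seed(23)
  s <- plant_telomere(random_dna(10000), "three_prime", 3)
  expect_equal(nrow(find_telomere_tracts(s)), 0)
  # a clean array buried 2 kb inside the chromosome is not terminal
  s2 <- random_dna(10000)
  substr(s2, 7000, 7000 + 6 * 10 - 1) <- strrep("TTAGGG", 10)
  expect_equal(nrow(find_telomere_tracts(s2, max_offset = 1000)), 0)
  expect_error(find_telomere_tracts(make_annotation(5)), "no sequences")
})

test_that("reverse-complementing a chromosome swaps the termini
           symmetrically", {
  set.seed(24)
  s <- plant_telomere(plant_telomere(random_dna(20000), "three_prime", 9),
                      "five_prime", 12)
  tr <- find_telomere_tracts(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  tr_rc <- find_telomere_tracts(rc)
  expect_setequal(tr$n_copies, tr_rc$n_copies)
  expect_equal(tr$n_copies[tr$terminus == "five_prime"],
               tr_rc$n_copies[tr_rc$terminus == "three_prime"])
})

test_that("disparity curve steps +1 on A/T and -1 on G/C", {
  expect_equal(gc_disparity_curve("ATAT"), c(1, 2, 3, 4))
  expect_equal(gc_disparity_curve("GCGC"), c(-1, -2, -3, -4))
  expect_equal(gc_disparity_curve("ANG"), c(1, 1, 0))
  expect_error(gc_disparity_curve("AXG"), "non-IUPAC")
  expect_error(gc_disparity_curve(""), "non-empty")
})

test_that("GC of any slice recovered from the curve equals base counting", {
  set.seed(31)
  s <- random_dna(5000, gc = 0.6)
  curve <- gc_disparity_curve(s)
  chars <- strsplit(s, "")[[1]]
  for (rep in 1:200) {
    i <- sample(0:4998, 1)
    j <- sample((i + 1):4999, 1)
    direct <- mean(chars[(i + 1):j] %in% c("G", "C"))
    expect_equal(gc_from_curve(curve, i, j), direct)
  }
})

test_that("a planted pure-AT tract in GC-balanced flanks is found exactly", {
  set.seed(41)
  s <- paste0(random_dna(3000, gc = 0.5), strrep("AT", 1000),
              random_dna(3000, gc = 0.5))
  seg <- find_at_rich_segments(s, min_length = 1000)
  expect_gte(nrow(seg), 1)
  main <- seg[which.max(seg$length), ]
  # flanks can contribute a few chance AT bases at the boundary
  expect_lte(abs(main$start - 3000), 50)
  expect_lte(abs(main$end - 5000), 50)
  expect_gte(main$at_fraction, 0.97)
})

test_that("planted 1500 bp tracts at 85% AT are recovered within tolerance", {
  set.seed(42)
  for (rep in 1:10) {
    left <- random_dna(4000, gc = 0.5)
    tract <- exact_at_dna(1500, 0.85)
    right <- random_dna(4000, gc = 0.5)
    seg <- find_at_rich_segments(paste0(left, tract, right),
                                 min_length = 1000)
    expect_equal(nrow(seg), 1)
    # boundaries sit at the optimum of the scoring walk, which wanders a
    # little inside a tract this close to the threshold
    expect_lte(abs(seg$start - 4000), 150)
    expect_lte(abs(seg$end - 5500), 150)
    expect_gte(seg$length, 0.85 * 1500)
    expect_lte(abs(seg$at_fraction - 0.85), 0.03)
  }
})

test_that("reported AT segments pass their own defining threshold when
           recounted directly", {
  set.seed(43)
  for (rep in 1:20) {
    s <- paste0(random_dna(2000, gc = 0.45),
                random_dna(sample(800:2000, 1), gc = sample(c(.1, .2), 1)),
                random_dna(2000, gc = 0.45))
    seg <- find_at_rich_segments(s, at_threshold = 0.8, min_length = 500)
    if (!nrow(seg)) next
    chars <- strsplit(s, "")[[1]]
    for (k in seq_len(nrow(seg))) {
      at <- mean(chars[(seg$start[k] + 1):seg$end[k]] %in% c("A", "T"))
      expect_gt(at, 0.8)
      expect_equal(at, seg$at_fraction[k])
    }
    # segments are disjoint and ordered
    if (nrow(seg) > 1)
      expect_true(all(seg$start[-1] >= head(seg$end, -1)))
  }
})

test_that("maximal AT segments equal the brute-force extraction oracle", {
  set.seed(44)
  theta <- 0.8
  for (rep in 1:25) {
    n <- sample(500:2000, 1)
    s <- random_dna(n, gc = sample(c(0.35, 0.5, 0.65), 1))
    codes <- strsplit(s, "")[[1]] %in% c("A", "T")
    # exact integer scores, as the detector itself uses
    t_int <- round(10000 * theta)
    scores <- ifelse(codes, 10000 - t_int, -t_int)
    got <- chromarch:::.maximal_scoring_subsequences(scores)
    want <- oracle_max_segments(scores)
    expect_equal(nrow(got), nrow(want))
    got <- got[order(got[, "start"]), , drop = FALSE]
    expect_equal(unname(got[, "start"]), want$start)
    expect_equal(unname(got[, "end"]), want$end)
    expect_equal(unname(got[, "score"]), want$score)
  }
})

test_that("positional classes follow the distance bands and partition the
           genes", {
  cfg <- positional_class_config()
  # 10 kb from the 3' end of a 3 Mb chromosome
  expect_equal(classify_position(3e6 - 11000, 3e6 - 10000, 3e6, cfg), "CEC")
  expect_equal(classify_position(100000, 101000, 3e6, cfg), "NCEC")
  expect_equal(classify_position(1.5e6, 1.501e6, 5e6, cfg), "MCC")
  # gap zone (50-65 kb) defaults to NCEC so the classes partition
  expect_equal(classify_position(55000, 56000, 3e6, cfg), "NCEC")
  expect_equal(
    classify_position(55000, 56000, 3e6,
                      positional_class_config(gap_policy = "MCC")), "MCC")
  expect_error(classify_position(-1, 100, 1000, cfg), "outside")
  expect_error(positional_class_config(cec_max = 70000), "require")

  sim <- simulate_genome(synthetic_genome_config(seed = 9))
  cls <- classify_genes(sim$annotation)
  expect_equal(sum(table(cls$class)), n_genes(sim$annotation))
  expect_true(all(cls$class %in% c("CEC", "NCEC", "MCC")))
})

test_that("non-terminal GC sampling is seed-reproducible and recovers the
           generator GC", {
  sim <- simulate_genome(synthetic_genome_config(seed = 12))
  a <- sample_region_gc(sim$annotation, n_regions = 60, seed = 99)
  b <- sample_region_gc(sim$annotation, n_regions = 60, seed = 99)
  expect_equal(a$regions, b$regions)
  expect_lte(abs(a$mean_gc - 51.5), 1)
  expect_equal(a$fraction_at_above_threshold, 0)
  expect_error(sample_region_gc(make_annotation(5)), "no sequences")
})

test_that("a pure-AT genome saturates the AT statistics", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
                      end = 2000, strand = "+")
  seqs <- c(chr1 = paste(rep(c("A", "T"), 60000)[1:120000], collapse = ""))
  ann <- genome_annotation(genes, c(chr1 = 120000), sequences = seqs)
  st <- sample_region_gc(ann, n_regions = 10, region_length = 5000,
                         exclude_terminal = 10000, seed = 3)
  expect_equal(st$fraction_at_above_threshold, 1)
  expect_equal(st$fraction_with_at_segment, 1)
  expect_equal(st$mean_gc, 0)
})
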