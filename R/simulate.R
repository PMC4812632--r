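## Synthetic genomes with planted ground truth: multi-chromosome sequences
## with telomere repeats and AT-rich terminal tracts, gene annotations with
## planted family clusters, expression matrices with a chromosome-end basal
## deficit and planted induction, and histone-mark tables.

#' Default family definitions for the synthetic genome
#'
#' Family sizes follow realistic genome proportions (e.g. carbohydrate-active
#' enzymes at ~2.5% of genes); each definition states how many clusters are
#' planted, their size, and the number of intervening non-family genes
#' between consecutive members.
#'
#' @return list of family definitions (`label`, `n_members`,
#'   `n_planted_clusters`, `cluster_size`, `planted_gap`).
#' @export
default_family_defs <- function() {
  list(
    list(label = "CAZYME",   n_members = 24, n_planted_clusters = 3,
         cluster_size = 4, planted_gap = 2),
    list(label = "SECRETED", n_members = 60, n_planted_clusters = 4,
         cluster_size = 4, planted_gap = 0),
    list(label = "SSCP",     n_members = 16, n_planted_clusters = 2,
         cluster_size = 3, planted_gap = 0),
    list(label = "KOG:A",    n_members = 36, n_planted_clusters = 2,
         cluster_size = 4, planted_gap = 3),
    list(label = "KOG:J",    n_members = 34, n_planted_clusters = 2,
         cluster_size = 3, planted_gap = 3),
    list(label = "PROTEASE", n_members = 20, n_planted_clusters = 1,
         cluster_size = 3, planted_gap = 1),
    list(label = "ORPHAN",   n_members = 30, n_planted_clusters = 0,
         cluster_size = 0, planted_gap = 0))
}

#' Default telomere layout
#'
#' Mirrors a typical assembly where only some chromosome ends retain their
#' telomere: two chromosomes carry tracts on both termini, two on a single
#' terminus (one of them a short N = 5 tract), and three carry none.
#'
#' @return data.frame: `chrom`, `terminus`, `n_copies`.
#' @export
default_telomere_spec <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr3", "chr4", "chr5", "chr5"),
    terminus = c("five_prime", "three_prime", "five_prime", "three_prime",
                 "five_prime", "three_prime"),
    n_copies = c(16L, 17L, 5L, 14L, 15L, 16L))
}

#' Default AT-rich terminal tract layout
#'
#' Tracts of 1-2.8 kb at ~86% AT: both termini of four chromosomes, one
#' terminus each of three others (absent from the remaining ends).
#'
#' @return data.frame: `chrom`, `terminus`, `length`, `at_fraction`.
#' @export
default_at_tract_spec <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr4", "chr4", "chr5",
              "chr5", "chr3", "chr6", "chr7"),
    terminus = c("five_prime", "three_prime", "five_prime", "three_prime",
                 "five_prime", "three_prime", "five_prime", "three_prime",
                 "three_prime", "five_prime", "five_prime"),
    length = c(2800L, 2200L, 1800L, 2500L, 1200L, 2000L, 1500L, 2600L,
               1000L, 1400L, 2400L),
    at_fraction = 0.86)
}

#' Default expression generation parameters
#'
#' Basal expression is log-normal; positional classes scale it (chromosome
#' ends silenced two orders of magnitude below the chromosome middle, the
#' near-end band intermediate). Induced genes are multiplied by a fold drawn
#' from `induction_fold_range`; non-induced genes fluctuate within
#' `noise_range` (always below the twofold call threshold).
#'
#' @return list of expression parameters.
#' @export
default_expression_spec <- function() {
  list(basal_meanlog = log(100), basal_sdlog = 1,
       class_basal_factor = c(CEC = 0.01, NCEC = 0.3, MCC = 1),
       induction_fold_range = c(3, 30),
       noise_range = c(0.75, 1.3),
       induced_fraction = c(cellulose = 0.5, lactose = 0.4,
                            sophorose = 0.3),
       induced_labels = c("CAZYME", "SECRETED"),
       conidiation_fraction = 0.8,
       conidiation_labels = c("SSCP", "SECRETED"),
       confrontation_fraction = 0.05,
       confrontation_labels = c("SSCP", "SECRETED"),
       conditions = c("glucose", "glycerol", "lactose", "cellulose",
                      "sophorose", "conidiation", "confrontation"))
}

#' Default histone-mark generation parameters
#'
#' The silencing mark H3K9me3 is enriched in the terminal class (8% of CEC
#' genes vs 1% elsewhere); the active marks H3K4me2/me3 show the opposite
#' bias.
#'
#' @return list of per-class Bernoulli rates.
#' @export
default_mark_spec <- function() {
  list(h3k9_rate_cec = 0.08, h3k9_rate_other = 0.01,
       h3k4me2_rate_cec = 0.10, h3k4me2_rate_other = 0.45,
       h3k4me3_rate_cec = 0.08, h3k4me3_rate_other = 0.40)
}

#' Configuration of the synthetic genome generator
#'
#' Defaults encode the study conditions the generator emulates: seven
#' chromosomes spanning the 2.8-6.9 Mb size range scaled down tenfold for
#' fast tests, gene density 0.28 genes/kb, background GC 51.5%, telomere
#' unit TTAGGG, terminal AT-rich tracts of 1-2.8 kb, a hundredfold basal
#' expression deficit at chromosome ends, and H3K9me3 at 8% of terminal vs
#' 1% of other genes.
#'
#' @param seed integer seed; every output is reproducible from it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param gene_density genes per kb.
#' @param background_gc genome background GC fraction.
#' @param gene_length_range uniform gene length range (bp).
#' @param family_defs see [default_family_defs()].
#' @param telomere_spec see [default_telomere_spec()].
#' @param telomere_unit repeat unit planted at termini.
#' @param at_tract_spec see [default_at_tract_spec()].
#' @param expression_spec see [default_expression_spec()].
#' @param mark_spec see [default_mark_spec()].
#' @param class_config the [positional_class_config()] used for planted
#'   class-dependent effects.
#' @return An object of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(
    seed = 1L,
    chrom_lengths = c(chr1 = 690000, chr2 = 620000, chr3 = 560000,
                      chr4 = 500000, chr5 = 440000, chr6 = 350000,
                      chr7 = 280000),
    gene_density = 0.28,
    background_gc = 0.515,
    gene_length_range = c(500, 3000),
    family_defs = default_family_defs(),
    telomere_spec = default_telomere_spec(),
    telomere_unit = "TTAGGG",
    at_tract_spec = default_at_tract_spec(),
    expression_spec = default_expression_spec(),
    mark_spec = default_mark_spec(),
    class_config = positional_class_config()) {
  stopifnot(all(chrom_lengths > 0), gene_density > 0,
            background_gc > 0, background_gc < 1,
            length(gene_length_range) == 2,
            gene_length_range[1] < gene_length_range[2])
  # terminal-feature specs are restricted to the configured chromosomes so
  # the default layouts also serve scaled-down genomes
  telomere_spec <-
    telomere_spec[telomere_spec$chrom %in% names(chrom_lengths), ,
                  drop = FALSE]
  at_tract_spec <-
    at_tract_spec[at_tract_spec$chrom %in% names(chrom_lengths), ,
                  drop = FALSE]
  rates <- unlist(mark_spec)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 gene_density = gene_density, background_gc = background_gc,
                 gene_length_range = gene_length_range,
                 family_defs = family_defs, telomere_spec = telomere_spec,
                 telomere_unit = telomere_unit,
                 at_tract_spec = at_tract_spec,
                 expression_spec = expression_spec, mark_spec = mark_spec,
                 class_config = class_config),
            class = "synthetic_genome_config")
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with ground truth
#'
#' Draws chromosome sequences at the background GC, overwrites telomere
#' tandem arrays and AT-rich tracts at the configured termini, places
#' non-overlapping genes with exponential spacing matching the target
#' density, plants labeled family clusters at the configured gaps (remaining
#' members scattered uniformly), and generates expression and histone-mark
#' tables with class-dependent planted effects. Everything is reproducible
#' from the config seed.
#'
#' @param config a [synthetic_genome_config()].
#' @return An object of class `synthetic_genome`: list with `annotation`
#'   (a [genome_annotation] with sequences), `expression` (an
#'   [expression_table]), `marks` (data.frame `gene_id`, `mark`), `manifest`
#'   (ground truth: planted clusters, telomeres, AT tracts, class of every
#'   gene, induced gene sets, mark rates) and `config`.
#' @export
simulate_genome <- function(config = synthetic_genome_config()) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(config$seed)

  unit <- toupper(config$telomere_unit)
  unit5 <- revcomp_unit(unit)
  u <- nchar(unit)

  ## --- sequences with planted terminal features ---------------------------
  seqs <- character(0)
  telo_rows <- list()
  at_rows <- list()
  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    x <- sample_bases(L, config$background_gc)
    telo_len <- c(five_prime = 0L, three_prime = 0L)
    ts <- config$telomere_spec
    ts <- ts[ts$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ts))) {
      n_copies <- ts$n_copies[i]
      tl <- n_copies * u
      if (ts$terminus[i] == "five_prime") {
        x[seq_len(tl)] <- strsplit(strrep(unit5, n_copies), "")[[1]]
        # break any chance inward extension of the array
        x[tl + 1L] <- "G"
        telo_rows[[length(telo_rows) + 1L]] <-
          data.frame(chrom = ch, terminus = "five_prime", unit = unit,
                     n_copies = n_copies, start = 0, end = tl,
                     orientation = "revcomp")
      } else {
        x[(L - tl + 1L):L] <- strsplit(strrep(unit, n_copies), "")[[1]]
        x[L - tl] <- "C"
        telo_rows[[length(telo_rows) + 1L]] <-
          data.frame(chrom = ch, terminus = "three_prime", unit = unit,
                     n_copies = n_copies, start = L - tl, end = L,
                     orientation = "forward")
      }
      telo_len[ts$terminus[i]] <- tl
    }
    at <- config$at_tract_spec
    at <- at[at$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(at))) {
      len <- at$length[i]
      af <- at$at_fraction[i]
      if (at$terminus[i] == "five_prime") {
        s0 <- telo_len[["five_prime"]] + 150L
      } else {
        s0 <- L - telo_len[["three_prime"]] - 150L - len
      }
      x[(s0 + 1L):(s0 + len)] <-
        sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c(af / 2, af / 2, (1 - af) / 2, (1 - af) / 2))
      at_rows[[length(at_rows) + 1L]] <-
        data.frame(chrom = ch, terminus = at$terminus[i], start = s0,
                   end = s0 + len, at_fraction = af)
    }
    seqs[ch] <- paste(x, collapse = "")
  }

  ## --- gene placement -----------------------------------------------------
  spacing <- 1000 / config$gene_density            # bp between gene starts
  mean_len <- mean(config$gene_length_range)
  mean_gap <- max(50, spacing - mean_len)
  margin <- 3000                                   # keep off the termini
  gene_rows <- list()
  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    pos <- margin
    starts <- numeric(0); ends <- numeric(0)
    repeat {
      gap <- rexp(1, rate = 1 / mean_gap)
      len <- round(runif(1, config$gene_length_range[1],
                         config$gene_length_range[2]))
      s <- round(pos + gap)
      if (s + len > L - margin) break
      starts <- c(starts, s); ends <- c(ends, s + len)
      pos <- s + len
    }
    if (length(starts))
      gene_rows[[ch]] <- data.frame(chrom = ch, start = starts, end = ends)
  }
  genes <- do.call(rbind, gene_rows)
  genes$gene_id <- sprintf("%s_g%04d", genes$chrom,
                           unlist(lapply(gene_rows, function(d)
                             seq_len(nrow(d)))))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  rownames(genes) <- NULL

  ## --- family labels with planted clusters --------------------------------
  n_per_chrom <- vapply(split(genes$chrom, genes$chrom), length, numeric(1))
  chrom_of <- genes$chrom
  # within-chromosome ordinal (genes are generated in order)
  ordinal_of <- unlist(lapply(gene_rows, function(d) seq_len(nrow(d)) - 1L),
                       use.names = FALSE)
  labels <- list()
  planted_clusters <- list()
  for (fd in config$family_defs) {
    total_planted <- fd$n_planted_clusters * fd$cluster_size
    if (total_planted > fd$n_members)
      stop("family ", fd$label, ": more planted genes than members")
    taken <- logical(nrow(genes))  # taken by this family
    for (k in seq_len(fd$n_planted_clusters)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        ch <- sample(names(n_per_chrom), 1,
                     prob = n_per_chrom / sum(n_per_chrom))
        span <- (fd$cluster_size - 1) * (fd$planted_gap + 1)
        if (n_per_chrom[[ch]] <= span) next
        anchor <- sample.int(n_per_chrom[[ch]] - span, 1) - 1L
        ords <- anchor + (0:(fd$cluster_size - 1)) * (fd$planted_gap + 1)
        idx <- which(chrom_of == ch)[match(ords, ordinal_of[chrom_of == ch])]
        if (any(taken[idx])) next
        taken[idx] <- TRUE
        planted_clusters[[length(planted_clusters) + 1L]] <-
          list(family = fd$label, chrom = ch,
               member_ids = genes$gene_id[idx])
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted cluster for ", fd$label)
    }
    n_rest <- fd$n_members - total_planted
    free <- which(!taken)
    scatter <- sample(free, n_rest)
    taken[scatter] <- TRUE
    labels[[fd$label]] <- data.frame(gene_id = genes$gene_id[taken],
                                     label = fd$label)
  }
  label_table <- do.call(rbind, labels)
  rownames(label_table) <- NULL

  ann <- genome_annotation(genes[c("gene_id", "chrom", "start", "end",
                                   "strand")],
                           config$chrom_lengths, sequences = seqs,
                           labels = label_table)

  ## --- positional class of every gene -------------------------------------
  cls <- classify_genes(ann, config$class_config)
  class_of <- stats::setNames(cls$class, cls$gene_id)

  ## --- expression ----------------------------------------------------------
  es <- config$expression_spec
  ids <- ann$genes$gene_id
  n <- length(ids)
  basal0 <- rlnorm(n, meanlog = es$basal_meanlog, sdlog = es$basal_sdlog)
  names(basal0) <- ids
  cf <- es$class_basal_factor[class_of[ids]]
  basal <- basal0 * cf

  label_pool <- function(lbls) {
    pool <- unique(ann$labels$gene_id[ann$labels$label %in% lbls])
    pool[order(match(pool, ids))]
  }
  induced <- list()
  for (cond in names(es$induced_fraction)) {
    pool <- label_pool(es$induced_labels)
    induced[[cond]] <- sort(sample(pool,
                                   round(es$induced_fraction[[cond]] *
                                           length(pool))))
  }
  pool_con <- label_pool(es$conidiation_labels)
  induced[["conidiation"]] <- sort(sample(pool_con,
                                          round(es$conidiation_fraction *
                                                  length(pool_con))))
  pool_cf <- label_pool(es$confrontation_labels)
  induced[["confrontation"]] <- sort(sample(pool_cf,
                                            max(1, round(
                                              es$confrontation_fraction *
                                                length(pool_cf)))))

  vals <- matrix(NA_real_, n, length(es$conditions),
                 dimnames = list(ids, es$conditions))
  vals[, "glucose"] <- basal
  for (cond in setdiff(es$conditions, "glucose")) {
    v <- basal * runif(n, es$noise_range[1], es$noise_range[2])
    ind <- induced[[cond]]
    if (!is.null(ind) && length(ind)) {
      fold <- runif(length(ind), es$induction_fold_range[1],
                    es$induction_fold_range[2])
      # induced level is position-independent: the silenced classes reach
      # the same induced level, hence show the largest fold
      v[ind] <- basal0[ind] * fold
    }
    vals[, cond] <- v
  }
  expr <- expression_table(vals, value_kind = "rpkm")

  ## --- histone marks --------------------------------------------------------
  ms <- config$mark_spec
  is_cec <- class_of[ids] == "CEC"
  draw <- function(rate_cec, rate_other)
    rbinom(n, 1, ifelse(is_cec, rate_cec, rate_other)) == 1
  mk <- rbind(
    data.frame(gene_id = ids[draw(ms$h3k9_rate_cec, ms$h3k9_rate_other)],
               mark = "H3K9me3"),
    data.frame(gene_id = ids[draw(ms$h3k4me2_rate_cec,
                                  ms$h3k4me2_rate_other)],
               mark = "H3K4me2"),
    data.frame(gene_id = ids[draw(ms$h3k4me3_rate_cec,
                                  ms$h3k4me3_rate_other)],
               mark = "H3K4me3"))
  rownames(mk) <- NULL

  manifest <- list(
    seed = config$seed,
    n_genes = n,
    planted_clusters = planted_clusters,
    telomeres = do.call(rbind, telo_rows),
    at_tracts = do.call(rbind, at_rows),
    class_of_gene = as.list(class_of),
    induced_genes = induced,
    mark_rates = ms,
    class_basal_factor = as.list(es$class_basal_factor))

  sim <- structure(list(annotation = ann, expression = expr, marks = mk,
                        manifest = manifest, config = config),
                   class = "synthetic_genome")
  validate_manifest(sim)
  sim
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_genome (seed %d): %d genes, %d chromosomes, %d planted ",
    "clusters,\n  %d telomere tracts, %d AT-rich tracts\n"),
    x$config$seed, n_genes(x$annotation),
    length(x$config$chrom_lengths),
    length(x$manifest$planted_clusters),
    NROW(x$manifest$telomeres), NROW(x$manifest$at_tracts)))
  invisible(x)
}

# internal consistency of the manifest against the emitted objects
validate_manifest <- function(sim) {
  ann <- sim$annotation
  m <- sim$manifest
  for (pc in m$planted_clusters) {
    lbls <- ann$labels$gene_id[ann$labels$label == pc$family]
    if (!all(pc$member_ids %in% lbls))
      stop("manifest inconsistency: planted cluster members lack the ",
           pc$family, " label")
  }
  for (cond in names(m$induced_genes)) {
    if (!all(m$induced_genes[[cond]] %in% sim$expression$genes))
      stop("manifest inconsistency: induced genes absent from expression")
  }
  if (!setequal(names(m$class_of_gene), ann$genes$gene_id))
    stop("manifest inconsistency: class map does not cover the genes")
  invisible(TRUE)
}

#' Write a synthetic genome to files
#'
#' Emits `genome.fa` (FASTA), `genes.tsv` and `genes.gff3` (annotation, with
#' labels), `expression.tsv`, `marks.tsv` and `manifest.json`. Outputs are
#' byte-identical for identical simulations.
#'
#' @param sim a [simulate_genome()] result.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- sim$annotation
  paths <- c(fasta = file.path(dir, "genome.fa"),
             tsv = file.path(dir, "genes.tsv"),
             gff3 = file.path(dir, "genes.gff3"),
             expression = file.path(dir, "expression.tsv"),
             marks = file.path(dir, "marks.tsv"),
             manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(ann$sequences, paths["fasta"])
  write_annotation(ann, paths["tsv"])
  write_annotation(ann, paths["gff3"])
  ex <- data.frame(gene_id = sim$expression$genes,
                   sim$expression$values, check.names = FALSE)
  write.table(ex, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$marks[order(sim$marks$gene_id, sim$marks$mark), ],
              paths["marks"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write the miniature demonstration fixture
#'
#' A deterministic small genome (seven ~300 kb chromosomes) exercising every
#' feature class: chromosomes with telomeres on both, one or no termini,
#' AT-rich tracts of 1-2.8 kb, planted family clusters and class-dependent
#' expression/marks. Generated programmatically so the fixture is always in
#' sync with the generator.
#'
#' @param dir output directory.
#' @param seed seed (default 42).
#' @return The written paths, invisibly.
#' @export
write_demo_fixture <- function(dir, seed = 42L) {
  cfg <- synthetic_genome_config(
    seed = seed,
    chrom_lengths = c(chr1 = 320000, chr2 = 310000, chr3 = 300000,
                      chr4 = 300000, chr5 = 295000, chr6 = 290000,
                      chr7 = 280000))
  write_simulation(simulate_genome(cfg), dir)
}
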