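# In-code fixture builders.

# Tiny annotation: genes placed at regular bp spacing on one or more
# chromosomes; `labelled` gives the ordinals (0-based, per chromosome)
# carrying `label`.
make_annotation <- function(n_genes_per_chrom, chrom_length = NULL,
                            labelled = list(), label = "FAM",
                            spacing = 1000, gene_len = 400,
                            sequences = NULL) {
  chroms <- sprintf("chrA%02d", seq_along(n_genes_per_chrom))
  if (is.null(chrom_length))
    chrom_length <- (max(n_genes_per_chrom) + 1) * spacing + 1000
  rows <- list()
  lab_rows <- list()
  for (k in seq_along(chroms)) {
    n <- n_genes_per_chrom[k]
    starts <- (seq_len(n) - 1) * spacing + 100
    ids <- sprintf("%s_g%03d", chroms[k], seq_len(n))
    rows[[k]] <- data.frame(gene_id = ids, chrom = chroms[k],
                            start = starts, end = starts + gene_len,
                            strand = "+")
    lab_ord <- if (k <= length(labelled)) labelled[[k]] else integer()
    if (length(lab_ord))
      lab_rows[[k]] <- data.frame(gene_id = ids[lab_ord + 1], label = label)
  }
  labels <- if (length(lab_rows)) do.call(rbind, lab_rows) else NULL
  lens <- stats::setNames(rep(chrom_length, length(chroms)), chroms)
  genome_annotation(do.call(rbind, rows), lens, sequences = sequences,
                    labels = labels)
}

# A random single-chromosome annotation with m labelled genes out of n.
random_family_annotation <- function(n, m, label = "FAM",
                                     chrom_length = NULL) {
  make_annotation(n, chrom_length = chrom_length,
                  labelled = list(sort(sample.int(n, m) - 1)),
                  label = label)
}

member_ordinal_sets <- function(ann, clusters) {
  lapply(seq_len(nrow(clusters)), function(i) {
    ids <- strsplit(clusters$member_ids[i], ",", fixed = TRUE)[[1]]
    sort(ann$genes$ordinal[match(ids, ann$genes$gene_id)])
  })
}

plant_telomere <- function(seq, terminus, n_copies, unit = "TTAGGG") {
  u <- nchar(unit)
  tl <- n_copies * u
  if (terminus == "three_prime") {
    substr(seq, nchar(seq) - tl + 1, nchar(seq)) <- strrep(unit, n_copies)
    # break chance inward extension so the planted copy number is the truth
    substr(seq, nchar(seq) - tl, nchar(seq) - tl) <- "C"
  } else {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(unit)))
    substr(seq, 1, tl) <- strrep(rc, n_copies)
    substr(seq, tl + 1, tl + 1) <- "G"
  }
  seq
}
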