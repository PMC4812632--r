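## Genome annotation container: the coordinate backbone of every analysis.
## Internal convention throughout the package: 0-based, half-open [start, end),
## i.e. BED-style. GFF3 I/O converts from/to 1-based inclusive.

#' Build a validated genome annotation
#'
#' Constructs the central annotation object from a gene table, chromosome
#' lengths and (optionally) chromosome sequences and a gene-to-category label
#' table. Genes are ordered along each chromosome and assigned 0-based
#' ordinals; all cluster rules operate on these ordinals.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`, `-` or `.`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param sequences optional named character vector or
#'   [Biostrings::DNAStringSet] of chromosome sequences (A/C/G/T/N).
#' @param labels optional data.frame with columns `gene_id`, `label` assigning
#'   genes to functional categories (e.g. `KOG:A`, `CAZYME`, `SECRETED`,
#'   `SSCP`, `PROTEASE`, `ORPHAN`); a gene may carry several labels.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (with `ordinal` column added), `chrom_lengths`, `sequences`
#'   (`DNAStringSet` or `NULL`) and `labels`.
#' @details Ordinals on a chromosome are a permutation of `0..n-1` given by
#'   sorting on start, with ties broken by end and then `gene_id`, so the
#'   assignment is invariant under permutation of the input rows. Strand is
#'   carried but ignored by all cluster and position logic.
#' @export
genome_annotation <- function(genes, chrom_lengths, sequences = NULL,
                              labels = NULL) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes)[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- as.character(genes$strand)

  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  chrom_lengths <- chrom_lengths[order(names(chrom_lengths))]

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  unknown <- setdiff(genes$chrom, names(chrom_lengths))
  if (length(unknown))
    stop("genes on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  bad <- genes$start < 0 | genes$start >= genes$end |
    genes$end > chrom_lengths[genes$chrom]
  if (any(bad))
    stop("malformed coordinates for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")

  if (!is.null(sequences)) {
    if (!inherits(sequences, "DNAStringSet"))
      sequences <- Biostrings::DNAStringSet(sequences)
    if (!setequal(names(sequences), names(chrom_lengths)))
      stop("sequence names do not match chromosome names")
    seq_len_mismatch <-
      Biostrings::width(sequences)[match(names(chrom_lengths),
                                         names(sequences))] != chrom_lengths
    if (any(seq_len_mismatch))
      stop("sequence/length mismatch for: ",
           paste(names(chrom_lengths)[seq_len_mismatch], collapse = ", "))
  }

  # ordinal: 0-based rank by (start, end, gene_id) within chromosome
  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- unlist(lapply(split(seq_len(nrow(genes)), genes$chrom),
                                 function(i) seq_along(i) - 1L),
                          use.names = FALSE)
  rownames(genes) <- NULL

  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!all(c("gene_id", "label") %in% names(labels)))
      stop("label table needs columns gene_id, label")
    labels$gene_id <- as.character(labels$gene_id)
    labels$label <- as.character(labels$label)
    orphan_labels <- setdiff(labels$gene_id, genes$gene_id)
    if (length(orphan_labels))
      stop("labels for unknown gene(s): ",
           paste(orphan_labels, collapse = ", "))
    labels <- unique(labels)
  } else {
    labels <- data.frame(gene_id = character(), label = character())
  }

  structure(list(genes = genes, chrom_lengths = chrom_lengths,
                 sequences = sequences, labels = labels),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosomes (%.2f Mb)%s\n",
              nrow(x$genes), length(x$chrom_lengths),
              sum(x$chrom_lengths) / 1e6,
              if (is.null(x$sequences)) "" else ", with sequence"))
  dens <- vapply(names(x$chrom_lengths), function(ch)
    gene_density(x, ch), numeric(1))
  cat(sprintf("  %s: %.0f kb, %d genes (%.2f genes/kb)\n",
              names(x$chrom_lengths), x$chrom_lengths / 1e3,
              as.integer(table(factor(x$genes$chrom,
                                      names(x$chrom_lengths)))),
              dens), sep = "")
  if (nrow(x$labels)) {
    tab <- sort(table(x$labels$label), decreasing = TRUE)
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total number of genes
#' @param ann a `genome_annotation`.
#' @return Integer count of genes genome-wide.
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Total genome size in bp
#' @param ann a `genome_annotation`.
#' @return Sum of chromosome lengths (bp).
#' @export
genome_size <- function(ann) sum(ann$chrom_lengths)

#' Gene ids carrying a functional label
#' @param ann a `genome_annotation`.
#' @param label a category tag, e.g. `"CAZYME"` or `"KOG:A"`.
#' @return Character vector of gene ids.
#' @export
genes_with_label <- function(ann, label) {
  if (!label %in% ann$labels$label)
    stop("unknown label: ", label)
  unique(ann$labels$gene_id[ann$labels$label == label])
}

#' Chromosome sequence as a character string
#' @param ann a `genome_annotation` with sequences loaded.
#' @param chrom chromosome name.
#' @return Upper-case nucleotide string.
#' @export
chrom_sequence <- function(ann, chrom) {
  if (is.null(ann$sequences))
    stop("no sequences loaded; supply a FASTA to read_annotation()")
  if (!chrom %in% names(ann$sequences)) stop("unknown chromosome: ", chrom)
  toupper(as.character(ann$sequences[[chrom]]))
}

#' Read a genome annotation from GFF3 or TSV, optionally with a FASTA
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; a TSV is expected to carry internal coordinates
#' already, with header columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' and optionally `labels` (semicolon-separated category tags).
#'
#' @param path annotation file; `.gff3`/`.gff` is parsed as GFF3 (features of
#'   type `gene`, id from the `ID` attribute), anything else as TSV.
#' @param fasta optional multi-record FASTA of chromosome sequences; defines
#'   chromosome lengths. Without it, lengths come from GFF3
#'   `##sequence-region` pragmas or, as a fallback, the rightmost gene end.
#' @param labels optional data.frame (`gene_id`, `label`) overriding/adding
#'   category labels.
#' @return A validated [genome_annotation].
#' @export
read_annotation <- function(path, fasta = NULL, labels = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  sequences <- NULL
  if (!is.null(fasta)) {
    if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
    sequences <- Biostrings::readDNAStringSet(fasta)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }

  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    if (is.null(ids)) stop("GFF3 gene features lack ID attributes")
    genes <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,  # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
    sl <- GenomeInfoDb::seqlengths(gr)
    chrom_lengths <- sl[!is.na(sl)]
    if (!length(chrom_lengths)) {
      # lengths from ##sequence-region pragmas (1-based inclusive end)
      pragmas <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (length(pragmas)) {
        parts <- strsplit(trimws(pragmas), "\\s+")
        chrom_lengths <- stats::setNames(
          vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
          vapply(parts, `[`, character(1), 2))
      }
    }
    lab <- S4Vectors::mcols(gr)$labels
    if (!is.null(lab) && is.null(labels)) {
      keep <- !is.na(lab) & nzchar(lab)
      labels <- split_label_column(ids[keep], lab[keep])
    }
  } else {
    genes <- read.delim(path, stringsAsFactors = FALSE)
    required <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(required %in% names(genes)))
      stop("TSV must have header columns ", paste(required, collapse = ", "))
    if ("labels" %in% names(genes) && is.null(labels)) {
      keep <- !is.na(genes$labels) & nzchar(genes$labels)
      labels <- split_label_column(genes$gene_id[keep], genes$labels[keep])
    }
    chrom_lengths <- NULL
  }

  if (!is.null(sequences)) {
    chrom_lengths <- stats::setNames(Biostrings::width(sequences),
                                     names(sequences))
  } else if (is.null(chrom_lengths) || !length(chrom_lengths)) {
    chrom_lengths <- vapply(split(genes$end, genes$chrom), max, numeric(1))
  } else {
    # genes may sit on chromosomes the pragmas missed
    extra <- setdiff(unique(genes$chrom), names(chrom_lengths))
    if (length(extra)) {
      add <- vapply(split(genes$end[genes$chrom %in% extra],
                          genes$chrom[genes$chrom %in% extra]),
                    max, numeric(1))
      chrom_lengths <- c(chrom_lengths, add)
    }
  }
  genome_annotation(genes, chrom_lengths, sequences = sequences,
                    labels = labels)
}

split_label_column <- function(gene_id, labels) {
  parts <- strsplit(as.character(labels), ";", fixed = TRUE)
  data.frame(gene_id = rep(as.character(gene_id), lengths(parts)),
             label = trimws(unlist(parts)))
}

#' Write an annotation to GFF3 or TSV
#'
#' The inverse of [read_annotation()]: GFF3 output is 1-based inclusive with
#' `##sequence-region` pragmas and a `labels` attribute; TSV output keeps the
#' internal 0-based half-open convention.
#'
#' @param ann a `genome_annotation`.
#' @param path destination; `.gff3`/`.gff` selects GFF3, else TSV.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes
  lab <- vapply(g$gene_id, function(id) {
    l <- ann$labels$label[ann$labels$gene_id == id]
    paste(sort(l), collapse = ";")
  }, character(1))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = g$start + 1, end = g$end),
      strand = ifelse(g$strand == ".", "*", g$strand))
    S4Vectors::mcols(gr)$source <- "chromarch"
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- g$gene_id
    S4Vectors::mcols(gr)$labels <- ifelse(nzchar(lab), lab, NA_character_)
    GenomeInfoDb::seqlengths(gr) <-
      ann$chrom_lengths[GenomeInfoDb::seqlevels(gr)]
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = g$start, end = g$end, strand = g$strand,
                      labels = lab)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Gene density of a chromosome
#'
#' Genes per kilobase, the per-chromosome density statistic.
#'
#' @param ann a `genome_annotation`.
#' @param chrom chromosome name.
#' @param digits decimals to round to (default 2, the conventional report
#'   precision); `NULL` returns the exact quotient.
#' @return Genes per kb.
#' @export
gene_density <- function(ann, chrom, digits = 2) {
  if (!chrom %in% names(ann$chrom_lengths))
    stop("unknown chromosome: ", chrom)
  len <- ann$chrom_lengths[[chrom]]
  if (len <= 0) stop("zero-length chromosome: ", chrom)
  d <- sum(ann$genes$chrom == chrom) / (len / 1000)
  if (is.null(digits)) d else round(d, digits)
}

#' Write detected clusters as BED
#'
#' BED6, 0-based half-open, with `name` = family, `score` = number of member
#' genes; rows ordered deterministically by (chrom, start). A header comment
#' line is always written.
#'
#' @param clusters cluster table from [detect_clusters()] or
#'   [detect_secretome_clusters()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (!is.null(clusters) && nrow(clusters)) {
    o <- order(clusters$chrom, clusters$start)
    bed <- data.frame(chrom = clusters$chrom[o],
                      start = format(clusters$start[o], scientific = FALSE,
                                     trim = TRUE),
                      end = format(clusters$end[o], scientific = FALSE,
                                   trim = TRUE),
                      name = clusters$family[o],
                      score = clusters$n_members[o],
                      strand = ".")
    write.table(bed, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a cluster BED written by [write_clusters_bed()]
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `family`,
#'   `n_members`.
#' @export
read_clusters_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), family = character(),
                      n_members = integer()))
  f <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = f[[1]], start = f[[2]], end = f[[3]],
             family = f[[4]], n_members = f[[5]])
}
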