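Package: chromarch
Title: Chromosome Architecture Analysis for Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Density-based detection of functionally related gene clusters on
    assembled chromosomes, characterization of chromosome ends (telomere
    tandem repeats, AT-rich subtelomeric tracts, window-less GC disparity
    curves), positional classification of clusters relative to chromosome
    termini, and integration of gene-level expression and histone-mark data
    to test whether chromosomal position and clustering affect expression.
    Includes a synthetic-genome generator with a ground-truth manifest so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
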