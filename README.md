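# chromarch

Chromosome-architecture analysis for assembled fungal genomes: where do
functionally related genes cluster, what do the chromosome ends look like,
and does position silence expression?

Many filamentous fungi keep part of their gene inventory — carbohydrate-active
enzymes (CAZymes), small secreted cysteine-rich proteins (SSCPs), proteases,
secondary-metabolite enzymes — in loose chromosomal clusters, with a striking
excess near the chromosome ends. The terminal compartment carries telomere
repeats (TTAGGG)<sub>N</sub>, AT-rich tracts of 1–3 kb at 10–18% GC, and
silencing chromatin (H3K9me3); genes there show basal expression orders of
magnitude below the chromosome interior while still reaching full induced
levels, i.e. the largest induction folds. `chromarch` provides the complete
toolchain to quantify this on any genome given a FASTA, an annotation
(GFF3 or TSV) and a table of functional labels, plus optional gene-level
expression matrices and histone-mark calls.

## What it computes

* **Cluster detection.** For a family of *m* genes among *N* ORFs the
  average distribution number is *D = N/m*; a cluster is ≥3 family genes
  with at most ⌊*D*/5⌋ other genes between consecutive members (a fivefold
  density excess; e.g. *D* = 50 → at least three genes within a stretch of
  thirty, *D* ≈ 41 → max gap 8). A mean-gap variant and the stringent
  secretome adjacency rule (≥3 adjacent secreted genes, or ≥4 with exactly
  one interruption) are included. Significance comes from a label-shuffling
  permutation test.
* **Chromosome ends.** Exact telomere tandem-array detection at both
  termini (forward unit at 3′, reverse complement at 5′), window-less GC
  disparity curves, AT-rich segments as linear-time maximal-scoring
  subsequences (score +(1−θ) per A/T, −θ per G/C), and random non-terminal
  GC controls.
* **Positional classes.** CEC (≤50 kb from a terminus), NCEC (65–150 kb),
  MCC (interior), assigned to genes and clusters by nearest envelope edge.
* **Expression & chromatin.** Induction calls (>2-fold over glucose),
  per-class means and induction folds, enrichment tables, H3K9me3/H3K4me2/3
  counts per class, and Welch tests with BH adjustment.
* **Synthetic genomes.** `simulate_genome()` plants all of the above with a
  ground-truth manifest, so the entire pipeline is testable offline.

## Worked example

```r
library(chromarch)
sim <- simulate_genome(synthetic_genome_config(seed = 1))
ann <- sim$annotation

find_telomere_tracts(ann)
#>   chrom    terminus   unit n_copies  start    end orientation
#> 1  chr1  five_prime TTAGGG       16      0     96     revcomp
#> 2  chr1 three_prime TTAGGG       17 689898 690000     forward
#> 3  chr3  five_prime TTAGGG        5      0     30     revcomp
#> 4  chr4 three_prime TTAGGG       14 499916 500000     forward
#> 5  chr5  five_prime TTAGGG       15      0     90     revcomp
#> 6  chr5 three_prime TTAGGG       16 439904 440000     forward
```

Six termini carry tracts (two chromosomes on both ends, including one short
N = 5 array); chr2, chr6 and chr7 have none — the 17-copy array is
17 × 6 = 102 nt long. Cluster detection derives its own thresholds:

```r
spec <- family_spec(ann, "CAZYME")
spec
#> family_spec 'CAZYME': 24 members, D = 39.42, mode = max_gap, gap <= 7, min 3 genes
classify_clusters(detect_clusters(ann, spec), ann)
#>   family chrom first_ordinal last_ordinal n_members positional_class
#> 1 CAZYME  chr1            68           77         4              MCC
#> 2 CAZYME  chr2           162          171         4              CEC
#> 3 CAZYME  chr4           112          121         5             NCEC
permutation_test(ann, spec, n_perm = 999, seed = 1)
#> permutation test 'CAZYME': observed 54.2% clustered, p = 0.002 (999 perms)
```

24 family members give *D* = 960/24 ≈ 39, hence a maximum gap of
⌊39/5⌋ = 7; 13 of the 24 CAZymes (54.2%) sit in three clusters, far more
than label shuffling produces (p = 0.002). Position drives basal expression
and chromatin, not induced levels:

```r
cls <- classify_genes(ann)
group_mean_expression(sim$expression, cls, "glucose")
#>   group condition   n   mean     sd
#> 1   CEC   glucose 205   1.56   1.72
#> 2   MCC   glucose 355 162.04 199.87
#> 3  NCEC   glucose 386  54.77  67.15
induction_ratio(sim$expression, cls, "cellulose", "glucose")
#>   group   n mean_condition mean_reference   fold
#> 1   CEC 205            297           1.56 190.47
#> 2   MCC 355            216         162.04   1.33
#> 3  NCEC 386            264          54.77   4.82
mark_counts_by_class(sim$marks, cls)   # H3K9me3 rows
#>   class    mark n_class n_marked percent
#> 7   CEC H3K9me3     205       16    7.80
#> 8   MCC H3K9me3     355        3    0.85
#> 9  NCEC H3K9me3     386        4    1.04
```

Chromosome-end genes sit ~100× below the interior on glucose (1.56 vs
162.04) yet reach comparable induced levels (297 vs 216), hence the largest
fold (190×), and carry H3K9me3 at 7.8% vs ~1% elsewhere — the silenced-ends
signature the package is built to detect.

`run_full_pipeline(run_config(...))` chains all stages and writes per-stage
TSV/BED files plus a `summary.json`; see the vignette
(`vignettes/chromosome-architecture.Rmd`) for the models, parameter
meanings and design choices.

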