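# tirscope

Translation initiation region (TIR) analysis for bacterial ribosome
profiling, built around organisms whose mRNAs lack Shine–Dalgarno
sequences (the Bacteroidetes being the canonical case). Given per-gene
RNA-seq and ribo-seq count tables, a genome and its annotation, `tirscope`
asks what tunes initiation when SD–anti-SD pairing cannot: upstream
sequence determinants (a bacterial Kozak-like context), local mRNA
secondary structure, promoter architecture, and genome-level avoidance of
decoy AUG triplets near start codons.

It is aimed at computational biologists analysing bulk prokaryotic
profiling data who want the downstream statistics as tested, reusable
functions rather than one-off scripts.

## What it computes

**Average ribosome density (ARD).** Per gene, with replicate-summed
counts normalised to CPM against a representative set (the top third of
genes by RNA-seq density):

```
ARD_g = CPM_ribo(g) / CPM_rna(g)
```

a proxy for initiation rate (translation efficiency). Genes are binned
into octiles of ARD (octile 1 = highest) and every downstream contrast
compares octile 1 with octile 8.

**TIR composition.** Nucleotide frequencies at offsets −30..+30 around
the start codon (offset 0 = first base of the start codon), with
per-position two-sample t-tests on per-gene indicators and Bonferroni
correction over the 61 positions.

**Secondary structure.** Per-position base-pairing probabilities over
−100..+100 windows from an exact McCaskill-style partition function on a
pair-weight energy model (GC = e³, AU = e², GU = e¹, min hairpin 3), with
octile contrasts of the positionwise means.

**Promoter (−7 element) analysis.** Scan of the 50 nt upstream of each
TSS for TANNTTTG-like elements (consensus scan or built-in Gibbs
sampler), spacing histogram, probable-promoter filter (spacing 4–5 nt),
aligned frequency matrix, IUPAC consensus derivation (which revises
TANNTTTG to TAHHTTTG when G is absent at the degenerate positions), and
leader-length statistics.

**AUG underrepresentation.** Counts of AUG vs its composition-matched
permutations (GAU, GUA, AGU) in windows −21..−1 and +4..+24 around the
start codon against midgene controls, one ratio per genome per window,
with one-sample and pairwise t-tests across phyla.

**Synthetic data.** A seeded generator emits genome/GFF3/TSS/count
bundles with planted ground truth (efficiency gradients at −3/−6/−12/−13,
promoter elements, AUG depletion, hairpins) so every stage can be tested
against what was planted.

## Worked example

Simulate a 960-gene bundle with AUG depletion, profile it, and contrast
octile 1 against octile 8:

```r
library(tirscope)

cfg  <- synthetic_config(seed = 42, n_genes = 960, aug_depletion = 0.6)
sim  <- generate_genome(cfg)
cnt  <- generate_counts(cfg, sim$truth)
prof <- expression_profile(cnt$rna, cnt$ribo, sim$genes)
prof
#> expression_profile
#>   960 genes; representative set: 320; 8 groups of 40
#>   genes with undefined ARD (zero RNA): 0

summary(prof)
#> ARD range by octile (1 = highest ARD):
#>  octile  n    ard_min    ard_max
#>       1 40 1.83539367 21.0366397
#>       2 40 1.08601005  1.7241687
#>  ...
#>       8 40 0.01119256  0.1543002
```

Octile ranges are non-overlapping and span ~3 orders of magnitude, as ARD
does in real profiling data. The planted A determinants come back out of
the octile contrast:

```r
w   <- tir_windows(sim$genome,
                   sim$genes[sim$genes$gene_id %in% prof$representative, ])
ctr <- octile_contrast(w[octile_genes(prof, 1)], w[octile_genes(prof, 8)])
ctr[ctr$position %in% c(-13, -12, -6, -3),
    c("position", "freq_a", "freq_b", "p_value", "significant")]
#>  position freq_a freq_b  p_value significant
#>       -13  0.550  0.175 3.62e-04        TRUE
#>       -12  0.575  0.000 9.33e-09        TRUE
#>        -6  0.575  0.100 2.88e-06        TRUE
#>        -3  0.575  0.175 1.47e-04        TRUE
```

`freq_a`/`freq_b` are the A-frequencies in octile 1 and octile 8; all four
planted offsets clear the Bonferroni threshold (0.05/61), and no other
offset does. The depleted AUG ratios land near the planted retention of
0.6 in the TIR windows while midgene controls stay near 1:

```r
genome_ratios(sim$genome, sim$genes, gene_ids = prof$representative,
              genome_id = "synthetic")
#> trinuc_ratios for synthetic ( 320 genes )
#>                    AUG/GAU AUG/GUA AUG/AGU
#> tir_upstream         0.727   0.706   0.649
#> tir_downstream       0.592   0.542   0.464
#> midgene_upstream     0.868   0.829   0.876
#> midgene_downstream   0.928   0.972   0.920
```

End-to-end runs over files work through `run_config()` /
`run_pipeline()`, which write one TSV per stage plus a JSON manifest with
the resolved configuration and per-filter gene accounting.

## Layout

* `R/` — analysis stages: `sequence_io`, `stats_core`, `expression`,
  `tir_composition`, `structure` (+ `src/partition.cpp`), `promoter`,
  `trinucleotide`, `synthetic`, `pipeline`.
* `vignettes/tirscope-methods.Rmd` — the model, parameter and design
  discussion.
* `tests/testthat/` — unit, property and pipeline-scale tests, all on
  generated fixtures.
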