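---
title: "Methods: translation initiation region analysis with tirscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translation initiation region analysis with tirscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirscope)
```

## The scientific problem

Most bacterial mRNAs carry a Shine–Dalgarno (SD) element that base-pairs
with the 3' end of 16S rRNA and positions the start codon in the ribosomal
P site. Entire phyla, however — most prominently the Bacteroidetes — have
mRNAs with no SD sequences at all, yet initiate translation faithfully.
Ribosome profiling (parallel RNA-seq and ribo-seq) of such organisms makes
it possible to ask which mRNA features substitute for the SD: sequence
determinants around the start codon, local mRNA secondary structure, and
genome-level avoidance of decoy start triplets.

`tirscope` implements the downstream computational analysis of such a
profiling experiment as a reusable, tested pipeline, together with a
synthetic-data generator that emits inputs with known ground truth for
every stage. Nothing in the package touches raw reads: alignment and
per-gene counting are upstream concerns, and transcriptional start sites
(TSSs) are consumed as a prediction table, never computed.

## Average ribosome density and octiles

For each gene, RNA-seq fragments measure transcript abundance and ribo-seq
footprints measure ribosome load. After summing replicates, genes are
ranked by RNA-seq counts per nucleotide of coding length, and the top third
forms the *representative set* of highly transcribed genes on which the
downstream analyses run. Counts of both assays are normalised to counts
per million (CPM) where the scale factor comes from the representative set
only — a deliberate, literal reading of the normalisation: the
representative genes define the sequencing-depth scale, and every gene is
expressed on it. The *average ribosome density* is then

$$\mathrm{ARD}_g = \frac{\mathrm{CPM}^{\mathrm{ribo}}_g}{\mathrm{CPM}^{\mathrm{rna}}_g},$$

a quantity that largely reflects translation initiation rate (also called
translation efficiency). Representative genes are ranked by ARD and split
into octiles of `floor(n/8)` genes; octile 1 holds the highest-ARD genes.
When `n` is not divisible by 8 the remainder is dropped from the low-ARD
tail — the rule is inert on set sizes that are exact multiples of eight
(1712, 1440, 1392) but must be defined for arbitrary inputs. Genes with
zero RNA CPM have undefined ARD; they are excluded from octile assignment
and counted in the run manifest. Zero-RNA genes are also excluded from the
representative set itself (they cannot be "highly transcribed"); for a top
third of expressed genes the order of this exclusion relative to the
ranking is immaterial, but we document ours: ranking happens over all
genes, zero-density genes are removed from the selection afterwards.

Relative protein synthesis rates are computed as ribo-seq coverage per
gene length, rescaled to sum to $10^6$ over all genes — a proxy for
relative protein production that is useful for estimating subunit
stoichiometries. Replicate quality is summarised by pairwise Spearman
correlations of per-gene counts.

## Positional nucleotide composition of the TIR

The translation initiation region (TIR) is profiled over offsets −30..+30,
where offset 0 is the first nucleotide of the start codon and offset −1 the
base immediately 5' of it. Windows are extracted from genomic context,
strand-aware, and transcribed T→U; they are *not* clipped at transcript
boundaries (the alternative — clipping at the TSS — would entangle the
composition profile with TSS prediction quality, and the genomic context is
what the initiating ribosome sees in any case). Windows truncated by a
contig edge keep their offset labels; genes carrying an N at a position are
excluded at that position only, not gene-wise, which maximises usable data.

Octile contrasts encode each gene as a 0/1 indicator ("gene has base *b*
at offset *k*") and compare octile 1 against octile 8 with a two-sample
t-test per position — a comparison of two Bernoulli proportions. Welch's
unequal-variance form is the default since the octiles have no reason to
share a variance; a pooled-variance option exists for sensitivity analysis.
P-values are Bonferroni-corrected over the positions tested in the panel
(m = 61 for −30..+30; the correction scope is recorded in the output
attributes since different panel widths change m). A sample that is
entirely constant (an octile with no A at some position) is legitimate
indicator data and is handled by the Welch formula; only two constant
samples with different values — where no finite statistic exists — raise an
error.

## Local mRNA secondary structure

Each gene's window (−100..+100 by default; local folding only) is folded
with an exact partition function over nested secondary structures. The
energy model is deliberately minimal: one Boltzmann weight per pair class,

$$w_{GC} = e^{3}, \quad w_{AU} = e^{2}, \quad w_{GU} = e^{1},$$

with a minimum hairpin loop of 3 unpaired nucleotides, no stacking terms
and no loop entropies. A structure's weight is the product of its pair
weights; the empty structure contributes 1. The inside–outside dynamic
programme computes, exactly to floating precision, the ensemble probability
that each position is paired to anything, in $O(n^3)$ time and $O(n^2)$
space (a 201-nt window folds in tens of milliseconds).

Why this model rather than a full nearest-neighbour thermodynamic model?
The pipeline's claims are about *relative* pairing propensity near start
codons between gene groups, not about absolute free energies — and a model
this simple admits an independent oracle: for short sequences every nested
structure can be enumerated exhaustively and the partition function summed
directly. The test suite verifies the dynamic programme against that
enumeration to $10^{-9}$ relative error over hundreds of seeded sequences;
no such verification is possible for a reimplementation of the full Turner
model. For publication-grade absolute numbers, an external folder's
per-position probabilities can be substituted through
`read_pairing_profiles()` without touching the downstream averaging and
testing code.

Two numerical notes. The computation runs in linear (not log) space;
weights and window lengths of the default configuration keep the partition
function far below double-precision overflow, but pathological inputs
(thousands of nucleotides of pure G/C) would overflow — windows are
expected to stay in the few-hundred-nucleotide range. Second, the wobble
pair breaks reverse-complement symmetry of the pairing profile (G·U maps to
the non-pairing C·A), so that symmetry — which the test suite checks — is
exact only for Watson–Crick-only models (`GU = 0`).

Group summaries average the per-gene pairing probability positionwise over
informative genes and contrast two groups with the same per-position
Welch-test-plus-Bonferroni machinery as the composition stage.

## Promoter (−7 element) analysis

Bacteroidetes promoters carry a distinctive −7 element (classically
TANNTTTG) recognised by the primary sigma factor, located a few nucleotides
upstream of the TSS. Starting from a TSS table, the pipeline extracts the
50 nt immediately 5' of each TSS and searches for candidate elements in two
modes: a degenerate-consensus scan seeded with TANNTTTG (score = number of
agreeing defined positions, default threshold all 6), and a width-8 Gibbs
site sampler for discovery without a seed pattern. One hit per TSS is kept
— the best-scoring site, ties resolved toward the TSS — matching a
one-candidate-per-promoter accounting.

*Spacing* is defined as the number of nucleotides strictly between the
element's 3' base and the TSS; under this convention the biologically
functional class sits at spacing 4–5, and `filter_probable_promoters()`
keeps exactly those hits. The spacing histogram, the positional frequency
matrix over the aligned elements (± flank), and an IUPAC consensus are then
derived. Consensus derivation uses two thresholds: a column is written as a
plain base when its frequency reaches 0.9 (*invariant*), and otherwise as
the minimal IUPAC code covering every base above 0.05 (*absent* threshold)
— so a column where only G is effectively missing becomes H, which is
precisely the logic that revises TANNTTTG to TAHHTTTG when G is virtually
absent at the two degenerate positions. The element coordinate labels
(−12..−5) follow the field's −7-element nomenclature.

The Gibbs sampler is a standard site sampler (one occurrence per sequence,
pseudocount 0.5, pooled background) with one addition that matters in
practice: a periodic phase-shift move that proposes sliding all sites one
position left or right and keeps the shift when it improves the total
log-odds. Without it, roughly half of all restarts converge onto the motif
offset by one — a well-known failure mode of site samplers. The sampler is
bit-reproducible given its mandatory seed; the second motif of the
classical promoter description (the −33 element) is deliberately not
modelled, and upstream AT-rich periodicity is left to the descriptive
frequency matrix.

Leader lengths are computed as the distance from the TSS to the first base
of the start codon (a leaderless transcript has leader 0), with a summary
reporting the mean and the fraction exceeding a threshold (default 10 nt).

## AUG underrepresentation

An organism without SD elements could reduce spurious initiation by
purging AUG triplets from the vicinity of true start codons. The statistic:
count AUG occurrences (overlapping) in four windows per gene — offsets
−21..−1 and +4..+24 around the start codon (the start codon itself, ending
at +2, is never counted), and the 20 nt on each side of the gene midpoint
`m = floor(len/2)` as composition controls — and normalise by the same
counts of GAU, GUA and AGU, the three permutations of AUG with identical
base composition. Counts are summed across genes first and one ratio per
genome per window is formed from the aggregates (per-gene ratios would
divide by zero constantly; a per-gene mode exists behind a flag for
sensitivity analysis). Genes shorter than 43 nt cannot host both midgene
windows and are skipped for the midgene counts only.

Cross-phylum comparison takes one ratio table per genome, groups genomes by
phylum, and tests: per phylum/window/ratio a one-sample t-test against 1,
and per window/ratio a two-sample t-test for every phylum pair, all
Bonferroni-corrected within each ratio family (phyla × windows tests for
the one-sample family; pairs × windows for the pairwise family — the
correction scope is a package decision, recorded in the output, since the
underlying convention is a free choice). A cell is flagged as
"significantly below one" only when the adjusted p-value clears alpha *and*
the median is below one.

## The synthetic-data generator

`generate_genome()` and `generate_counts()` emit a complete input bundle —
genome FASTA, GFF3, TSS table, replicate count tables — whose statistical
structure matches what the analysis assumes, with full ground truth and no
hidden entropy (every draw flows from the config seed; counts use seed + 1
so the two streams are decoupled but jointly reproducible).

Each gene unit consists of an intergenic pad, a planted TAHHTTTG element
(H drawn uniformly from A/C/T), a spacer of 4 or 5 nt (default mixture
70/30), the TSS, a leader, and a CDS that always starts AUG. Defaults and
their reasoning:

* **GC content 0.34** — the AT-rich Bacteroidetes-like background the
  composition analyses expect.
* **Leader length ~ NB(mean 33, size 5)** — mean leader of 33 nt with ~93%
  of leaders above 10 nt, the regime in which most transcripts are
  leadered.
* **True translation efficiency ~ lognormal, sdlog 1.0** — ARD spans
  roughly two orders of magnitude across a transcriptome, and at
  sequencing depth 200 reads/gene with NB dispersion 0.1 this signal-to-
  noise gives Spearman(estimated ARD, truth) ≈ 0.95.
* **Determinant effects 0.5** at offsets −3, −6, −12, −13: the probability
  of A at those offsets is `P(A) = background + effect × (percentile −
  0.5)`, clamped to [0.02, 0.98], so octile-1 genes reach ~0.55 A-frequency
  at −3 against ~0.11 in octile 8 — a strong but not saturated Kozak-like
  gradient.
* **Counts**: RNA-seq mean per gene is depth × (lognormal expression
  level, sdlog 1) × (length / mean length); ribo-seq mean multiplies in the
  true efficiency; replicates are negative binomial with variance
  $\mu + \alpha\mu^2$, $\alpha = 0.1$.
* **AUG depletion** keeps each AUG occurrence in the two TIR windows with
  probability `aug_depletion` and otherwise applies a point mutation: one
  non-determinant base of the triplet is redrawn from the background until
  it changes. Restricting the edit to the TIR windows keeps midgene
  composition neutral, which is exactly the control the statistic relies
  on; the single-base edit (rather than redrawing the whole triplet)
  leaves the matched denominators essentially untouched, so the realised
  TIR AUG/GAU ratio tracks the nominal retention (measured 0.62 ± 0.05 at
  a nominal 0.6 over 12 seeds).
* **Hairpins**: optionally, bottom-octile genes receive a perfect 8-bp GC
  helix with a 4-nt loop at offsets −60..−41 — clear of the determinant
  offsets and recognisable as a contiguous stem in the pairing profile.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: operon structure and overlapping genes, non-AUG start
codons, codon-usage and amino-acid constraints inside CDSs, positional
autocorrelation of real intergenic sequence, alignment and mapping error,
and any coupling between secondary structure and the planted sequence
determinants (in real data the two are confounded; here they are
independent by construction). One known construction artifact: the planted
element's invariant trailing G meets random spacer sequence, so G-A-U
occurs at that boundary at several times the background rate; for
short-leader genes this inflates the GAU denominator in the upstream TIR
window by ~3% and leaves the neutral-genome TIR AUG/GAU mean at ≈0.97
rather than 1.00 — comfortably inside the binomial confidence bands the
tests use, and left as-is rather than patched around.

## Orchestration, sizes and reproducibility

`run_pipeline()` executes the stages in dependency order on file paths or
in-memory objects, writes one TSV per result plus a JSON manifest carrying
the resolved configuration and the gene counts excluded at every filter,
and is bit-reproducible for identical inputs and config. The octile count
is itself a parameter (8 by default), so quartile or decile designs are the
same code path.

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make their statistical checks decisive: paper-scale runs
(5138 genes → representative set 1712 → octiles of 214) for the positional
determinant tests, 500-gene genomes for trinucleotide calibration, 960
genes with 40 folded windows per octile for the structure contrast, and
200-sequence fixtures for promoter recovery. Partition-function exactness
is checked against exhaustive enumeration on sequences up to 14 nt, where
the full structure ensemble is small enough to sum directly.

## Known limitations

* The folding model is relative, not thermodynamic; absolute pairing
  probabilities are not comparable to nearest-neighbour-model outputs.
* Bonferroni is the only multiplicity correction offered, matching the
  analysis it reimplements; no FDR control.
* The trinucleotide statistic aggregates counts per genome; it has no
  per-gene inferential machinery.
* GU wobble pairs break reverse-complement symmetry of pairing profiles;
  this is a property of the biology (C·A does not pair), not a bug, but it
  surprises users who expect strand symmetry.
* Spliced features, multi-contig genes and non-AUG starts are out of
  scope throughout.
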