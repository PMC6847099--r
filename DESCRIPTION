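Package: tirscope
Title: Translation Initiation Region Analysis for Bacteria Lacking
    Shine-Dalgarno Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of bacterial ribosome profiling
    (ribo-seq + RNA-seq) aimed at translation initiation regions (TIRs),
    built around organisms such as the Bacteroidetes whose mRNAs lack
    Shine-Dalgarno elements.  Computes average ribosome density (ARD) per
    gene with octile binning, positional nucleotide-frequency profiles and
    octile contrasts across the TIR, per-position base-pairing
    probabilities from an exact partition function over nested secondary
    structures, Bacteroidetes -7 promoter element discovery with spacing
    filters and IUPAC consensus derivation, and composition-matched AUG
    trinucleotide underrepresentation statistics.  Includes a seeded
    synthetic-data generator that emits genomes, annotations, TSS tables
    and negative-binomial count tables with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
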