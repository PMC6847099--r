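# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# genome from named character vector of DNA strings
make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

make_gene <- function(gene_id, contig, start, end, strand = "+") {
  data.frame(gene_id = gene_id, contig = contig, start = start, end = end,
             strand = strand, length = end - start, stringsAsFactors = FALSE)
}

# a tir_window object directly from an RNA string and its offset range
make_window <- function(seq, from, gene_id = "g", complete = TRUE) {
  structure(list(gene_id = gene_id,
                 offsets = seq.int(from, from + nchar(seq) - 1L),
                 sequence = seq, complete = complete),
            class = "tir_window")
}

# write a minimal GFF3 file from raw lines
write_gff_lines <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# random DNA string with Bacteroidetes-like composition
random_dna <- function(n, gc = 0.34) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# upstream-of-TSS promoter fixture: `n_planted` background sequences of
# length `len` with a TAHHTTTG element planted at the given spacings, plus
# `n_decoys` plain background sequences.  Returns sequences plus the truth.
make_promoter_fixture <- function(n_planted, n_decoys = 0, len = 50,
                                  spacing_probs = c("4" = 0.7, "5" = 0.3),
                                  gc = 0.34) {
  spacings <- as.integer(sample(names(spacing_probs), n_planted,
                                replace = TRUE, prob = spacing_probs))
  elements <- character(n_planted)
  seqs <- character(n_planted + n_decoys)
  for (i in seq_len(n_planted)) {
    s <- strsplit(random_dna(len, gc), "")[[1]]
    el <- c("T", "A", sample(c("A", "C", "T"), 1), sample(c("A", "C", "T"), 1),
            "T", "T", "T", "G")
    start <- len - 7L - spacings[i]
    s[start:(start + 7L)] <- el
    seqs[i] <- paste(s, collapse = "")
    elements[i] <- paste(el, collapse = "")
  }
  for (i in seq_len(n_decoys)) seqs[n_planted + i] <- random_dna(len, gc)
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  list(seqs = seqs,
       truth = data.frame(gene_id = names(seqs)[seq_len(n_planted)],
                          element = elements, spacing = spacings,
                          stringsAsFactors = FALSE))
}
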