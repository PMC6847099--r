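# Format reading, coordinate conversion and strand-aware window extraction.

test_that("read_genome normalises case and alphabet and rejects bad input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT"), f)
  g <- read_genome(f)
  expect_equal(names(g), "c1")
  expect_equal(as.character(g[["c1"]]), "ACGT")

  writeLines(c(">c1", "acgu"), f)
  expect_equal(as.character(read_genome(f)[["c1"]]), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), f)
  expect_error(read_genome(f), "duplicate contig")

  writeLines(c(">c1", "ACXT"), f)
  expect_error(read_genome(f), "illegal characters")

  writeLines(character(0), f)
  expect_error(read_genome(f), "empty")
})

test_that("read_annotations converts GFF3 1-based coordinates to 0-based half-open", {
  f <- write_gff_lines(c(
    "c1\tt\tCDS\t11\t13\t.\t+\t0\tlocus_tag=gA",
    "c1\tt\tCDS\t20\t40\t.\t-\t0\tlocus_tag=gB"))
  ann <- read_annotations(f)
  expect_equal(ann$start[ann$gene_id == "gA"], 10L)
  expect_equal(ann$end[ann$gene_id == "gA"], 13L)
  expect_equal(ann$length[ann$gene_id == "gA"], 3L)
  expect_setequal(ann$gene_id, c("gA", "gB"))
})

test_that("read_annotations rejects missing strand and missing ids", {
  f <- write_gff_lines("c1\tt\tCDS\t11\t13\t.\t.\t0\tlocus_tag=gA")
  expect_error(read_annotations(f), "strand")
  f2 <- write_gff_lines("c1\tt\tCDS\t11\t13\t.\t+\t0\tID=x")
  expect_error(read_annotations(f2), "locus_tag")
})

test_that("annotation coordinates round-trip through GFF3", {
  genes <- rbind(make_gene("gA", "c1", 10, 13, "+"),
                 make_gene("gB", "c1", 19, 40, "-"))
  f <- tempfile(fileext = ".gff3")
  write_annotations(genes, f)
  back <- read_annotations(f)
  back <- back[order(back$gene_id), names(genes)]
  rownames(back) <- NULL
  expect_equal(back, genes)
  # the file itself carries the original 1-based inclusive values
  raw <- grep("CDS", readLines(f), value = TRUE)
  fields <- do.call(rbind, strsplit(raw, "\t"))
  expect_setequal(as.integer(fields[, 4]), c(11L, 20L))
  expect_setequal(as.integer(fields[, 5]), c(13L, 40L))
})

test_that("extract_tir_window anchors offset 0 at the start codon (+ strand)", {
  g <- make_genome(c1 = "AAAAAATGGGG")
  gene <- make_gene("gA", "c1", 5, 11, "+")
  w <- extract_tir_window(g, gene, upstream = 2, downstream = 3)
  expect_equal(w$sequence, "AAAUGG")
  expect_equal(w$offsets, -2:3)
  expect_true(w$complete)
  expect_equal(window_subseq(w, 0, 2), "AUG")
})

test_that("extract_tir_window is strand symmetric and truncates at contig edges", {
  # reverse complement of genomic CAT is AUG
  g <- make_genome(c1 = "GGCCCATTTT")
  gene <- make_gene("gA", "c1", 1, 7, "-")  # CDS sense starts at genomic 6
  w <- extract_tir_window(g, gene, upstream = 2, downstream = 3)
  expect_equal(window_subseq(w, 0, 2), "AUG")
  # truncation: upstream window hits the left contig edge
  g2 <- make_genome(c1 = "AATGCCCCCC")
  gene2 <- make_gene("gB", "c1", 1, 10, "+")
  w2 <- extract_tir_window(g2, gene2, upstream = 30, downstream = 3)
  expect_false(w2$complete)
  expect_lt(length(w2$offsets), 34)
  expect_equal(min(w2$offsets), -1)
  expect_error(extract_tir_window(g2, make_gene("gC", "nope", 0, 3), 1, 1),
               "contig")
})

test_that("windows agree between a genome and its reverse complement", {
  set.seed(5)
  for (r in 1:20) {
    L <- 60
    s <- random_dna(L)
    g_fwd <- make_genome(c1 = s)
    g_rev <- make_genome(c1 = as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(s))))
    start <- sample(20:30, 1); end <- start + 12
    gene_fwd <- make_gene("g", "c1", start, end, "+")
    gene_rev <- make_gene("g", "c1", L - end, L - start, "-")
    w1 <- extract_tir_window(g_fwd, gene_fwd, 10, 10)
    w2 <- extract_tir_window(g_rev, gene_rev, 10, 10)
    expect_identical(w1$sequence, w2$sequence)
    expect_identical(w1$offsets, w2$offsets)
  }
})

test_that("extract_upstream_of_tss returns the 5'-adjacent sequence per strand", {
  g <- make_genome(c1 = "ACGTACGTAC")
  # + strand: bases [2,5) precede a TSS at 5
  expect_equal(extract_upstream_of_tss(
    g, list(contig = "c1", position = 5, strand = "+"), 3), "GUA")
  # truncation at the contig start
  expect_equal(extract_upstream_of_tss(
    g, list(contig = "c1", position = 3, strand = "+"), 50), "ACG")
  # - strand: reverse complement of the 3'-adjacent genomic segment [4,7)
  expect_equal(extract_upstream_of_tss(
    g, list(contig = "c1", position = 3, strand = "-"), 3), "CGU")
  # at the very edge: nothing upstream
  expect_equal(extract_upstream_of_tss(
    g, list(contig = "c1", position = 0, strand = "+"), 10), "")
})

test_that("TSS tables round-trip and gene mRNA extraction is strand-aware", {
  tss <- data.frame(gene_id = "gA", contig = "c1", position = 4L,
                    strand = "+", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_tss(tss, f)
  expect_equal(read_tss(f), tss)

  g <- make_genome(c1 = "CCATGAAATTTCAT")
  expect_equal(gene_mrna(g, make_gene("gA", "c1", 2, 8, "+")), "AUGAAA")
  expect_equal(gene_mrna(g, make_gene("gB", "c1", 8, 14, "-")), "AUGAAA")
})
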