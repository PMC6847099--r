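# Expression stage: replicate combination, representative-set selection,
# CPM normalisation, ARD, octiles, synthesis rates, replicate QC.

toy_counts <- function(v, assay = "rna", ids = names(v)) {
  counts_table(matrix(v, ncol = 1, dimnames = list(ids, "r1")), assay)
}

test_that("combine_replicates sums per-gene counts and validates inputs", {
  m <- matrix(c(2, 1, 3, 0, 5, 9), nrow = 2,
              dimnames = list(c("gA", "gB"), c("r1", "r2", "r3")))
  ct <- counts_table(m, "rna")
  comb <- combine_replicates(ct)
  expect_equal(unname(comb$counts[, 1]), c(10, 10))

  single <- toy_counts(c(gA = 4, gB = 7))
  expect_equal(combine_replicates(single)$counts[, 1], c(gA = 4, gB = 7))

  other <- toy_counts(c(gA = 1, gC = 2))
  expect_error(combine_replicates(list(single, other)), "gene set mismatch")
  ribo <- toy_counts(c(gA = 1, gB = 2), assay = "ribo")
  expect_error(combine_replicates(list(single, ribo)), "assay mismatch")
})

test_that("representative set = top fraction by count density with documented ties", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:9), contig = "c",
                      start = 0, end = 100, strand = "+", length = 100)
  cnt <- toy_counts(setNames(c(90, 10, 80, 20, 70, 30, 60, 40, 50),
                             genes$gene_id))
  sel <- select_representative_set(cnt, genes, 1 / 3)
  expect_equal(sel, c("g01", "g03", "g05"))  # 3 largest densities of 9

  # tie at the cut: lexicographically smaller id kept
  cnt2 <- toy_counts(setNames(c(50, 50, 50, 10), c("gB", "gA", "gC", "gD")))
  genes2 <- data.frame(gene_id = c("gB", "gA", "gC", "gD"), contig = "c",
                       start = 0, end = 100, strand = "+", length = 100)
  sel2 <- select_representative_set(cnt2, genes2, 0.5)
  expect_equal(sel2, c("gA", "gB"))

  # zero-density genes never selected
  cnt3 <- toy_counts(setNames(c(5, 0, 0), c("gA", "gB", "gC")))
  genes3 <- data.frame(gene_id = c("gA", "gB", "gC"), contig = "c",
                       start = 0, end = 100, strand = "+", length = 100)
  expect_message(sel3 <- select_representative_set(cnt3, genes3, 1),
                 "zero-density")
  expect_equal(sel3, "gA")
})

test_that("normalize_cpm uses the representative total and sums to 1e6 over it", {
  cnt <- toy_counts(c(gA = 50, gB = 150, gC = 999800))
  cpm <- normalize_cpm(cnt, c("gB", "gC"))
  expect_equal(sum(cpm[c("gB", "gC")]), 1e6, tolerance = 1e-6)
  expect_true("gA" %in% names(cpm))   # outside genes still get a value

  # unit scale: representative total exactly 1e6
  cnt2 <- toy_counts(c(gA = 50, gB = 1e6 - 50))
  expect_equal(unname(normalize_cpm(cnt2, c("gA", "gB"))["gA"]), 50)

  # doubling all counts leaves CPM unchanged
  cnt3 <- toy_counts(c(gA = 100, gB = 300, gC = 999600))
  expect_equal(normalize_cpm(cnt3, c("gA", "gB")) / 2,
               normalize_cpm(toy_counts(c(gA = 200, gB = 600, gC = 1999200)),
                             c("gA", "gB")) / 2)
  expect_error(normalize_cpm(toy_counts(c(gA = 0)), "gA"), "zero total")
})

test_that("compute_ard forms the ratio and marks zero-RNA genes undefined", {
  rna <- c(gA = 10, gB = 5, gC = 0, gD = 8, gE = 2, gF = 4)
  ribo <- c(gA = 10, gB = 20, gC = 7, gD = 0, gE = 3, gF = 1)
  expect_message(ard <- compute_ard(rna, ribo), "zero RNA")
  ref <- c(1, 4, NA, 0, 1.5, 0.25)
  expect_equal(ard$ard, ref)
})

test_that("ARD is invariant to rescaling both assays' counts", {
  set.seed(3)
  rna <- setNames(rpois(50, 100) + 1, sprintf("g%02d", 1:50))
  ribo <- setNames(rpois(50, 80) + 1, names(rna))
  a1 <- compute_ard(rna, ribo)$ard
  a2 <- compute_ard(rna * 7, ribo * 7)$ard
  expect_equal(a1, a2)
})

test_that("assign_octiles gives equal, ordered, non-overlapping groups", {
  set.seed(4)
  ard <- setNames(runif(17), sprintf("g%02d", 1:17))
  oct <- assign_octiles(ard, names(ard))
  expect_equal(sum(!is.na(oct)), 16)   # octiles of 2, one gene unassigned
  expect_equal(as.integer(table(oct)), rep(2L, 8))
  # ranges decrease from octile 1 to 8 and never overlap
  rng <- sapply(1:8, function(o) range(ard[names(oct)[!is.na(oct) & oct == o]]))
  expect_true(all(diff(rng[1, ]) < 0) && all(diff(rng[2, ]) < 0))
  expect_true(all(rng[1, -8] >= rng[2, -1]))
  # the dropped gene has the lowest ARD
  expect_equal(names(which(is.na(oct))), names(which.min(ard)))

  expect_error(assign_octiles(ard[1:5], names(ard)[1:5]), "fewer genes")
  ard2 <- ard; ard2[3] <- NA
  expect_error(assign_octiles(ard2, names(ard2)), "undefined ARD")
})

test_that("synthesis rates are coverage per length, scaled to 1e6", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), contig = "c", start = 0,
                      end = c(100, 200, 50), strand = "+",
                      length = c(100, 200, 50))
  r <- synthesis_rates(toy_counts(c(gA = 100, gB = 100, gC = 0), "ribo"),
                       genes)
  expect_equal(unname(r["gA"] / r["gB"]), 2)
  expect_equal(unname(r["gC"]), 0)
  expect_equal(sum(r), 1e6)
  one <- synthesis_rates(toy_counts(c(gA = 42), "ribo"), genes[1, ])
  expect_equal(unname(one), 1e6)
})

test_that("replicate_spearman reproduces known correlation structure", {
  set.seed(6)
  base <- rpois(1000, 50)
  m <- cbind(r1 = base, r2 = base, r3 = sample(base))
  rownames(m) <- sprintf("g%04d", 1:1000)
  rs <- replicate_spearman(counts_table(m, "rna"))
  expect_equal(dim(rs), c(3, 3))
  expect_equal(rs["r1", "r2"], 1)
  expect_lt(abs(rs["r1", "r3"]), 0.1)   # shuffled ~ 0 within sampling error
  expect_error(replicate_spearman(toy_counts(c(gA = 1))), "2 replicates")
})

test_that("expression_profile wires the stages together consistently", {
  set.seed(7)
  n <- 160
  ids <- sprintf("g%03d", 1:n)
  genes <- data.frame(gene_id = ids, contig = "c", start = 0, end = 300,
                      strand = "+", length = 300)
  rna <- counts_table(matrix(rpois(2 * n, 100), ncol = 2,
                             dimnames = list(ids, c("r1", "r2"))), "rna")
  ribo <- counts_table(matrix(rpois(2 * n, 80), ncol = 2,
                              dimnames = list(ids, c("b1", "b2"))), "ribo")
  prof <- suppressMessages(expression_profile(rna, ribo, genes))
  expect_s3_class(prof, "expression_profile")
  expect_equal(nrow(prof$table), n)
  expect_equal(length(prof$representative), floor(n / 3))
  sizes <- table(prof$table$octile)
  expect_equal(length(sizes), 8L)
  expect_equal(length(unique(sizes)), 1L)
  # octile genes are a subset of the representative set
  expect_true(all(prof$table$gene_id[!is.na(prof$table$octile)] %in%
                    prof$representative))
  # CPM over representative genes sums to 1e6
  rep_rows <- prof$table$gene_id %in% prof$representative
  expect_equal(sum(prof$table$rna_cpm[rep_rows]), 1e6, tolerance = 1e-6)
  expect_equal(sum(prof$table$ribo_cpm[rep_rows]), 1e6, tolerance = 1e-6)
})
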