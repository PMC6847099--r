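# Composition-matched trinucleotide counting and the cross-phylum tests.

test_that("overlapping trinucleotide counting is exact", {
  expect_equal(count_trinucleotides("AUGAUGAUG", "AUG"), 3L)
  expect_equal(count_trinucleotides("AUGAUGAUG", "GAU"), 2L)
  expect_equal(count_trinucleotides("AUGAUGAUG", "GUA"), 0L)
  expect_equal(count_trinucleotides("AAAA", "AUG"), 0L)
  expect_error(count_trinucleotides("AU", "AUG"), "shorter than 3")
  expect_error(count_trinucleotides("AUGC", "AUGC"), "3-mer")
})

test_that("genome_ratios reproduces a hand-counted single-gene fixture", {
  # tir_upstream (-21..-1) = (AUG)x7: AUG/GAU = 7/6
  win <- strrep("ATG", 7)
  cds <- paste0("ATG", strrep("GCA", 20), "TAA")  # 66 nt, no AUG after start
  g <- make_genome(c1 = paste0(strrep("C", 10), win, cds, strrep("C", 30)))
  gene <- make_gene("gA", "c1", 31, 31 + nchar(cds), "+")
  r <- genome_ratios(g, gene, genome_id = "toy")
  expect_equal(unname(r$counts["tir_upstream", "AUG"]), 7L)
  expect_equal(unname(r$counts["tir_upstream", "GAU"]), 6L)
  expect_equal(unname(r$ratios["tir_upstream", "AUG/GAU"]), 7 / 6)
  # the start codon itself is never counted: tir_downstream starts at +4
  expect_equal(unname(r$counts["tir_downstream", "AUG"]), 0L)
  # 21-nt windows hold 19 trinucleotide start offsets
  up_tot <- 19L
  gca_counts <- sum(vapply(c("GCA", "CAG", "AGC"), function(t) {
    count_trinucleotides(window_subseq(
      extract_tir_window(g, gene, 21, 24), 4, 24), t)
  }, integer(1)))
  expect_equal(gca_counts, up_tot)
})

test_that("gene order does not change aggregate counts; short genes skip midgene", {
  set.seed(16)
  contig <- random_dna(3000)
  g <- make_genome(c1 = contig)
  genes <- do.call(rbind, lapply(1:8, function(i) {
    make_gene(sprintf("g%02d", i), "c1", 100 + 300 * (i - 1),
              100 + 300 * (i - 1) + 90, "+")
  }))
  r1 <- genome_ratios(g, genes)
  r2 <- genome_ratios(g, genes[sample(nrow(genes)), ])
  expect_identical(r1$counts, r2$counts)

  # a 42-nt gene is excluded from midgene windows only
  short <- make_gene("gS", "c1", 1000, 1042, "+")
  rs <- genome_ratios(g, rbind(genes[1, ], short))
  expect_equal(unname(rs$n_genes["midgene_upstream"]), 1L)
  expect_equal(unname(rs$n_genes["tir_upstream"]), 2L)
})

test_that("uniform random sequence gives ratios near one", {
  set.seed(17)
  contig <- random_dna(130000)
  g <- make_genome(c1 = contig)
  genes <- do.call(rbind, lapply(1:150, function(i) {
    make_gene(sprintf("g%03d", i), "c1", 100 + 800 * (i - 1),
              100 + 800 * (i - 1) + 600, "+")
  }))
  r <- genome_ratios(g, genes)
  # all permutations of AUG are equiprobable under i.i.d. composition, so
  # conditionally on the two counts the AUG share is Binomial(n, 1/2);
  # none of the 12 ratios should reject that at the 0.1% level
  for (w in rownames(r$counts)) {
    for (tri in c("GAU", "GUA", "AGU")) {
      n_aug <- r$counts[w, "AUG"]; n_den <- r$counts[w, tri]
      p <- binom.test(n_aug, n_aug + n_den, 0.5)$p.value
      expect_gt(p, 0.001)
    }
  }
})

test_that("phylum_analysis flags ratios below one and contrasts phyla", {
  set.seed(18)
  fake_ratios <- function(id, mu) {
    ratios <- matrix(rnorm(12, mu, 0.05), 4, 3,
                     dimnames = list(TRINUC_WINDOWS <- c(
                       "tir_upstream", "tir_downstream",
                       "midgene_upstream", "midgene_downstream"),
                       c("AUG/GAU", "AUG/GUA", "AUG/AGU")))
    structure(list(genome_id = id, counts = NULL, ratios = ratios,
                   n_genes = NULL, n_total = 100), class = "trinuc_ratios")
  }
  tabs <- c(lapply(1:10, function(i) fake_ratios(paste0("b", i), 0.56)),
            lapply(1:10, function(i) fake_ratios(paste0("p", i), 0.75)))
  phyla <- setNames(rep(c("Bacteroidetes", "Proteobacteria"), each = 10),
                    c(paste0("b", 1:10), paste0("p", 1:10)))
  res <- phylum_analysis(tabs, phyla)
  one <- res$one_sample
  expect_true(all(one$significant_lt1))
  expect_true(all(one$median < 1))
  expect_true(all(res$pairwise$significant))

  # near-1 ratios with noise: not significant
  tabs2 <- c(lapply(1:5, function(i) fake_ratios(paste0("x", i), 1.0)),
             lapply(1:5, function(i) fake_ratios(paste0("y", i), 1.0)))
  phyla2 <- setNames(rep(c("A", "B"), each = 5),
                     c(paste0("x", 1:5), paste0("y", 1:5)))
  res2 <- phylum_analysis(tabs2, phyla2)
  expect_false(any(res2$one_sample$significant_lt1))

  # single phylum: one-sample only, no pairwise table
  res3 <- phylum_analysis(tabs[1:10], phyla[1:10])
  expect_null(res3$pairwise)
  expect_error(phylum_analysis(tabs[1:2], setNames(c("A", "B"),
                                                   c("b1", "b2"))),
               "at least 2")
})
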