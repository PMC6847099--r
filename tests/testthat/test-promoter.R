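# -7 element discovery, spacing logic, frequency model, IUPAC consensus and
# leader lengths.

test_that("consensus_scan finds an exact seed match with the right spacing", {
  # element ends 5 nt before the TSS (the sequence 3' end)
  s <- c(gX = paste0(strrep("C", 20), "TAGGTTTG", strrep("C", 5)))
  hits <- find_candidate_elements(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$element, "TAGGTTTG")
  expect_equal(hits$spacing, 5L)
  expect_equal(hits$score, 6L)

  # all-A sequence: no hit at the default threshold
  expect_equal(nrow(find_candidate_elements(c(gY = strrep("A", 50)))), 0L)
  expect_error(find_candidate_elements(character(0)), "empty")
})

test_that("ties go to the most TSS-proximal site and U input is accepted", {
  s <- c(gX = paste0("TACCTTTG", strrep("C", 10), "TAGGTTTG",
                     strrep("C", 4)))
  hits <- find_candidate_elements(s)
  expect_equal(hits$spacing, 4L)
  expect_equal(hits$element, "TAGGTTTG")

  # RNA alphabet in, DNA alphabet out
  s_rna <- c(gZ = chartr("T", "U", paste0(strrep("C", 20), "TAGGTTTG",
                                          strrep("C", 4))))
  expect_equal(find_candidate_elements(s_rna)$element, "TAGGTTTG")
})

test_that("planted elements are recovered and the consensus re-derived", {
  set.seed(14)
  fx <- make_promoter_fixture(80, n_decoys = 20)
  hits <- find_candidate_elements(fx$seqs)
  m <- merge(hits, fx$truth, by = "gene_id", suffixes = c("", ".true"))
  recovered <- mean(m$element == m$element.true & m$spacing == m$spacing.true)
  expect_gte(recovered, 0.95)

  probable <- filter_probable_promoters(hits)
  expect_true(all(probable$spacing %in% 4:5))
  model <- build_promoter_model(probable, fx$seqs)
  expect_equal(model$consensus, "TAHHTTTG")
})

test_that("spacing_histogram returns proportions that sum to one", {
  hits <- data.frame(gene_id = c("a", "b", "c", "d"),
                     element = "TAGGTTTG", spacing = c(4L, 4L, 5L, 7L),
                     score = 6)
  h <- spacing_histogram(hits)
  expect_equal(sum(h), 1)
  expect_equal(unname(h["4"]), 0.5)
  expect_equal(unname(h["5"]), 0.25)
  expect_equal(spacing_histogram(hits[hits$spacing == 4, ]),
               c("4" = 1.0))
  expect_error(spacing_histogram(hits[0, ]), "no hits")
})

test_that("filter_probable_promoters keeps exactly spacing 4-5 and is idempotent", {
  hits <- data.frame(gene_id = letters[1:4], element = "TAGGTTTG",
                     spacing = c(3L, 4L, 5L, 6L), score = 6)
  f <- filter_probable_promoters(hits)
  expect_equal(f$spacing, c(4L, 5L))
  expect_equal(filter_probable_promoters(f), f)
  expect_equal(nrow(filter_probable_promoters(hits[0, ])), 0L)
  expect_equal(nrow(filter_probable_promoters(
    data.frame(gene_id = "a", element = "x", spacing = 7L, score = 6))), 0L)
})

test_that("build_promoter_model aligns elements and handles short flanks", {
  seqs <- c(g1 = paste0(strrep("A", 20), "TAGGTTTG", "CCCC"),
            g2 = paste0(strrep("A", 20), "TAGGTTTG", "CCCC"))
  hits <- find_candidate_elements(seqs)
  model <- build_promoter_model(hits, seqs)
  expect_equal(dim(model$counts), c(4L, 8L))
  expect_true(all(model$frequencies %in% c(0, 1)))  # identical elements
  expect_equal(model$consensus, "TAGGTTTG")
  expect_equal(colnames(model$counts), as.character(-12:-5))

  # flank wider than the sequence: per-column n decreases, no error
  short <- c(g1 = "TAGGTTTGCCCC", g2 = "TAGGTTTGCCCC")
  h2 <- find_candidate_elements(short)
  m2 <- build_promoter_model(h2, short, flank = 6)
  expect_lt(min(m2$n), max(m2$n))
  expect_error(build_promoter_model(hits[0, ], seqs), "at least 2")
})

test_that("derive_consensus applies the invariant and absent thresholds", {
  mk <- function(...) {
    m <- cbind(...)
    rownames(m) <- c("A", "C", "G", "T")
    m
  }
  expect_equal(derive_consensus(mk(c(0.97, 0.01, 0.01, 0.01))), "A")
  # G virtually absent, others present -> H (the -10/-9 rule)
  expect_equal(derive_consensus(mk(c(0.35, 0.32, 0.02, 0.31))), "H")
  expect_equal(derive_consensus(mk(c(0.25, 0.25, 0.25, 0.25))), "N")
  expect_equal(derive_consensus(mk(c(0.5, 0.02, 0.02, 0.46))), "W")
  # U rownames accepted
  mU <- mk(c(0.35, 0.32, 0.02, 0.31)); rownames(mU)[4] <- "U"
  expect_equal(derive_consensus(mU), "H")
  expect_error(derive_consensus(mk(c(1, 0, 0, 0)), invariant_threshold = 0.4),
               "invariant_threshold")
})

test_that("gibbs sampler is seed-reproducible and recovers a planted motif", {
  set.seed(15)
  fx <- make_promoter_fixture(50, n_decoys = 0, spacing_probs = c("4" = 1))
  a <- gibbs_motif_sampler(fx$seqs, iterations = 400, restarts = 3, seed = 99)
  b <- gibbs_motif_sampler(fx$seqs, iterations = 400, restarts = 3, seed = 99)
  expect_identical(a, b)           # bit-reproducible under a fixed seed

  hamming <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  ok <- 0L
  for (sd in 1:10) {
    fit <- gibbs_motif_sampler(fx$seqs, iterations = 600, restarts = 5,
                               seed = sd)
    cons <- derive_consensus(fit$pwm)
    if (hamming(cons, "TAHHTTTG") <= 1) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("leader lengths follow the TSS-to-start distance on both strands", {
  genes <- rbind(make_gene("gA", "c1", 100, 160, "+"),
                 make_gene("gB", "c1", 200, 260, "-"))
  tss <- data.frame(gene_id = c("gA", "gB"), contig = "c1",
                    position = c(100L, 292L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  ll <- leader_lengths(tss, genes)
  expect_equal(unname(ll$lengths["gA"]), 0L)    # leaderless
  expect_equal(unname(ll$lengths["gB"]), 33L)   # 292 - 259
  expect_equal(ll$mean, 16.5)
  expect_equal(ll$frac_over, 0.5)

  bad <- tss; bad$position[1] <- 101L
  expect_error(leader_lengths(bad, genes), "downstream")
  flip <- tss; flip$strand[1] <- "-"
  expect_error(leader_lengths(flip, genes), "strand")
})
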