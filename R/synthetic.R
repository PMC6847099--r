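# Seeded synthetic-data generator: genomes, annotations, TSS tables and
# negative-binomial count tables with the statistical structure the
# analysis stages assume, so every stage can be tested against known ground
# truth.
#
# What it emulates (and what it does not) is laid out in the methods
# vignette.  Every random draw flows from the config seed; there is no
# hidden entropy.

#' Configuration for the synthetic-data generator
#'
#' @param seed mandatory RNG seed.
#' @param n_genes number of genes.
#' @param gene_length `(min, max)` CDS length range in nt (rounded to whole
#'   codons).
#' @param gc_content genomic G+C fraction (default 0.34, an AT-rich
#'   Bacteroidetes-like background).
#' @param n_replicates replicates per assay.
#' @param depth mean reads per gene per replicate.
#' @param nb_dispersion negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2`.
#' @param efficiency_sdlog sd of log true translation efficiency
#'   (log-normal; default 1.0, spanning roughly two orders of magnitude
#'   across genes as ARD does in profiling data).
#' @param a3_effect,a6_effect,a12_13_effect strength of the link between a
#'   gene's efficiency percentile and the probability of A at offsets -3,
#'   -6 and -12/-13: `P(A) = gc-background P(A) + effect * (percentile - 0.5)`,
#'   clamped to `[0.02, 0.98]`.
#' @param aug_depletion multiplier on AUG retention within the TIR windows
#'   -21..-1 and +4..+24 (1 = no depletion; 0.6 keeps ~60% of AUGs).
#' @param promoter_spacing_probs named proportions over element-to-TSS
#'   spacings (names = spacing in nt).
#' @param hairpin_fraction_low_ard fraction of bottom-octile genes given a
#'   perfect 8-bp GC hairpin at offsets -60..-41.
#' @param leader_mean,leader_size negative-binomial leader-length
#'   distribution (mean 33 nt; size 5 puts ~93% of leaders above 10 nt).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, n_genes = 500,
                             gene_length = c(300, 900), gc_content = 0.34,
                             n_replicates = 3, depth = 200,
                             nb_dispersion = 0.1, efficiency_sdlog = 1.0,
                             a3_effect = 0.5, a6_effect = 0.5,
                             a12_13_effect = 0.5, aug_depletion = 1,
                             promoter_spacing_probs = c("4" = 0.7, "5" = 0.3),
                             hairpin_fraction_low_ard = 0,
                             leader_mean = 33, leader_size = 5) {
  if (missing(seed)) stop("synthetic_config: seed is mandatory")
  stopifnot(n_genes >= 1, length(gene_length) == 2,
            gene_length[1] >= 60, gene_length[2] >= gene_length[1],
            gc_content > 0, gc_content < 1,
            n_replicates >= 1, depth > 0, nb_dispersion > 0,
            efficiency_sdlog >= 0,
            a3_effect >= 0, a6_effect >= 0, a12_13_effect >= 0,
            aug_depletion > 0, aug_depletion <= 1,
            abs(sum(promoter_spacing_probs) - 1) < 1e-9,
            hairpin_fraction_low_ard >= 0, hairpin_fraction_low_ard <= 1,
            leader_mean > 0, leader_size > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# background base probabilities (A, C, G, T) for a GC content
.bg_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                            G = gc / 2, T = (1 - gc) / 2)

#' Generate a synthetic genome with planted signals
#'
#' Builds `n_genes` non-overlapping genes on both strands, each consisting
#' of (5' to 3' on its coding strand) an intergenic pad, a planted
#' `TAHHTTTG` promoter element, a sampled 4-5 nt spacer, the TSS and
#' leader, and the CDS (always starting AUG).  Plants, per gene:
#'
#' * A-enrichment at offsets -3, -6, -12, -13 increasing with the gene's
#'   true translation-efficiency percentile;
#' * optional AUG depletion within the TIR windows -21..-1 and +4..+24:
#'   each AUG occurrence is kept with probability `aug_depletion`; a
#'   rejected occurrence has one of its (non-determinant) bases redrawn
#'   from the background composition until the triplet changes — a point
#'   mutation that destroys the AUG while leaving the composition-matched
#'   denominators essentially untouched;
#' * optional perfect 8-bp GC hairpins at offsets -60..-41 in bottom-octile
#'   genes.
#'
#' Byte-identical outputs for a fixed config.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_genome`: list with `genome`
#'   ([Biostrings::DNAStringSet], one contig `synth_1`), `genes`, `tss`,
#'   `truth` (per-gene data.frame incl. true efficiency, percentile and
#'   octile, planted element, spacing, leader, hairpin flag) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  bg <- .bg_probs(config$gc_content)

  eff <- stats::rlnorm(n, 0, config$efficiency_sdlog)
  pct <- (rank(eff, ties.method = "first") - 0.5) / n
  true_oct <- pmin(8L, pmax(1L, ceiling(
    rank(-eff, ties.method = "first") * 8 / n)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  spac_lv <- as.integer(names(config$promoter_spacing_probs))
  spac <- sample(spac_lv, n, replace = TRUE,
                 prob = config$promoter_spacing_probs)
  leaders <- stats::rnbinom(n, size = config$leader_size,
                            mu = config$leader_mean)
  ncod <- sample(seq(ceiling(config$gene_length[1] / 3),
                     floor(config$gene_length[2] / 3)), n, replace = TRUE)
  clens <- 3L * ncod
  hairpin <- true_oct == 8L &
    stats::runif(n) < config$hairpin_fraction_low_ard

  det_offsets <- c(-3L, -6L, -12L, -13L)
  det_effects <- c(config$a3_effect, config$a6_effect,
                   config$a12_13_effect, config$a12_13_effect)
  stem1 <- c("G", "C", "C", "G", "G", "C", "G", "C")
  hp <- c(stem1, c("A", "A", "A", "A"), revcomp_vec(stem1))

  units <- vector("list", n)
  cds0 <- tss0 <- tots <- integer(n)
  elements <- character(n)

  for (g in seq_len(n)) {
    s <- spac[g]; L <- leaders[g]; clen <- clens[g]
    pad <- sample(30:80, 1L)
    if (hairpin[g]) pad <- max(pad, 61L - (8L + s + L))
    pre <- pad + 8L + s + L                  # 0-based CDS start within unit
    tot <- pre + clen + sample(15:40, 1L)
    u <- sample(BASES_DNA, tot, replace = TRUE, prob = bg)
    el <- c("T", "A", sample(c("A", "C", "T"), 1L),
            sample(c("A", "C", "T"), 1L), "T", "T", "T", "G")
    u[(pad + 1L):(pad + 8L)] <- el
    u[(pre + 1L):(pre + 3L)] <- c("A", "T", "G")
    u[(pre + clen - 2L):(pre + clen)] <- c("T", "A", "A")
    if (hairpin[g]) {
      u[(pre - 60L + 1L):(pre - 41L + 1L)] <- hp
    }
    for (d in seq_along(det_offsets)) {
      pA <- min(0.98, max(0.02, bg[["A"]] +
                            det_effects[d] * (pct[g] - 0.5)))
      u[pre + det_offsets[d] + 1L] <-
        if (stats::runif(1) < pA) "A" else
          sample(c("C", "G", "T"), 1L, prob = bg[c("C", "G", "T")])
    }
    if (config$aug_depletion < 1) {
      det_idx <- pre + det_offsets + 1L
      for (off in c(-21L:-3L, 4L:22L)) {
        i0 <- pre + off + 1L
        if (u[i0] == "A" && u[i0 + 1L] == "T" && u[i0 + 2L] == "G" &&
            stats::runif(1) > config$aug_depletion) {
          free <- setdiff(i0:(i0 + 2L), det_idx)
          p <- if (length(free) == 1L) free else sample(free, 1L)
          old <- u[p]
          for (try in 1:50) {
            b <- sample(BASES_DNA, 1L, prob = bg)
            if (b != old) { u[p] <- b; break }
          }
        }
      }
    }
    units[[g]] <- u
    cds0[g] <- pre; tss0[g] <- pad + 8L + s; tots[g] <- tot
    elements[g] <- paste(el, collapse = "")
  }

  offset <- 0L
  starts <- ends <- tsspos <- integer(n)
  parts <- vector("list", n)
  for (g in seq_len(n)) {
    u <- units[[g]]; tot <- tots[g]
    if (strands[g] == "+") {
      starts[g] <- offset + cds0[g]
      ends[g] <- starts[g] + clens[g]
      tsspos[g] <- offset + tss0[g]
    } else {
      u <- revcomp_vec(u)
      starts[g] <- offset + tot - (cds0[g] + clens[g])
      ends[g] <- offset + tot - cds0[g]
      tsspos[g] <- offset + tot - 1L - tss0[g]
    }
    parts[[g]] <- u
    offset <- offset + tot
  }

  genome <- Biostrings::DNAStringSet(paste(unlist(parts), collapse = ""))
  names(genome) <- "synth_1"
  ids <- sprintf("g%04d", seq_len(n))
  genes <- data.frame(gene_id = ids, contig = "synth_1", start = starts,
                      end = ends, strand = strands, length = clens,
                      stringsAsFactors = FALSE)
  tss <- data.frame(gene_id = ids, contig = "synth_1", position = tsspos,
                    strand = strands, stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, efficiency = eff, percentile = pct,
                      true_octile = true_oct, length = clens,
                      leader = leaders, spacing = spac, element = elements,
                      hairpin = hairpin, strand = strands,
                      stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes, tss = tss, truth = truth,
                 config = config),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d genes on %d nt (seed %d)\n",
              nrow(x$genes), sum(Biostrings::width(x$genome)),
              x$config$seed))
  invisible(x)
}

#' Generate replicate count tables from ground truth
#'
#' Per gene, the RNA-seq mean is proportional to a log-normal expression
#' level weighted by gene length, `mu_rna = depth * (e/mean(e)) *
#' (len/mean(len))`, and the ribo-seq mean is `mu_rna * efficiency`.
#' Replicate counts are drawn negative-binomial with
#' `var = mu + dispersion * mu^2`.  Seeded from `config$seed + 1` so the
#' count stream is decoupled from (but determined by) the genome stream.
#'
#' @param config a [synthetic_config()].
#' @param truth truth data.frame from [generate_genome()] (needs columns
#'   `gene_id`, `efficiency`, `length`).
#' @return list with `rna` and `ribo` `counts_table`s and the per-gene
#'   `expression` levels used.
#' @export
generate_counts <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("gene_id", "efficiency", "length") %in% names(truth)))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  expr <- stats::rlnorm(n, 0, 1)
  mu_rna <- config$depth * (expr / mean(expr)) *
    (truth$length / mean(truth$length))
  mu_ribo <- mu_rna * truth$efficiency
  size <- 1 / config$nb_dispersion
  draw <- function(mu, prefix) {
    m <- matrix(stats::rnbinom(n * config$n_replicates,
                               mu = rep(mu, config$n_replicates),
                               size = size),
                nrow = n, ncol = config$n_replicates,
                dimnames = list(truth$gene_id,
                                paste0(prefix, "_rep",
                                       seq_len(config$n_replicates))))
    m
  }
  list(rna = counts_table(draw(mu_rna, "rna"), assay = "rna"),
       ribo = counts_table(draw(mu_ribo, "ribo"), assay = "ribo"),
       expression = stats::setNames(expr, truth$gene_id))
}

#' Write a synthetic bundle to disk
#'
#' Emits the exact input formats the analysis stages consume: genome FASTA,
#' GFF3 annotations, TSS TSV, ground-truth TSV and (when `counts` is given)
#' one counts TSV per assay.
#'
#' @param sim a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @param counts optional result of [generate_counts()].
#' @return named character vector of the files written, invisibly.
#' @export
write_synthetic_bundle <- function(sim, dir, counts = NULL) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotations = file.path(dir, "annotations.gff3"),
             tss = file.path(dir, "tss.tsv"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write_annotations(sim$genes, paths[["annotations"]])
  write_tss(sim$tss, paths[["tss"]])
  write_tsv_report(sim$truth, paths[["truth"]])
  if (!is.null(counts)) {
    paths <- c(paths, rna_counts = file.path(dir, "rna_counts.tsv"),
               ribo_counts = file.path(dir, "ribo_counts.tsv"))
    write_counts_table(counts$rna, paths[["rna_counts"]])
    write_counts_table(counts$ribo, paths[["ribo_counts"]])
  }
  invisible(paths)
}
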