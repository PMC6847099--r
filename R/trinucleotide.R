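# AUG-underrepresentation statistic: counts of AUG and its composition-
# matched permutations (GAU, GUA, AGU) in TIR and midgene windows,
# aggregated per genome, with cross-phylum testing.
#
# Window definitions (offsets relative to the first base of the start
# codon):
#   tir_upstream      offsets -21..-1   (21 nt, 19 trinucleotide starts)
#   tir_downstream    offsets  +4..+24  (21 nt; never overlaps the start
#                                        codon, whose last base is +2)
#   midgene_upstream  the 20 nt immediately 5' of the gene midpoint
#   midgene_downstream the 20 nt immediately 3' of the midpoint
# For a gene of length l the midpoint is m = floor(l/2); the midgene
# windows are [m-20, m) and [m, m+20) in mRNA coordinates.  Genes shorter
# than 43 nt cannot host both midgene windows and are excluded from the
# midgene counts only.

TRINUC_SET <- c("AUG", "GAU", "GUA", "AGU")
TRINUC_WINDOWS <- c("tir_upstream", "tir_downstream",
                    "midgene_upstream", "midgene_downstream")

#' Count (overlapping) occurrences of a trinucleotide in a window
#'
#' @param seq RNA string of length >= 3.
#' @param tri 3-mer to count.
#' @return integer count over all start offsets.
#' @export
count_trinucleotides <- function(seq, tri) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("count_trinucleotides: window shorter than 3 nt")
  if (nchar(tri) != 3L) stop("count_trinucleotides: tri must be a 3-mer")
  starts <- seq_len(nchar(seq) - 2L)
  sum(substring(seq, starts, starts + 2L) == toupper(tri))
}

#' Genome-wide trinucleotide ratios in TIR and midgene windows
#'
#' For each of the four windows, trinucleotide counts are summed across all
#' analysed genes and the ratios AUG/GAU, AUG/GUA and AUG/AGU are formed
#' from the aggregate counts (one number per genome per window, avoiding
#' per-gene zero denominators).  Windows truncated by a contig edge or
#' containing N are skipped for that gene; genes shorter than 43 nt are
#' skipped for the midgene windows only.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param genes annotation data.frame.
#' @param gene_ids optional subset of genes to analyse (e.g. a
#'   representative set); default all.
#' @param genome_id label carried into the output.
#' @return object of class `trinuc_ratios`: list with `genome_id`, `counts`
#'   (4 windows x 4 trinucleotides), `ratios` (4 windows x 3 ratios),
#'   `n_genes` (per window) and `n_total`.
#' @export
genome_ratios <- function(genome, genes, gene_ids = NULL,
                          genome_id = "genome") {
  if (!is.null(gene_ids)) {
    genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  }
  if (!nrow(genes)) stop("genome_ratios: no genes to analyse")
  counts <- matrix(0L, 4, 4,
                   dimnames = list(TRINUC_WINDOWS, TRINUC_SET))
  n_genes <- stats::setNames(integer(4), TRINUC_WINDOWS)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- extract_tir_window(genome, g, upstream = 21, downstream = 24)
    up <- window_subseq(w, -21, -1)
    dn <- window_subseq(w, 4, 24)
    segs <- list(tir_upstream = up, tir_downstream = dn)
    if (g$length >= 43L) {
      mrna <- gene_mrna(genome, g)
      m <- g$length %/% 2L
      mu <- substr(mrna, m - 20L + 1L, m)
      md <- substr(mrna, m + 1L, m + 20L)
      if (!grepl("N", mu, fixed = TRUE)) segs$midgene_upstream <- mu
      if (!grepl("N", md, fixed = TRUE)) segs$midgene_downstream <- md
    }
    for (wname in names(segs)) {
      s <- segs[[wname]]
      if (is.na(s)) next
      for (tri in TRINUC_SET) {
        counts[wname, tri] <- counts[wname, tri] + count_trinucleotides(s, tri)
      }
      n_genes[wname] <- n_genes[wname] + 1L
    }
  }
  ratios <- cbind(
    `AUG/GAU` = ifelse(counts[, "GAU"] > 0, counts[, "AUG"] / counts[, "GAU"], NA),
    `AUG/GUA` = ifelse(counts[, "GUA"] > 0, counts[, "AUG"] / counts[, "GUA"], NA),
    `AUG/AGU` = ifelse(counts[, "AGU"] > 0, counts[, "AUG"] / counts[, "AGU"], NA))
  structure(list(genome_id = genome_id, counts = counts, ratios = ratios,
                 n_genes = n_genes, n_total = nrow(genes)),
            class = "trinuc_ratios")
}

#' @export
print.trinuc_ratios <- function(x, ...) {
  cat("trinuc_ratios for", x$genome_id, "(", x$n_total, "genes )\n")
  print(round(x$ratios, 3))
  invisible(x)
}

#' Cross-phylum comparison of AUG ratios
#'
#' For every phylum, window and ratio: the median across member genomes and
#' a one-sample t-test of the per-genome ratios against 1; additionally a
#' two-sample t-test for every pair of phyla.  P-values are Bonferroni-
#' corrected within each ratio family (one-sample: over phyla x windows;
#' pairwise: over pairs x windows).  A cell is flagged `significant_lt1`
#' only when the adjusted p-value is below `alpha` *and* the median is
#' below one.
#'
#' @param ratio_tables list of `trinuc_ratios`, one per genome.
#' @param phyla named character vector mapping genome_id to phylum; every
#'   phylum needs at least 2 genomes.
#' @param alpha family-wise error rate (default 0.05).
#' @return object of class `phylum_comparison`: list with `one_sample` and
#'   `pairwise` data.frames and `alpha`.
#' @export
phylum_analysis <- function(ratio_tables, phyla, alpha = 0.05) {
  long <- do.call(rbind, lapply(ratio_tables, function(rt) {
    data.frame(genome_id = rt$genome_id,
               phylum = unname(phyla[rt$genome_id]),
               window = rep(rownames(rt$ratios), ncol(rt$ratios)),
               ratio = rep(colnames(rt$ratios), each = nrow(rt$ratios)),
               value = as.vector(rt$ratios),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(long$phylum)) {
    stop("phylum_analysis: genome(s) without a phylum label")
  }
  sizes <- table(unique(long[, c("genome_id", "phylum")])$phylum)
  if (any(sizes < 2)) {
    stop("phylum_analysis: every phylum needs at least 2 genomes")
  }
  phyla_lv <- sort(unique(long$phylum))

  one <- do.call(rbind, lapply(split(long, long[, c("ratio", "window",
                                                    "phylum")]), function(d) {
    if (!nrow(d)) return(NULL)
    v <- d$value[!is.na(d$value)]
    tt <- one_sample_t(v, 1)
    data.frame(phylum = d$phylum[1], window = d$window[1],
               ratio = d$ratio[1], n = length(v), median = stats::median(v),
               statistic = tt$statistic, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(one) <- NULL
  one <- one[order(one$ratio, one$window, one$phylum), ]
  one$p_adjusted <- stats::ave(one$p_value, one$ratio, FUN = function(p) {
    pmin(1, p * length(p))
  })
  one$significant_lt1 <- one$p_adjusted < alpha & one$median < 1

  pw <- NULL
  if (length(phyla_lv) >= 2) {
    pairs <- utils::combn(phyla_lv, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(split(long, long[, c("ratio", "window")]),
                                function(d) {
      do.call(rbind, lapply(pairs, function(pr) {
        va <- d$value[d$phylum == pr[1] & !is.na(d$value)]
        vb <- d$value[d$phylum == pr[2] & !is.na(d$value)]
        tt <- two_sample_t(va, vb)
        data.frame(phylum_a = pr[1], phylum_b = pr[2],
                   window = d$window[1], ratio = d$ratio[1],
                   statistic = tt$statistic, p_value = tt$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(pw) <- NULL
    pw$p_adjusted <- stats::ave(pw$p_value, pw$ratio, FUN = function(p) {
      pmin(1, p * length(p))
    })
    pw$significant <- pw$p_adjusted < alpha
  }
  structure(list(one_sample = one, pairwise = pw, alpha = alpha),
            class = "phylum_comparison")
}

#' @export
print.phylum_comparison <- function(x, ...) {
  cat("phylum_comparison (alpha =", x$alpha, ")\n")
  sig <- x$one_sample[x$one_sample$significant_lt1, ]
  cat("  cells significantly < 1:", nrow(sig), "\n")
  invisible(x)
}
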