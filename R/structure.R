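# Local mRNA secondary structure: per-position base-pairing probabilities
# over start-codon-centred windows, from an exact partition function over
# nested structures.
#
# The energy model is deliberately simple — one Boltzmann weight per pair
# type (GC, AU, GU), no stacking or loop entropies — so that the computation
# is exactly verifiable against exhaustive enumeration.  The claims the
# pipeline makes are about *relative* pairing propensity near start codons,
# for which relative pair strengths suffice.  For publication-grade numbers
# an external folder's per-position probabilities can be substituted via
# [read_pairing_profiles()].

#' Folding model: pair weights and hairpin constraint
#'
#' Default weights `GC = e^3`, `AU = e^2`, `GU = e^1` encode the relative
#' stability ordering of the three pair types; `min_hairpin` is the minimum
#' number of unpaired nucleotides enclosed by any pair (3, the sterically
#' feasible minimum).
#'
#' @param pair_weights named numeric vector with elements `GC`, `AU`, `GU`;
#'   weights are symmetric (GC = CG etc.).  A weight of 0 removes that pair
#'   class from the model (e.g. `GU = 0` for Watson-Crick-only folding,
#'   under which pairing probabilities become exactly reverse-complement
#'   invariant; the wobble pair breaks that symmetry since its reverse
#'   complement C-A cannot pair).
#' @param min_hairpin integer >= 3.
#' @return object of class `folding_model`.
#' @export
folding_model <- function(pair_weights = c(GC = exp(3), AU = exp(2),
                                           GU = exp(1)),
                          min_hairpin = 3) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_weights)),
            all(is.finite(pair_weights)), all(pair_weights >= 0),
            min_hairpin >= 3)
  W <- matrix(0, 4, 4, dimnames = list(BASES_RNA, BASES_RNA))
  W["G", "C"] <- W["C", "G"] <- pair_weights[["GC"]]
  W["A", "U"] <- W["U", "A"] <- pair_weights[["AU"]]
  W["G", "U"] <- W["U", "G"] <- pair_weights[["GU"]]
  structure(list(pair_weights = pair_weights,
                 min_hairpin = as.integer(min_hairpin),
                 weight_matrix = W),
            class = "folding_model")
}

#' Partition function and pairing probabilities for an RNA sequence
#'
#' Computes `Z`, the Boltzmann-weighted sum over all nested (pseudoknot-free)
#' secondary structures — each structure contributes the product of its pair
#' weights, the empty structure contributes 1 — and, for each position, the
#' probability that it is paired to anything in the ensemble.  Exact to
#' floating precision via an inside–outside dynamic programme, O(n^3) time
#' and O(n^2) space.
#'
#' @param seq RNA string over `{A,C,G,U}`, length >= 1.
#' @param model a [folding_model()].
#' @return list with `Z` (scalar) and `p_paired` (numeric vector, one entry
#'   per position, each in \[0, 1\]).
#' @export
partition_function <- function(seq, model = folding_model()) {
  stopifnot(inherits(model, "folding_model"))
  s <- toupper(seq)
  if (nchar(s) < 1L) stop("partition_function: empty sequence")
  if (grepl("[^ACGU]", s)) {
    stop("partition_function: illegal characters in sequence")
  }
  enc <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES_RNA)
  res <- mccaskill_pf(enc, model$weight_matrix, model$min_hairpin)
  res$p_paired <- pmin(pmax(res$p_paired, 0), 1)
  res
}

#' Fold the TIR window of one gene
#'
#' Extracts the strand-aware window around the start codon (default
#' -100..+100, local folding only) and runs [partition_function()] on it.
#' Truncated windows are folded as-is; windows containing N are an error
#' (callers filter them out and log the exclusion).
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param gene one annotation row.
#' @param model a [folding_model()].
#' @param upstream,downstream window extents (default 100 each).
#' @return object of class `pairing_profile`: list with `gene_id`,
#'   `offsets`, `p_paired`, `complete`.
#' @export
fold_tir <- function(genome, gene, model = folding_model(),
                     upstream = 100, downstream = 100) {
  w <- extract_tir_window(genome, gene, upstream, downstream)
  if (grepl("N", w$sequence, fixed = TRUE)) {
    stop("fold_tir: window for ", w$gene_id, " contains N")
  }
  pf <- partition_function(w$sequence, model)
  structure(list(gene_id = w$gene_id, offsets = w$offsets,
                 p_paired = pf$p_paired, complete = w$complete),
            class = "pairing_profile")
}

#' @export
print.pairing_profile <- function(x, ...) {
  cat(sprintf("pairing_profile for %s: offsets %d..%d, mean p = %.3f%s\n",
              x$gene_id, min(x$offsets), max(x$offsets), mean(x$p_paired),
              if (!x$complete) " (truncated window)" else ""))
  invisible(x)
}

#' Fold TIR windows for many genes
#'
#' Genes whose windows contain N are skipped with a message.
#'
#' @inheritParams fold_tir
#' @param genes annotation data.frame.
#' @return named list of `pairing_profile`s.
#' @export
fold_tir_set <- function(genome, genes, model = folding_model(),
                         upstream = 100, downstream = 100) {
  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    w <- extract_tir_window(genome, genes[i, ], upstream, downstream)
    if (grepl("N", w$sequence, fixed = TRUE)) {
      skipped <- c(skipped, w$gene_id)
      next
    }
    pf <- partition_function(w$sequence, model)
    out[[w$gene_id]] <- structure(
      list(gene_id = w$gene_id, offsets = w$offsets,
           p_paired = pf$p_paired, complete = w$complete),
      class = "pairing_profile")
  }
  if (length(skipped)) {
    message("fold_tir_set: skipped ", length(skipped),
            " window(s) containing N")
  }
  out
}

#' Read externally computed pairing profiles
#'
#' Adapter for substituting an external folder's output: TSV with columns
#' `gene_id`, `offset`, `p_paired`.
#'
#' @param path TSV path.
#' @return named list of `pairing_profile`s.
#' @export
read_pairing_profiles <- function(path) {
  df <- read_tsv_report(path)
  need <- c("gene_id", "offset", "p_paired")
  if (!all(need %in% names(df))) {
    stop("pairing profile table must have columns ",
         paste(need, collapse = ", "))
  }
  lapply(split(df, df$gene_id), function(d) {
    d <- d[order(d$offset), ]
    structure(list(gene_id = d$gene_id[1], offsets = as.integer(d$offset),
                   p_paired = as.numeric(d$p_paired), complete = NA),
              class = "pairing_profile")
  })
}

# matrix genes x positions of p_paired values, NA outside each profile
.profile_matrix <- function(profiles, positions) {
  M <- matrix(NA_real_, nrow = length(profiles), ncol = length(positions),
              dimnames = list(names(profiles), positions))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    idx <- match(positions, p$offsets)
    ok <- !is.na(idx)
    M[i, ok] <- p$p_paired[idx[ok]]
  }
  M
}

#' Average pairing probability per position, by gene set, with contrast
#'
#' Positionwise mean of the per-gene pairing probabilities within each
#' group, plus a positionwise two-sample t-test between two chosen groups
#' with Bonferroni correction over the positions tested.
#'
#' @param groups named list of profile lists (e.g.
#'   `list(octile1 = ..., octile8 = ...)`), each from [fold_tir_set()].
#' @param positions offsets to summarise; default: every offset observed.
#' @param contrast indices (or names) of the two groups to compare; default
#'   first vs last.
#' @param alpha family-wise error rate.
#' @return object of class `pairing_summary`: list with `positions`, `mean`
#'   (groups x positions matrix), `n` (same shape) and `contrast`
#'   (data.frame: `position`, `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`).
#' @export
average_pairing_by_set <- function(groups, positions = NULL,
                                   contrast = c(1, length(groups)),
                                   alpha = 0.05) {
  stopifnot(length(groups) >= 1, all(lengths(groups) >= 1))
  if (is.null(positions)) {
    positions <- sort(unique(unlist(lapply(groups, function(g) {
      unlist(lapply(g, `[[`, "offsets"))
    }))))
  }
  mats <- lapply(groups, .profile_matrix, positions = positions)
  mean_mat <- do.call(rbind, lapply(mats, function(M) {
    colMeans(M, na.rm = TRUE)
  }))
  n_mat <- do.call(rbind, lapply(mats, function(M) colSums(!is.na(M))))
  rownames(mean_mat) <- rownames(n_mat) <- names(groups)
  ctr <- NULL
  if (length(groups) >= 2) {
    Ma <- mats[[contrast[1]]]; Mb <- mats[[contrast[2]]]
    rows <- lapply(seq_along(positions), function(j) {
      xa <- Ma[, j]; xa <- xa[!is.na(xa)]
      xb <- Mb[, j]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2L || length(xb) < 2L) return(NULL)
      if (stats::var(xa) == 0 && stats::var(xb) == 0 && xa[1] != xb[1]) {
        return(NULL)  # untestable under the zero-variance rule
      }
      tt <- two_sample_t(xa, xb)
      data.frame(position = positions[j], mean_a = mean(xa),
                 mean_b = mean(xb), statistic = tt$statistic,
                 p_value = tt$p_value, stringsAsFactors = FALSE)
    })
    ctr <- do.call(rbind, rows)
    if (!is.null(ctr) && nrow(ctr)) {
      bc <- bonferroni(ctr$p_value, alpha)
      ctr$p_adjusted <- bc$adjusted
      ctr$significant <- ctr$p_value < bc$threshold
      attr(ctr, "m") <- bc$m
      attr(ctr, "threshold") <- bc$threshold
    }
  }
  structure(list(positions = positions, mean = mean_mat, n = n_mat,
                 contrast = ctr),
            class = "pairing_summary")
}

#' @export
print.pairing_summary <- function(x, ...) {
  cat(sprintf("pairing_summary: %d group(s), offsets %d..%d\n",
              nrow(x$mean), min(x$positions), max(x$positions)))
  if (!is.null(x$contrast)) {
    cat(sprintf("  contrast: %d positions tested, %d significant at alpha/m\n",
                nrow(x$contrast), sum(x$contrast$significant)))
  }
  invisible(x)
}
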