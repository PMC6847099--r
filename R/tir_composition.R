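# Positional nucleotide composition of TIR windows and octile contrasts.
#
# Frequencies are per-position proportions over the genes informative at
# that position: genes whose window is truncated at a position, or carries
# an N there, are excluded position-wise (not gene-wise).

# character matrix genes x positions from a list of tir_windows; NA where a
# window does not cover the position or the base is N
.window_base_matrix <- function(windows, positions) {
  M <- matrix(NA_character_, nrow = length(windows),
              ncol = length(positions),
              dimnames = list(names(windows), positions))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    idx <- match(positions, w$offsets)
    ch <- strsplit(w$sequence, "", fixed = TRUE)[[1]]
    ok <- !is.na(idx)
    M[i, ok] <- ch[idx[ok]]
  }
  M[M == "N"] <- NA_character_
  M
}

#' Positional nucleotide-frequency profile
#'
#' For every position `k` and base `b`, the fraction of informative genes
#' carrying `b` at offset `k` (offset 0 = first base of the start codon).
#' At each position the four frequencies sum to one.
#'
#' @param windows named list of `tir_window` objects (see [tir_windows()]).
#' @param positions integer offsets to profile (default `-30:30`).
#' @return object of class `positional_freq`: list with `positions`,
#'   `freq` (4 x P matrix, rows A/C/G/U) and `n` (informative genes per
#'   position).
#' @export
positional_frequencies <- function(windows, positions = -30:30) {
  if (!length(windows)) stop("positional_frequencies: no windows")
  M <- .window_base_matrix(windows, positions)
  n <- colSums(!is.na(M))
  freq <- sapply(seq_along(positions), function(j) {
    col <- M[, j]
    col <- col[!is.na(col)]
    if (!length(col)) return(rep(NA_real_, 4))
    tab <- table(factor(col, levels = BASES_RNA))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- BASES_RNA
  colnames(freq) <- positions
  structure(list(positions = positions, freq = freq, n = n),
            class = "positional_freq")
}

#' @export
print.positional_freq <- function(x, ...) {
  cat(sprintf("positional_freq over offsets %d..%d (%d positions)\n",
              min(x$positions), max(x$positions), length(x$positions)))
  invisible(x)
}

#' @export
as.data.frame.positional_freq <- function(x, ...) {
  data.frame(position = rep(x$positions, each = 4),
             base = rep(BASES_RNA, length(x$positions)),
             frequency = as.vector(x$freq),
             n = rep(unname(x$n), each = 4),
             stringsAsFactors = FALSE)
}

#' Octile contrast of per-position base frequencies
#'
#' At every position, genes of the two groups are encoded as 0/1 indicators
#' ("gene has `base` at this offset") and compared with a two-sample t-test
#' (a comparison of two Bernoulli proportions); p-values are Bonferroni-
#' corrected over the positions tested.  Positions where either group has
#' fewer than two informative genes are skipped.
#'
#' @param windows_a,windows_b named lists of `tir_window`s for the two gene
#'   groups (conventionally octile 1 and octile 8).
#' @param positions offsets to test (default `-30:30`).
#' @param base nucleotide tested (default `"A"`).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param var_equal passed to [two_sample_t()].
#' @return data.frame with one row per tested position: `position`, `base`,
#'   `freq_a`, `freq_b`, `n_a`, `n_b`, `statistic`, `p_value`, `p_adjusted`,
#'   `significant`.  Attributes `m` (tests performed) and `threshold`
#'   (= alpha/m) record the correction.
#' @export
octile_contrast <- function(windows_a, windows_b, positions = -30:30,
                            base = "A", alpha = 0.05, var_equal = FALSE) {
  if (!length(windows_a) || !length(windows_b)) {
    stop("octile_contrast: both gene groups must be nonempty")
  }
  Ma <- .window_base_matrix(windows_a, positions)
  Mb <- .window_base_matrix(windows_b, positions)
  rows <- lapply(seq_along(positions), function(j) {
    xa <- Ma[, j]; xa <- as.numeric(xa[!is.na(xa)] == base)
    xb <- Mb[, j]; xb <- as.numeric(xb[!is.na(xb)] == base)
    if (length(xa) < 2L || length(xb) < 2L) return(NULL)
    tt <- two_sample_t(xa, xb, var_equal = var_equal)
    data.frame(position = positions[j], base = base,
               freq_a = mean(xa), freq_b = mean(xb),
               n_a = length(xa), n_b = length(xb),
               statistic = tt$statistic, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("octile_contrast: no testable positions")
  bc <- bonferroni(out$p_value, alpha)
  out$p_adjusted <- bc$adjusted
  out$significant <- out$p_value < bc$threshold
  attr(out, "m") <- bc$m
  attr(out, "threshold") <- bc$threshold
  attr(out, "alpha") <- alpha
  out[order(out$position), ]
}

#' Frequency of one base at one offset, per octile
#'
#' Convenience for trend plots of, e.g., A at -3 versus octile rank.
#'
#' @param windows_by_octile list of window lists, indexed by octile (1 =
#'   highest ARD).
#' @param offset single offset.
#' @param base nucleotide.
#' @return data.frame with `octile`, `frequency`, `n`.
#' @export
octile_base_trend <- function(windows_by_octile, offset, base = "A") {
  rows <- lapply(seq_along(windows_by_octile), function(o) {
    M <- .window_base_matrix(windows_by_octile[[o]], offset)
    col <- M[, 1]; col <- col[!is.na(col)]
    data.frame(octile = o, frequency = mean(col == base), n = length(col))
  })
  do.call(rbind, rows)
}
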