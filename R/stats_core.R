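# Small statistical kernel shared by the analysis stages: one- and
# two-sample t-tests, Bonferroni correction, Spearman correlation.  The
# heavy lifting is delegated to stats::t.test / stats::cor; what lives here
# is the degenerate-input policy the pipeline relies on.

new_tir_test <- function(statistic, p_value, n1, n2 = NA_integer_,
                         df = NA_real_, method = "welch") {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, df = df, method = method),
            class = "tir_test")
}

#' Two-sample t-test (Welch by default)
#'
#' Two-sided test of equal means.  Welch's unequal-variance form is the
#' default because the gene groups compared here (e.g. expression octiles)
#' have no reason to share a variance; a pooled-variance form is available
#' for sensitivity analysis.
#'
#' Degenerate inputs: samples smaller than 2 are an error; two constant
#' samples with the same value give statistic 0 and p = 1; two constant
#' samples with different values are an error (no finite statistic exists).
#' A single constant sample is fine — the Welch standard error is then
#' carried by the other sample alone, which matters when the inputs are
#' 0/1 indicators and one group happens to be all-0 or all-1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance form instead of Welch.
#' @return object of class `tir_test` with fields `statistic`, `p_value`,
#'   `n1`, `n2`, `df`, `method`.
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("two_sample_t: each sample needs at least 2 observations")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (x[1] == y[1]) {
      return(new_tir_test(0, 1, length(x), length(y),
                          method = if (var_equal) "pooled" else "welch"))
    }
    stop("two_sample_t: zero variance in both samples")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  new_tir_test(unname(tt$statistic), tt$p.value, length(x), length(y),
               df = unname(tt$parameter),
               method = if (var_equal) "pooled" else "welch")
}

#' One-sample t-test
#'
#' Two-sided test of H0: mean(x) = `mu0`.
#'
#' @param x numeric vector of length >= 2 with nonzero variance.
#' @param mu0 null mean.
#' @return object of class `tir_test`.
#' @export
one_sample_t <- function(x, mu0) {
  if (length(x) < 2L) {
    stop("one_sample_t: need at least 2 observations")
  }
  if (stats::var(x) == 0) stop("one_sample_t: zero variance")
  tt <- stats::t.test(x, mu = mu0)
  new_tir_test(unname(tt$statistic), tt$p.value, length(x),
               df = unname(tt$parameter), method = "one-sample")
}

#' @export
print.tir_test <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, p = %.4g (n1 = %d%s)\n",
              x$method, x$statistic, x$p_value, x$n1,
              if (!is.na(x$n2)) paste0(", n2 = ", x$n2) else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param alpha family-wise error rate in (0, 1).
#' @return list with `threshold` (= `alpha / m`), `adjusted`
#'   (= `min(1, p * m)`) and `m` (= `length(p)`).
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("bonferroni: empty p-value list")
  if (any(p < 0 | p > 1)) stop("bonferroni: p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("bonferroni: alpha must lie in (0, 1)")
  m <- length(p)
  list(threshold = alpha / m,
       adjusted = stats::p.adjust(p, method = "bonferroni"),
       m = m)
}

#' Spearman rank correlation
#'
#' Average ranks are used for ties (the standard `stats::cor` behaviour).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation coefficient in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_cor: length mismatch")
  if (length(x) < 3L) stop("spearman_cor: need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("spearman_cor: constant input")
  }
  stats::cor(x, y, method = "spearman")
}
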