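## Shared statistical primitives used by every analysis arm.

new_test_result <- function(ht, a, b, method) {
  structure(
    list(statistic = unname(ht$statistic),
         p_value   = unname(ht$p.value),
         df        = unname(ht$parameter),
         mean_a    = mean(a),
         mean_b    = mean(b),
         n_a       = length(a),
         n_b       = length(b),
         method    = method),
    class = "immunoflux_test")
}

#' @export
print.immunoflux_test <- function(x, ...) {
  cat(sprintf("%s: t = %.4f, df = %.2f, p = %.4g\n", x$method, x$statistic,
              x$df, x$p_value))
  cat(sprintf("  mean_a = %.4f (n = %d), mean_b = %.4f (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

check_two_samples <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    iflux_input_error("t-test inputs must be finite and non-missing")
  if (length(a) < 2 || length(b) < 2)
    iflux_input_error("each group needs at least 2 observations")
  if (var(a) == 0 && var(b) == 0)
    iflux_degenerate_error(
      "both groups have zero variance; the t statistic is undefined")
  list(a = a, b = b)
}

#' Welch's two-sample t-test
#'
#' Two-tailed comparison of two group means without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom). Used for the respirometry group
#' comparisons, where donor-level variances differ between age groups.
#'
#' @param a,b Numeric vectors (length >= 2) of finite observations.
#' @return An object of class `immunoflux_test` with fields `statistic`,
#'   `p_value`, `df`, `mean_a`, `mean_b`, `n_a`, `n_b`. The statistic has the
#'   sign of `mean(a) - mean(b)`.
#' @export
#' @examples
#' welch_ttest(c(10, 11, 12, 13), c(20, 21, 22, 23))
welch_ttest <- function(a, b) {
  s <- check_two_samples(a, b)
  ht <- t.test(s$a, s$b, var.equal = FALSE)
  new_test_result(ht, s$a, s$b, "Welch two-sample t-test")
}

#' Student's two-sample t-test (pooled variance)
#'
#' Two-tailed equal-variance comparison, df = n_a + n_b - 2. Used for the
#' proteomics ratio statistics, the morphometry comparisons and the mitophagy
#' bin-fraction contrasts.
#'
#' @inheritParams welch_ttest
#' @return An `immunoflux_test` object; see [welch_ttest()].
#' @export
student_ttest <- function(a, b) {
  s <- check_two_samples(a, b)
  ht <- t.test(s$a, s$b, var.equal = TRUE)
  new_test_result(ht, s$a, s$b, "Student two-sample t-test")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    iflux_input_error("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sided standard-normal tail probability
#'
#' Converts a Z statistic to a two-sided p-value, as used for PAGE enrichment
#' scores.
#'
#' @param z Finite numeric vector of Z statistics.
#' @return Two-sided p-values, `2 * pnorm(-|z|)`.
#' @export
normal_ztest_p <- function(z) {
  if (any(!is.finite(z))) iflux_input_error("z must be finite")
  2 * pnorm(-abs(z))
}
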