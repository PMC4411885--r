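# Fisher's method for comparing two independent correlations.
#
# The test transforms each correlation to the variance-stabilized scale
# z' = 0.5 * log((1 + r)/(1 - r)) and refers the standardized difference
# (z1' - z2') / sqrt(1/(n1 - 3) + 1/(n2 - 3)) to the standard normal
# distribution. Throughout this package the test is one-tailed: the
# working hypothesis is directional (MZ pairs at least as correlated as
# DZ pairs), so p = P(Z > z) under the null of equal population
# correlations.

#' Fisher's r-to-z' transformation
#'
#' Transforms a product-moment or intraclass correlation to the
#' variance-stabilized scale `0.5 * log((1 + r) / (1 - r))` (the inverse
#' hyperbolic tangent). The transform is strictly increasing and odd, and
#' is undefined at `r = +/-1`.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @return Numeric vector of transformed values.
#' @seealso [fisher_rz_inverse()], [compare_correlations()]
#' @examples
#' fisher_rz(0.62)
#' fisher_rz(c(-0.5, 0, 0.5))
#' @export
fisher_rz <- function(r) {
  if (!is.numeric(r)) {
    stop("`r` must be numeric, got ", class(r)[1], call. = FALSE)
  }
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse of the Fisher transformation
#'
#' Maps a value on the z' scale back to a correlation (the hyperbolic
#' tangent).
#'
#' @param zprime Numeric vector on the transformed scale.
#' @return Numeric vector of correlations in (-1, 1).
#' @export
fisher_rz_inverse <- function(zprime) {
  if (!is.numeric(zprime)) {
    stop("`zprime` must be numeric", call. = FALSE)
  }
  tanh(zprime)
}

#' Compare two independent correlations
#'
#' Fisher's two-sample z-test for the difference between two correlations
#' estimated on independent samples. Used here to compare the intraclass
#' correlation of monozygotic pairs (`r1`, from `n1` pairs) with that of
#' dizygotic pairs (`r2`, from `n2` pairs). The returned p-value is
#' one-tailed (upper tail): small values indicate `r1 > r2` beyond chance.
#'
#' All arguments are vectorized and recycled to a common length, so a
#' whole table of comparisons can be tested in one call.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Number of pairs behind each correlation; must exceed 3
#'   because the sampling variance of z' is 1/(n - 3).
#' @return A data frame of class `"fisher_test"` with columns `r1`, `n1`,
#'   `r2`, `n2`, `z1_prime`, `z2_prime`, `z` and `p_one_tailed`.
#' @examples
#' compare_correlations(0.62, 709, 0.42, 629)  # z = 5.05
#' compare_correlations(0.68, 923, 0.52, 525)  # z = 4.61
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (!is.numeric(n1) || !is.numeric(n2)) {
    stop("pair counts must be numeric", call. = FALSE)
  }
  if (any(!is.finite(n1)) || any(!is.finite(n2)) ||
      any(n1 <= 3) || any(n2 <= 3)) {
    stop("pair counts must exceed 3 (the z' variance is 1/(n - 3))",
         call. = FALSE)
  }
  z1 <- fisher_rz(r1)
  z2 <- fisher_rz(r2)
  out <- data.frame(
    r1 = r1, n1 = n1, r2 = r2, n2 = n2,
    z1_prime = z1, z2_prime = z2,
    z = (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  )
  out$p_one_tailed <- stats::pnorm(out$z, lower.tail = FALSE)
  class(out) <- c("fisher_test", "data.frame")
  out
}

#' Significance flag for a Fisher comparison
#'
#' `TRUE` when the one-tailed p-value is strictly below `alpha`. At
#' `alpha = 0.05` this is equivalent to `z > 1.645` (one-tailed critical
#' value); the boundary itself is not significant.
#'
#' @param test A `"fisher_test"` object from [compare_correlations()].
#' @param alpha Significance level, strictly between 0 and 1.
#' @return Logical vector, one element per comparison.
#' @export
is_significant <- function(test, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.null(test$p_one_tailed)) {
    stop("`test` must carry a `p_one_tailed` column; see compare_correlations()",
         call. = FALSE)
  }
  test$p_one_tailed < alpha
}

#' Banded p-value display
#'
#' Formats one-tailed p-values the way meta-analytic correlation tables
#' print them: `"<0.0001"`, `"<0.001"`, the exact value to three decimals
#' when below `alpha`, and `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Level below which a value is reported numerically.
#' @return Character vector.
#' @export
format_p_band <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  vapply(p, function(pi) {
    if (pi >= alpha) "ns"
    else if (pi < 1e-4) "<0.0001"
    else if (pi < 1e-3) "<0.001"
    else sprintf("%.3f", pi)
  }, character(1))
}

#' @export
print.fisher_test <- function(x, digits = 2, ...) {
  cat("Fisher z-test for two independent correlations (one-tailed)\n")
  df <- data.frame(
    r1 = x$r1, n1 = x$n1, r2 = x$r2, n2 = x$n2,
    z = round(x$z, digits),
    p = format_p_band(x$p_one_tailed)
  )
  print(df, row.names = FALSE, ...)
  invisible(x)
}
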