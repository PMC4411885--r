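# Intraclass correlation estimators for exchangeable twin pairs.
#
# Twins within a pair have no natural order, so the plain Pearson
# correlation of (twin1, twin2) depends on an arbitrary labelling. The
# default estimator removes that dependence by double entry: each pair
# contributes both (x1, x2) and (x2, x1) to a Pearson correlation. The
# one-way ANOVA estimator (MSB - MSW) / (MSB + MSW) is provided as a
# cross-check; the two agree asymptotically.

check_pairs <- function(x1, x2, min_pairs = 2L) {
  if (length(x1) != length(x2)) {
    stop("`x1` and `x2` must have equal length (one value per twin)",
         call. = FALSE)
  }
  if (length(x1) < min_pairs) {
    stop("need at least ", min_pairs, " pairs", call. = FALSE)
  }
  if (anyNA(x1) || anyNA(x2)) {
    stop("pair values must not contain NA", call. = FALSE)
  }
}

#' Double-entry intraclass correlation
#'
#' Pearson correlation on the double-entered data: each pair (x1, x2)
#' contributes both orderings, so the estimate is invariant to how twins
#' are labelled within a pair. Works for continuous scores and for 0/1
#' exposure indicators (where it is a phi-type coefficient).
#'
#' @param x1,x2 Numeric vectors, one value per twin; element i of each is
#'   the same pair.
#' @return The intraclass correlation, in `[-1, 1]`.
#' @examples
#' icc_double_entry(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
icc_double_entry <- function(x1, x2) {
  check_pairs(x1, x2)
  a <- c(x1, x2)
  if (stats::sd(a) == 0) {
    stop("zero variance: intraclass correlation undefined", call. = FALSE)
  }
  stats::cor(a, c(x2, x1))
}

#' One-way ANOVA intraclass correlation
#'
#' `(MSB - MSW) / (MSB + MSW)` from the between-pair and within-pair mean
#' squares of the one-way random-effects layout with two observations per
#' group. Agrees with [icc_double_entry()] as the number of pairs grows.
#'
#' @inheritParams icc_double_entry
#' @return The intraclass correlation, in `[-1, 1]`.
#' @export
icc_anova <- function(x1, x2) {
  check_pairs(x1, x2)
  n <- length(x1)
  msb <- 2 * stats::var((x1 + x2) / 2)
  msw <- sum((x1 - x2)^2 / 2) / n
  if (msb + msw == 0) {
    stop("zero variance: intraclass correlation undefined", call. = FALSE)
  }
  (msb - msw) / (msb + msw)
}

#' Read pair-level twin data from CSV
#'
#' Expects columns `pair_id`, `zygosity` (`mz`/`dz`), `twin1_value`,
#' `twin2_value`.
#'
#' @param path CSV file path.
#' @return A data frame with the four columns.
#' @export
read_pair_sample <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("pair_id", "zygosity", "twin1_value", "twin2_value"),
             basename(path))
  bad <- which(!df$zygosity %in% c("mz", "dz"))
  if (length(bad)) {
    row_fail(basename(path), bad[1], df$pair_id[bad[1]], "zygosity",
             "must be 'mz' or 'dz'")
  }
  df
}

#' Write pair-level twin data to CSV
#'
#' @param df Data frame with `pair_id`, `zygosity`, `twin1_value`,
#'   `twin2_value`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_sample <- function(df, path) {
  check_cols(df, c("pair_id", "zygosity", "twin1_value", "twin2_value"),
             "pair sample")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
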