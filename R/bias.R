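# Consequences of unequal environments for twin-based heritability.
#
# Linear variance-components (ACE) model for a standardized trait:
#   y = sqrt(h2) * A + sqrt(c2) * C + sqrt(e2) * E,
# where A correlates 1 within MZ pairs and 0.5 within DZ pairs, E is
# independent across twins, and the "shared" environmental component C is
# allowed a zygosity-specific within-pair correlation rho_env_mz /
# rho_env_dz. The equal-environment assumption is rho_env_mz ==
# rho_env_dz (classically both 1). Expected trait correlations are then
#   r_mz = h2 + c2 * rho_env_mz,   r_dz = h2 / 2 + c2 * rho_env_dz,
# so the Falconer estimate 2 * (r_mz - r_dz) equals
#   h2 + 2 * c2 * (rho_env_mz - rho_env_dz):
# the estimate is inflated by twice the shared-environment variance times
# the environmental-correlation gap.

#' ACE configuration with zygosity-specific environmental correlations
#'
#' @param h2 Additive-genetic variance share in `[0, 1]`.
#' @param c2 Shared-environment variance share in `[0, 1]`.
#' @param e2 Residual share; defaults to `1 - h2 - c2`. The three shares
#'   must sum to 1 (tolerance 1e-9).
#' @param rho_env_mz,rho_env_dz Within-pair correlations of the
#'   environmental component C for MZ and DZ pairs, in `[0, 1]`. Equal
#'   values encode the equal-environment assumption.
#' @param seed Integer seed (used by [simulate_falconer_bias()]).
#' @return A validated list of class `"ace_config"`.
#' @examples
#' ace_config(h2 = 0.3, c2 = 0.4, rho_env_mz = 0.6, rho_env_dz = 0.4)
#' @export
ace_config <- function(h2, c2, e2 = 1 - h2 - c2,
                       rho_env_mz = 1, rho_env_dz = 1, seed = 1L) {
  for (v in list(rho_env_mz = rho_env_mz, rho_env_dz = rho_env_dz)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("environmental correlations must lie in [0, 1]", call. = FALSE)
    }
  }
  if (abs(h2 + c2 + e2 - 1) > 1e-9 ||
      any(!is.finite(c(h2, c2, e2)) | c(h2, c2, e2) < 0 |
            c(h2, c2, e2) > 1)) {
    stop("variance shares must each lie in [0, 1] and sum to 1 ",
         sprintf("(h2 = %g, c2 = %g, e2 = %g)", h2, c2, e2), call. = FALSE)
  }
  structure(
    list(h2 = h2, c2 = c2, e2 = e2,
         rho_env_mz = rho_env_mz, rho_env_dz = rho_env_dz,
         seed = as.integer(seed)),
    class = "ace_config"
  )
}

#' Falconer heritability estimate
#'
#' Twice the difference between the MZ and DZ correlations,
#' `2 * (r_mz - r_dz)`. The value may fall outside `[0, 1]`; it is
#' returned as-is (callers can flag out-of-range estimates).
#'
#' @param r_mz,r_dz Twin-pair correlations in `[-1, 1]`.
#' @return The heritability estimate.
#' @examples
#' falconer_h2(0.67, 0.39)  # 0.56
#' @export
falconer_h2 <- function(r_mz, r_dz) {
  stopifnot(is.numeric(r_mz), is.numeric(r_dz),
            all(abs(r_mz) <= 1), all(abs(r_dz) <= 1))
  2 * (r_mz - r_dz)
}

#' Expected twin correlations and Falconer bias under the ACE model
#'
#' Closed form for the model described above: the expected MZ and DZ
#' trait correlations, the Falconer estimate they imply, and its bias
#' relative to the true `h2` (which equals
#' `2 * c2 * (rho_env_mz - rho_env_dz)`).
#'
#' @param config An [ace_config()].
#' @return A list of class `"bias_result"` with `expected_r_mz`,
#'   `expected_r_dz`, `falconer_h2`, `bias`, and `in_range` (whether the
#'   estimate lies in `[0, 1]`).
#' @examples
#' expected_twin_correlations(
#'   ace_config(h2 = 0, c2 = 0.5, rho_env_mz = 0.67, rho_env_dz = 0.39)
#' )$bias  # 0.28
#' @export
expected_twin_correlations <- function(config) {
  if (!inherits(config, "ace_config")) {
    config <- do.call(ace_config, config)
  }
  r_mz <- config$h2 + config$c2 * config$rho_env_mz
  r_dz <- 0.5 * config$h2 + config$c2 * config$rho_env_dz
  est <- falconer_h2(r_mz, r_dz)
  structure(
    list(expected_r_mz = r_mz, expected_r_dz = r_dz,
         falconer_h2 = est, bias = est - config$h2,
         in_range = est >= 0 && est <= 1),
    class = "bias_result"
  )
}

#' Monte-Carlo check of the Falconer bias
#'
#' Simulates trait values for MZ and DZ pairs under the ACE model
#' (genetic component correlated 1 / 0.5, environmental component
#' correlated `rho_env_mz` / `rho_env_dz`, residual independent),
#' estimates the twin correlations per replicate with
#' [icc_double_entry()], and summarizes the Falconer estimates. The mean
#' agrees with [expected_twin_correlations()] to Monte-Carlo error.
#'
#' @param config An [ace_config()].
#' @param n_pairs_per_zygosity Pairs per zygosity per replicate (>= 100).
#' @param n_replicates Number of replicates (>= 10).
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `mean_falconer`, `sd_falconer`, `mean_bias`,
#'   `mean_r_mz`, `mean_r_dz`, `n_pairs_per_zygosity`, `n_replicates`.
#' @export
simulate_falconer_bias <- function(config, n_pairs_per_zygosity = 5000L,
                                   n_replicates = 100L, seed = config$seed) {
  if (!inherits(config, "ace_config")) {
    config <- do.call(ace_config, config)
  }
  stopifnot(n_pairs_per_zygosity >= 100, n_replicates >= 10)
  set.seed(seed)
  n <- n_pairs_per_zygosity
  draw_zygosity <- function(r_a, rho_env) {
    a <- rnorm_pairs(n, r_a)
    cc <- rnorm_pairs(n, rho_env)
    y1 <- sqrt(config$h2) * a[, 1] + sqrt(config$c2) * cc[, 1] +
      sqrt(config$e2) * stats::rnorm(n)
    y2 <- sqrt(config$h2) * a[, 2] + sqrt(config$c2) * cc[, 2] +
      sqrt(config$e2) * stats::rnorm(n)
    icc_double_entry(y1, y2)
  }
  r_mz <- numeric(n_replicates)
  r_dz <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    r_mz[i] <- draw_zygosity(1, config$rho_env_mz)
    r_dz[i] <- draw_zygosity(0.5, config$rho_env_dz)
  }
  est <- falconer_h2(r_mz, r_dz)
  list(
    mean_falconer = mean(est),
    sd_falconer = stats::sd(est),
    mean_bias = mean(est) - config$h2,
    mean_r_mz = mean(r_mz),
    mean_r_dz = mean(r_dz),
    n_pairs_per_zygosity = n,
    n_replicates = n_replicates
  )
}

#' Closed-form bias over a parameter grid
#'
#' Expands a grid of variance shares and environmental correlations and
#' evaluates [expected_twin_correlations()] on every combination
#' (combinations with `h2 + c2 > 1` are dropped).
#'
#' @param h2,c2 Numeric vectors of variance shares.
#' @param rho_env_mz,rho_env_dz Numeric vectors of environmental
#'   correlations.
#' @return A data frame with one row per retained combination: the four
#'   parameters, `expected_r_mz`, `expected_r_dz`, `falconer_h2`, `bias`.
#' @export
falconer_bias_grid <- function(h2 = c(0, 0.3, 0.6),
                               c2 = c(0.2, 0.3, 0.4),
                               rho_env_mz = 0.67, rho_env_dz = 0.39) {
  grid <- expand.grid(h2 = h2, c2 = c2, rho_env_mz = rho_env_mz,
                      rho_env_dz = rho_env_dz, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$h2 + grid$c2 <= 1, , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    b <- expected_twin_correlations(
      ace_config(grid$h2[i], grid$c2[i],
                 rho_env_mz = grid$rho_env_mz[i],
                 rho_env_dz = grid$rho_env_dz[i])
    )
    data.frame(expected_r_mz = b$expected_r_mz,
               expected_r_dz = b$expected_r_dz,
               falconer_h2 = b$falconer_h2, bias = b$bias)
  })
  cbind(grid, do.call(rbind, res))
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(
    "Expected twin correlations: r_mz = %.4f, r_dz = %.4f\n", x$expected_r_mz,
    x$expected_r_dz))
  cat(sprintf("Falconer h2 = %.4f (bias %+.4f)%s\n", x$falconer_h2, x$bias,
              if (x$in_range) "" else "  [outside [0, 1]]"))
  invisible(x)
}
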