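# Synthetic twin-pair exposure data and whole meta-analytic corpora.
#
# Exposure model: per pair, an exchangeable bivariate standard normal
# with correlation equal to the target intraclass correlation
# (x_j = sqrt(rho) * shared + sqrt(1 - rho) * unique_j). Binary exposures
# dichotomize the latent values at the threshold giving the target
# prevalence; the reported r is then a phi-type ICC, attenuated relative
# to the latent correlation, with the latent truth logged alongside.
# Seeds are explicit; a corpus derives one substream per study by stable
# hashing of the study_id, so corpora are byte-identical given a seed.

#' Configuration for one simulated twin study
#'
#' @param study_id Short key; also drives the per-study seed substream in
#'   [simulate_meta_corpus()].
#' @param n_mz_pairs,n_dz_pairs Pair counts (at least 4).
#' @param true_icc_mz,true_icc_dz Target within-pair correlations on the
#'   latent scale, in `[0, 1)`. Defaults are the pooled bullying values
#'   of the packaged corpus (0.67 MZ, 0.39 DZ).
#' @param exposure_kind `"continuous"` or `"binary"`.
#' @param prevalence Exposure prevalence for binary data, in (0, 1).
#' @param seed Integer seed for [simulate_pairs()].
#' @return A validated list of class `"sim_study_config"`.
#' @export
sim_study_config <- function(study_id = "sim1",
                             n_mz_pairs = 500L, n_dz_pairs = 500L,
                             true_icc_mz = 0.67, true_icc_dz = 0.39,
                             exposure_kind = c("continuous", "binary"),
                             prevalence = 0.5, seed = 1L) {
  exposure_kind <- match.arg(exposure_kind)
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  if (n_mz_pairs < 4 || n_dz_pairs < 4) {
    stop("pair counts must be at least 4", call. = FALSE)
  }
  for (icc in c(true_icc_mz, true_icc_dz)) {
    if (!is.finite(icc) || icc < 0 || icc >= 1) {
      stop("true ICCs must lie in [0, 1)", call. = FALSE)
    }
  }
  if (exposure_kind == "binary" &&
      (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(study_id = study_id,
         n_mz_pairs = as.integer(n_mz_pairs),
         n_dz_pairs = as.integer(n_dz_pairs),
         true_icc_mz = true_icc_mz, true_icc_dz = true_icc_dz,
         exposure_kind = exposure_kind, prevalence = prevalence,
         seed = as.integer(seed)),
    class = "sim_study_config"
  )
}

#' Correlated pair values
#'
#' n exchangeable pairs from a bivariate standard normal with the given
#' within-pair correlation. Internal building block shared by the corpus
#' simulator and the heritability-bias module.
#'
#' @param n Number of pairs.
#' @param rho Within-pair correlation in `[0, 1)`.
#' @return An n x 2 matrix.
#' @noRd
rnorm_pairs <- function(n, rho) {
  g <- stats::rnorm(n)
  cbind(sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n),
        sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n))
}

#' Simulate pair-level exposures for one study
#'
#' Draws MZ and DZ pair values from the exchangeable bivariate normal
#' model of the config, optionally dichotomized at the threshold giving
#' the target prevalence. Deterministic given `config$seed`.
#'
#' @param config A [sim_study_config()].
#' @return A list of class `"twin_pair_sim"` with data frames `mz` and
#'   `dz` (columns `x1`, `x2`) and the config attached.
#' @export
simulate_pairs <- function(config) {
  if (!inherits(config, "sim_study_config")) {
    config <- do.call(sim_study_config, config)
  }
  set.seed(config$seed)
  draw <- function(n, rho) {
    xy <- rnorm_pairs(n, rho)
    if (config$exposure_kind == "binary") {
      thr <- stats::qnorm(config$prevalence, lower.tail = FALSE)
      xy <- (xy > thr) * 1
    }
    data.frame(x1 = xy[, 1], x2 = xy[, 2])
  }
  structure(
    list(mz = draw(config$n_mz_pairs, config$true_icc_mz),
         dz = draw(config$n_dz_pairs, config$true_icc_dz),
         config = config),
    class = "twin_pair_sim"
  )
}

# Deterministic 31-bit hash of a string key, used to derive per-study
# seed substreams from one master seed.
stable_hash <- function(key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Derive a per-study seed from a master seed
#'
#' @param seed Master integer seed.
#' @param key Study id.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + stable_hash(key)) %% 2147483647)
}

#' Simulate a whole meta-analytic corpus
#'
#' Simulates every study in `configs`, estimates each study's MZ and DZ
#' intraclass correlations with [icc_double_entry()], and assembles a
#' dataset in the schema of [load_twin_dataset()] (one comparison per
#' study; constructs grouping the studies by their assigned labels, with
#' unique pair counts summed over member studies). The result validates
#' and runs through the pooling analysis end to end.
#'
#' @param configs List of [sim_study_config()] objects (or lists coercible
#'   to them).
#' @param construct_labels Character vector recycled over studies
#'   assigning each comparison to a construct.
#' @param seed Optional master seed; when given, each study's seed is
#'   re-derived as `derive_seed(seed, study_id)`, overriding per-config
#'   seeds.
#' @param dir Optional directory: when given, the corpus is also written
#'   as CSV via [write_twin_dataset()].
#' @return A `"twin_dataset"`; comparisons carry the estimated ICCs and
#'   extra columns `true_icc_mz`, `true_icc_dz` with the latent truth.
#' @export
simulate_meta_corpus <- function(configs, construct_labels = "general_trauma",
                                 seed = NULL, dir = NULL) {
  if (length(configs) == 0L) stop("need at least one config", call. = FALSE)
  configs <- lapply(configs, function(cf) {
    if (inherits(cf, "sim_study_config")) cf else do.call(sim_study_config, cf)
  })
  ids <- vapply(configs, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("duplicated study_id in configs", call. = FALSE)
  labels <- rep_len(construct_labels, length(configs))

  rows <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (!is.null(seed)) cf$seed <- derive_seed(seed, cf$study_id)
    sim <- simulate_pairs(cf)
    data.frame(
      comparison_id = paste0(cf$study_id, "_cmp"),
      study_id = cf$study_id,
      construct = labels[i],
      stratum_label = "all",
      r_mz = icc_double_entry(sim$mz$x1, sim$mz$x2),
      r_dz = icc_double_entry(sim$dz$x1, sim$dz$x2),
      n_mz_eff = cf$n_mz_pairs,
      n_dz_eff = cf$n_dz_pairs,
      gender = "mixed",
      uses_instrument = TRUE,
      informant = "twins",
      site = "us_canada",
      interview_age_band = "proximate_le19",
      size_group = "below",
      measure_description = paste0("simulated ", cf$exposure_kind,
                                   " exposure"),
      true_icc_mz = cf$true_icc_mz,
      true_icc_dz = cf$true_icc_dz,
      stringsAsFactors = FALSE
    )
  })
  comparisons <- do.call(rbind, rows)

  studies <- data.frame(
    study_id = ids,
    label = paste("simulated study", ids),
    n_mz_pairs = vapply(configs, `[[`, integer(1), "n_mz_pairs"),
    n_dz_pairs = vapply(configs, `[[`, integer(1), "n_dz_pairs"),
    site = "us_canada",
    informant = "twins",
    interview_age_band = "proximate_le19",
    country = "simulated",
    stringsAsFactors = FALSE
  )
  split_idx <- split(seq_along(ids), labels[seq_along(ids)])
  constructs <- do.call(rbind, lapply(names(split_idx), function(lb) {
    i <- split_idx[[lb]]
    data.frame(
      construct = lb,
      member_comparison_ids = paste(comparisons$comparison_id[i],
                                    collapse = ";"),
      n_mz_unique = sum(studies$n_mz_pairs[i]),
      n_dz_unique = sum(studies$n_dz_pairs[i]),
      stringsAsFactors = FALSE
    )
  }))

  ds <- structure(
    list(studies = studies, comparisons = comparisons,
         constructs = constructs, moderators = NULL),
    class = "twin_dataset"
  )
  validate_twin_dataset(ds)
  if (!is.null(dir)) write_twin_dataset(ds, dir)
  ds
}

#' Study configs mirroring the packaged corpus sizes
#'
#' Eleven configs with the packaged studies' MZ/DZ pair counts and a
#' common pair of true ICCs: `icc_dz` for DZ pairs and `icc_dz + icc_gap`
#' for MZ pairs. `icc_gap = 0` gives the null corpus used for
#' calibration.
#'
#' @param icc_dz Baseline within-pair correlation.
#' @param icc_gap Excess MZ correlation (0 under the null).
#' @return A list of [sim_study_config()] objects.
#' @export
corpus_configs <- function(icc_dz = 0.45, icc_gap = 0) {
  ds <- load_twin_dataset()
  lapply(seq_len(nrow(ds$studies)), function(i) {
    sim_study_config(
      study_id = ds$studies$study_id[i],
      n_mz_pairs = ds$studies$n_mz_pairs[i],
      n_dz_pairs = ds$studies$n_dz_pairs[i],
      true_icc_mz = icc_dz + icc_gap,
      true_icc_dz = icc_dz
    )
  })
}

#' Construct-level rejection rate over simulated corpora
#'
#' Simulates `n_replicates` corpora, runs the construct pooling on each
#' (unrounded pooled correlations, recomputed unique counts) and returns
#' the fraction of construct-level one-tailed Fisher tests with
#' `p < alpha`. With equal true ICCs this estimates the empirical size of
#' the pooled test; with a positive gap, its power.
#'
#' @param configs Study configs, e.g. [corpus_configs()].
#' @param n_replicates Number of corpora.
#' @param alpha Significance level.
#' @param seed Master seed; replicate r uses `seed + r` as its corpus
#'   seed.
#' @param construct_labels Construct assignment passed to
#'   [simulate_meta_corpus()]; the default spreads the studies over the
#'   five primary adversity constructs.
#' @return A list with `rejection_rate`, `n_tests`, `n_replicates`.
#' @export
estimate_rejection_rate <- function(configs, n_replicates = 200L,
                                    alpha = 0.05, seed = 1L,
                                    construct_labels = .PRIMARY_CONSTRUCTS) {
  stopifnot(n_replicates >= 1)
  p <- unlist(lapply(seq_len(n_replicates), function(r) {
    ds <- simulate_meta_corpus(configs, construct_labels,
                               seed = seed + r)
    analyze_constructs(ds, alpha = alpha, digits = NULL,
                       counts = "recompute")$p_one_tailed
  }))
  list(rejection_rate = mean(p < alpha), n_tests = length(p),
       n_replicates = n_replicates)
}
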