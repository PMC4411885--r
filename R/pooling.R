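# Pair-count-weighted pooling of intraclass correlations, construct and
# moderator analyses, and the corpus-level summary counts.
#
# Pooling convention: each comparison's correlation is weighted by its
# effective pair count, Sum(r_i * n_i) / Sum(n_i), separately per
# zygosity. Pooled correlations are rounded to 2 decimals BEFORE the
# Fisher test (digits = 2 default); this matches how the source tables
# were produced (unrounded pooling shifts e.g. the sexual-abuse z from
# 3.53 to 3.63). The n entering the pooled test is the number of UNIQUE
# pairs across the member studies, not the sum over (possibly
# overlapping) stratified comparisons.

#' Pair-count-weighted pooled correlation
#'
#' `sum(r * n) / sum(n)`: a fixed-weights aggregate of correlations with
#' pair counts as weights. Invariant to rescaling all weights by a
#' positive constant, and bounded by the member correlations.
#'
#' @param r Numeric vector of correlations, strictly inside (-1, 1).
#' @param n Numeric vector of positive weights (pair counts).
#' @return The pooled correlation (not rounded).
#' @examples
#' pool_weighted_r(c(0.60, 0.68), c(896, 923))  # 0.6406
#' @export
pool_weighted_r <- function(r, n) {
  if (length(r) == 0L) stop("empty member list", call. = FALSE)
  if (length(r) != length(n)) {
    stop("`r` and `n` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("weights must be counts of at least 1", call. = FALSE)
  }
  total <- sum(n)
  if (total <= 0) stop("zero total weight", call. = FALSE)
  sum(r * n) / total
}

round_or_keep <- function(x, digits) {
  if (is.null(digits)) x else round(x, digits)
}

pooled_result <- function(label, members, n_mz, n_dz, digits, alpha) {
  r_mz <- round_or_keep(pool_weighted_r(members$r_mz, members$n_mz_eff),
                        digits)
  r_dz <- round_or_keep(pool_weighted_r(members$r_dz, members$n_dz_eff),
                        digits)
  ft <- compare_correlations(r_mz, n_mz, r_dz, n_dz)
  data.frame(
    group_label = label,
    k_comparisons = nrow(members),
    weighted_r_mz = r_mz,
    weighted_r_dz = r_dz,
    n_mz_unique = n_mz,
    n_dz_unique = n_dz,
    z = ft$z,
    z_display = round(ft$z, 2),
    p_one_tailed = ft$p_one_tailed,
    p_display = format_p_band(ft$p_one_tailed, alpha),
    significant = ft$p_one_tailed < alpha,
    stringsAsFactors = FALSE
  )
}

#' Members of a construct
#'
#' @param ds A `"twin_dataset"`.
#' @param construct Construct name as in `ds$constructs`.
#' @return The comparison rows belonging to the construct, in fixture
#'   order.
#' @export
construct_members <- function(ds, construct) {
  i <- match(construct, ds$constructs$construct)
  if (is.na(i)) {
    stop("unknown construct '", construct, "'", call. = FALSE)
  }
  ids <- parse_members(ds$constructs$member_comparison_ids[i])[[1]]
  j <- match(ids, ds$comparisons$comparison_id)
  if (anyNA(j)) {
    stop("construct '", construct, "' references unknown comparison '",
         ids[is.na(j)][1], "'", call. = FALSE)
  }
  ds$comparisons[j, , drop = FALSE]
}

#' Pooled analysis of one adversity construct
#'
#' Pools the member comparisons' correlations per zygosity (each weighted
#' by its effective pair count), optionally rounds the pooled values, and
#' applies the one-tailed Fisher test with the construct's unique pair
#' counts.
#'
#' @param ds A `"twin_dataset"`.
#' @param construct Construct name.
#' @param alpha Significance level for the flag and p display.
#' @param digits Decimal places applied to the pooled correlations before
#'   testing; `NULL` to test unrounded values (used in simulations).
#' @param counts `"fixture"` to take the unique pair counts as stored
#'   (the printed values), `"recompute"` to sum the member studies' pair
#'   counts instead.
#' @return One-row data frame: `group_label`, `k_comparisons`,
#'   `weighted_r_mz`, `weighted_r_dz`, `n_mz_unique`, `n_dz_unique`, `z`,
#'   `z_display`, `p_one_tailed`, `p_display`, `significant`.
#' @examples
#' ds <- load_twin_dataset()
#' analyze_construct(ds, "sexual_abuse")$z_display  # 3.53
#' @export
analyze_construct <- function(ds, construct, alpha = 0.05, digits = 2,
                              counts = c("fixture", "recompute")) {
  counts <- match.arg(counts)
  i <- match(construct, ds$constructs$construct)
  if (is.na(i)) stop("unknown construct '", construct, "'", call. = FALSE)
  members <- construct_members(ds, construct)
  if (counts == "fixture") {
    n_mz <- ds$constructs$n_mz_unique[i]
    n_dz <- ds$constructs$n_dz_unique[i]
  } else {
    st <- unique(members$study_id)
    n_mz <- sum(ds$studies$n_mz_pairs[ds$studies$study_id %in% st])
    n_dz <- sum(ds$studies$n_dz_pairs[ds$studies$study_id %in% st])
  }
  pooled_result(construct, members, n_mz, n_dz, digits, alpha)
}

#' Pooled analysis of every construct
#'
#' @inheritParams analyze_construct
#' @return A data frame with one row per construct, in fixture order.
#' @export
analyze_constructs <- function(ds, alpha = 0.05, digits = 2,
                               counts = c("fixture", "recompute")) {
  counts <- match.arg(counts)
  out <- lapply(ds$constructs$construct, analyze_construct, ds = ds,
                alpha = alpha, digits = digits, counts = counts)
  do.call(rbind, out)
}

#' Pooled analysis of the moderator subgroups
#'
#' For each moderator level defined in `ds$moderators`, pools the
#' correlations of the comparisons in that level (all adversity types
#' collapsed) and runs the one-tailed Fisher test with the level's unique
#' pair counts as stored in the fixture.
#'
#' @inheritParams analyze_construct
#' @param pooled `"recompute"` pools the member correlations from the
#'   fixture (rounded to `digits`); `"printed"` takes the pooled
#'   correlations stored in `ds$moderators` as direct inputs.
#' @return A data frame with one row per moderator level; columns as in
#'   [analyze_construct()] plus `parameter`.
#' @examples
#' ds <- load_twin_dataset()
#' mods <- analyze_moderators(ds, pooled = "printed")
#' range(mods$z_display)
#' @export
analyze_moderators <- function(ds, alpha = 0.05, digits = 2,
                               pooled = c("recompute", "printed")) {
  pooled <- match.arg(pooled)
  if (is.null(ds$moderators)) {
    stop("dataset carries no moderators.csv", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(ds$moderators)), function(i) {
    m <- ds$moderators[i, ]
    col <- ds$comparisons[[m$filter_column]]
    members <- ds$comparisons[as.character(col) == as.character(m$filter_value), ,
                              drop = FALSE]
    if (nrow(members) == 0L) {
      stop("moderator level '", m$level_label, "' matches no comparisons",
           call. = FALSE)
    }
    if (pooled == "printed") {
      ft <- compare_correlations(m$r_mz_printed, m$n_mz_unique,
                                 m$r_dz_printed, m$n_dz_unique)
      res <- data.frame(
        group_label = m$level_label,
        k_comparisons = nrow(members),
        weighted_r_mz = m$r_mz_printed,
        weighted_r_dz = m$r_dz_printed,
        n_mz_unique = m$n_mz_unique,
        n_dz_unique = m$n_dz_unique,
        z = ft$z,
        z_display = round(ft$z, 2),
        p_one_tailed = ft$p_one_tailed,
        p_display = format_p_band(ft$p_one_tailed, alpha),
        significant = ft$p_one_tailed < alpha,
        stringsAsFactors = FALSE
      )
    } else {
      res <- pooled_result(m$level_label, members, m$n_mz_unique,
                           m$n_dz_unique, digits, alpha)
    }
    cbind(parameter = m$parameter, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-comparison Fisher tests (the comparison-level table)
#'
#' Applies [compare_correlations()] to every comparison with its
#' effective pair counts, returning the comparison table with full and
#' 2-decimal z values, banded p-values and a significance flag.
#'
#' @inheritParams analyze_construct
#' @return A data frame, one row per comparison.
#' @export
comparison_table <- function(ds, alpha = 0.05) {
  cmp <- ds$comparisons
  ft <- compare_correlations(cmp$r_mz, cmp$n_mz_eff, cmp$r_dz, cmp$n_dz_eff)
  data.frame(
    comparison_id = cmp$comparison_id,
    study_id = cmp$study_id,
    construct = cmp$construct,
    stratum_label = cmp$stratum_label,
    r_mz = cmp$r_mz,
    r_dz = cmp$r_dz,
    n_mz_eff = cmp$n_mz_eff,
    n_dz_eff = cmp$n_dz_eff,
    z = ft$z,
    z_display = round(ft$z, 2),
    p_one_tailed = ft$p_one_tailed,
    p_display = format_p_band(ft$p_one_tailed, alpha),
    significant = ft$p_one_tailed < alpha,
    stringsAsFactors = FALSE
  )
}

#' Corpus-level summary counts
#'
#' How many of the comparisons are nominally higher in MZ than DZ pairs
#' (strict inequality), and how many reject the one-tailed Fisher test at
#' `alpha` using each comparison's effective pair counts.
#'
#' @inheritParams analyze_construct
#' @return A list with `n_comparisons`, `n_nominal_higher_mz`,
#'   `pct_nominal` (rounded to whole percent), and `n_significant`.
#' @examples
#' ds <- load_twin_dataset()
#' summary_counts(ds)  # 23 of 24 nominal, 16 significant
#' @export
summary_counts <- function(ds, alpha = 0.05) {
  cmp <- if (inherits(ds, "twin_dataset")) ds$comparisons else ds
  if (is.null(cmp) || nrow(cmp) == 0L) {
    stop("no comparisons to summarize", call. = FALSE)
  }
  ft <- compare_correlations(cmp$r_mz, cmp$n_mz_eff, cmp$r_dz, cmp$n_dz_eff)
  n_nominal <- sum(cmp$r_mz > cmp$r_dz)
  list(
    n_comparisons = nrow(cmp),
    n_nominal_higher_mz = n_nominal,
    pct_nominal = round(100 * n_nominal / nrow(cmp)),
    n_significant = sum(ft$p_one_tailed < alpha)
  )
}

#' Median split of studies by total pair count
#'
#' Assigns each study to the `"below"` or `"above"` group relative to the
#' median of the per-study pair totals (MZ + DZ). Studies exactly at the
#' median go to `"above"` by default (`ties = "above"`), configurable.
#'
#' Note that the packaged corpus stores the size-group assignment used by
#' its moderator table as an explicit `size_group` column, because that
#' historical grouping is not reproducible from any threshold on study
#' size (one mid-sized study sits on the opposite side of a smaller one);
#' this function implements the documented rule for new corpora.
#'
#' @param studies A studies data frame.
#' @param ties Where studies exactly at the median go.
#' @return A data frame with `study_id`, `total_pairs`, `size_group`.
#' @export
median_split <- function(studies, ties = c("above", "below")) {
  ties <- match.arg(ties)
  if (nrow(studies) < 2L) {
    stop("median split needs at least 2 studies", call. = FALSE)
  }
  totals <- studies$n_mz_pairs + studies$n_dz_pairs
  med <- stats::median(totals)
  grp <- ifelse(totals > med, "above",
                ifelse(totals < med, "below", ties))
  data.frame(study_id = studies$study_id, total_pairs = totals,
             size_group = grp, stringsAsFactors = FALSE)
}

#' Reproduce the corpus analysis end to end
#'
#' Convenience wrapper running the comparison-level table, the construct
#' pooling, the moderator subgroups and the summary counts in one call,
#' and optionally writing the three tables plus a summary as CSV.
#'
#' @inheritParams analyze_construct
#' @param out_dir Directory for the CSV artifacts, or `NULL` to skip
#'   writing.
#' @return A list with `comparisons`, `constructs`, `moderators`
#'   (data frames) and `summary` (list).
#' @export
run_corpus_analysis <- function(ds, alpha = 0.05, out_dir = NULL) {
  res <- list(
    comparisons = comparison_table(ds, alpha),
    constructs = analyze_constructs(ds, alpha),
    moderators = if (!is.null(ds$moderators)) {
      analyze_moderators(ds, alpha)
    },
    summary = c(summarize_sample_sizes(ds$studies),
                summary_counts(ds, alpha))
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(res$comparisons,
                     file.path(out_dir, "comparison_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(res$constructs,
                     file.path(out_dir, "construct_pooling.csv"),
                     row.names = FALSE)
    if (!is.null(res$moderators)) {
      utils::write.csv(res$moderators,
                       file.path(out_dir, "moderator_pooling.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(quantity = names(res$summary),
                                value = unlist(res$summary)),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  res
}
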