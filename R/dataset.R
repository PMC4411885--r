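# Packaged meta-analytic corpus: 11 twin studies, 24 MZ-vs-DZ pairs of
# intraclass correlations for childhood social adversity, and the
# construct / moderator groupings used to pool them.
#
# Conventions encoded in the fixtures rather than in code:
#   * Effective pair counts: gender- or time-point-stratified rows carry
#     the FULL study pair counts (the stratum splits were not published);
#     this is the convention that reproduces the per-comparison z values.
#   * Construct and moderator unique-pair counts are stored as printed in
#     the source tables; a "recompute" mode sums member-study counts
#     instead (the two disagree for sexual abuse: 1749 printed vs 1819
#     summed).
#   * Moderator level assignments (instrument use, informant, size group,
#     interview age, gender, site) are per-comparison fixture columns.
#     Ambiguous assignments were resolved so that the printed unique pair
#     counts and pooled correlations of the moderator table are matched;
#     see the package vignette for the flagged cases.

.CONSTRUCTS <- c("bullying", "sexual_abuse", "physical_maltreatment",
                 "emotional_abuse_neglect", "general_trauma",
                 "combined_abuse")
.PRIMARY_CONSTRUCTS <- .CONSTRUCTS[.CONSTRUCTS != "combined_abuse"]
.SITES <- c("us_canada", "europe_australia")
.INFORMANTS <- c("twins", "third_person")
.AGE_BANDS <- c("proximate_le19", "distant_gt22")
.GENDERS <- c("male", "female", "mixed")
.SIZE_GROUPS <- c("below", "above")

.studies_cols <- c("study_id", "label", "n_mz_pairs", "n_dz_pairs",
                   "site", "informant", "interview_age_band", "country")
.comparisons_cols <- c("comparison_id", "study_id", "construct",
                       "stratum_label", "r_mz", "r_dz", "n_mz_eff",
                       "n_dz_eff", "gender", "uses_instrument",
                       "informant", "site", "interview_age_band",
                       "size_group", "measure_description")
.constructs_cols <- c("construct", "member_comparison_ids",
                      "n_mz_unique", "n_dz_unique")
.moderators_cols <- c("parameter", "level_label", "filter_column",
                      "filter_value", "n_mz_unique", "n_dz_unique",
                      "r_mz_printed", "r_dz_printed")

fixture_dir <- function() {
  system.file("extdata", package = "twinEEA", mustWork = TRUE)
}

read_fixture_csv <- function(path, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

row_fail <- function(file, i, id, field, msg) {
  stop(sprintf("%s row %d (%s): field '%s' %s", file, i, id, field, msg),
       call. = FALSE)
}

check_enum <- function(df, file, field, levels, id_col) {
  bad <- which(!df[[field]] %in% levels)
  if (length(bad)) {
    row_fail(file, bad[1], df[[id_col]][bad[1]], field,
             sprintf("must be one of {%s}, got '%s'",
                     paste(levels, collapse = ", "), df[[field]][bad[1]]))
  }
}

#' Split a ;-separated member list into comparison ids
#' @noRd
parse_members <- function(x) strsplit(x, ";", fixed = TRUE)

#' Load a twin adversity dataset
#'
#' Reads and validates a dataset of twin studies, intraclass-correlation
#' comparisons, construct groupings and (optionally) moderator level
#' definitions. With `path = "builtin"` the packaged 11-study / 24-row
#' corpus is loaded.
#'
#' A dataset directory must contain `studies.csv`, `comparisons.csv` and
#' `constructs.csv`; `moderators.csv` is optional (the moderator analysis
#' requires it). All referential and range invariants are checked:
#' correlations strictly inside (-1, 1), effective pair counts of at
#' least 4, unique study and comparison ids, resolvable foreign keys, and
#' disjoint construct memberships.
#'
#' @param path `"builtin"` for the packaged corpus, or a directory
#'   containing the CSV files.
#' @return An object of class `"twin_dataset"`: a list with data frames
#'   `studies`, `comparisons`, `constructs`, and `moderators` (or `NULL`).
#' @examples
#' ds <- load_twin_dataset()
#' nrow(ds$studies)      # 11
#' nrow(ds$comparisons)  # 24
#' @export
load_twin_dataset <- function(path = "builtin") {
  dir <- if (identical(path, "builtin")) fixture_dir() else path
  if (!dir.exists(dir)) {
    stop("dataset directory not found: ", dir, call. = FALSE)
  }
  studies <- read_fixture_csv(file.path(dir, "studies.csv"), "studies")
  comparisons <- read_fixture_csv(file.path(dir, "comparisons.csv"),
                                  "comparisons")
  constructs <- read_fixture_csv(file.path(dir, "constructs.csv"),
                                 "constructs")
  mod_path <- file.path(dir, "moderators.csv")
  moderators <- if (file.exists(mod_path)) {
    utils::read.csv(mod_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  ds <- structure(
    list(studies = studies, comparisons = comparisons,
         constructs = constructs, moderators = moderators),
    class = "twin_dataset"
  )
  validate_twin_dataset(ds)
  ds
}

#' Validate a twin adversity dataset
#'
#' Checks schema, ranges and referential integrity; called by
#' [load_twin_dataset()] and by the corpus simulator. Errors name the
#' offending file, row and field.
#'
#' @param ds A `"twin_dataset"` object (or a bare list with the same
#'   components).
#' @return `ds`, invisibly, when valid.
#' @export
validate_twin_dataset <- function(ds) {
  studies <- ds$studies
  comparisons <- ds$comparisons
  constructs <- ds$constructs

  check_cols(studies, .studies_cols, "studies.csv")
  check_cols(comparisons, .comparisons_cols, "comparisons.csv")
  check_cols(constructs, .constructs_cols, "constructs.csv")

  if (nrow(studies) == 0L) stop("studies.csv: no rows", call. = FALSE)
  if (nrow(comparisons) == 0L) stop("comparisons.csv: no rows", call. = FALSE)
  if (nrow(constructs) == 0L) stop("constructs.csv: no rows", call. = FALSE)

  # studies
  if (anyDuplicated(studies$study_id)) {
    stop("studies.csv: duplicated study_id '",
         studies$study_id[duplicated(studies$study_id)][1], "'",
         call. = FALSE)
  }
  for (field in c("n_mz_pairs", "n_dz_pairs")) {
    bad <- which(!is.finite(studies[[field]]) | studies[[field]] < 1)
    if (length(bad)) {
      row_fail("studies.csv", bad[1], studies$study_id[bad[1]], field,
               "must be a count of at least 1")
    }
  }
  check_enum(studies, "studies.csv", "site", .SITES, "study_id")
  check_enum(studies, "studies.csv", "informant", .INFORMANTS, "study_id")
  check_enum(studies, "studies.csv", "interview_age_band", .AGE_BANDS,
             "study_id")

  # comparisons
  if (anyDuplicated(comparisons$comparison_id)) {
    stop("comparisons.csv: duplicated comparison_id '",
         comparisons$comparison_id[duplicated(comparisons$comparison_id)][1],
         "'", call. = FALSE)
  }
  for (field in c("r_mz", "r_dz")) {
    bad <- which(!is.finite(comparisons[[field]]) |
                   abs(comparisons[[field]]) >= 1)
    if (length(bad)) {
      row_fail("comparisons.csv", bad[1], comparisons$comparison_id[bad[1]],
               field, "must lie strictly inside (-1, 1)")
    }
  }
  for (field in c("n_mz_eff", "n_dz_eff")) {
    bad <- which(!is.finite(comparisons[[field]]) | comparisons[[field]] < 4)
    if (length(bad)) {
      row_fail("comparisons.csv", bad[1], comparisons$comparison_id[bad[1]],
               field, "must be at least 4 (the z test divides by n - 3)")
    }
  }
  dangling <- which(!comparisons$study_id %in% studies$study_id)
  if (length(dangling)) {
    row_fail("comparisons.csv", dangling[1],
             comparisons$comparison_id[dangling[1]], "study_id",
             sprintf("references unknown study '%s'",
                     comparisons$study_id[dangling[1]]))
  }
  check_enum(comparisons, "comparisons.csv", "construct", .CONSTRUCTS,
             "comparison_id")
  check_enum(comparisons, "comparisons.csv", "gender", .GENDERS,
             "comparison_id")
  check_enum(comparisons, "comparisons.csv", "informant", .INFORMANTS,
             "comparison_id")
  check_enum(comparisons, "comparisons.csv", "site", .SITES, "comparison_id")
  check_enum(comparisons, "comparisons.csv", "interview_age_band",
             .AGE_BANDS, "comparison_id")
  check_enum(comparisons, "comparisons.csv", "size_group", .SIZE_GROUPS,
             "comparison_id")
  if (!is.logical(comparisons$uses_instrument) ||
      anyNA(comparisons$uses_instrument)) {
    stop("comparisons.csv: field 'uses_instrument' must be TRUE/FALSE",
         call. = FALSE)
  }

  # constructs
  if (anyDuplicated(constructs$construct)) {
    stop("constructs.csv: duplicated construct", call. = FALSE)
  }
  members <- parse_members(constructs$member_comparison_ids)
  for (i in seq_len(nrow(constructs))) {
    m <- members[[i]]
    if (length(m) == 0L || any(!nzchar(m))) {
      row_fail("constructs.csv", i, constructs$construct[i],
               "member_comparison_ids", "must be a non-empty ;-list")
    }
    unknown <- setdiff(m, comparisons$comparison_id)
    if (length(unknown)) {
      row_fail("constructs.csv", i, constructs$construct[i],
               "member_comparison_ids",
               sprintf("references unknown comparison '%s'", unknown[1]))
    }
    # unique counts can be below the member-study sum (de-duplication and
    # source-table conventions) but never above it
    st <- unique(comparisons$study_id[match(m, comparisons$comparison_id)])
    max_mz <- sum(studies$n_mz_pairs[studies$study_id %in% st])
    max_dz <- sum(studies$n_dz_pairs[studies$study_id %in% st])
    if (constructs$n_mz_unique[i] > max_mz) {
      row_fail("constructs.csv", i, constructs$construct[i], "n_mz_unique",
               sprintf("exceeds the member-study pair total (%d)", max_mz))
    }
    if (constructs$n_dz_unique[i] > max_dz) {
      row_fail("constructs.csv", i, constructs$construct[i], "n_dz_unique",
               sprintf("exceeds the member-study pair total (%d)", max_dz))
    }
    if (constructs$n_mz_unique[i] < 4 || constructs$n_dz_unique[i] < 4) {
      row_fail("constructs.csv", i, constructs$construct[i], "n_mz_unique",
               "unique pair counts must be at least 4")
    }
  }
  # disjoint membership across the primary constructs
  prim <- constructs$construct %in% .PRIMARY_CONSTRUCTS
  flat <- unlist(members[prim])
  if (anyDuplicated(flat)) {
    stop("constructs.csv: comparison '", flat[duplicated(flat)][1],
         "' is a member of more than one primary construct", call. = FALSE)
  }

  if (!is.null(ds$moderators)) {
    check_cols(ds$moderators, .moderators_cols, "moderators.csv")
    bad <- which(!ds$moderators$filter_column %in% names(comparisons))
    if (length(bad)) {
      row_fail("moderators.csv", bad[1], ds$moderators$level_label[bad[1]],
               "filter_column",
               sprintf("'%s' is not a comparisons column",
                       ds$moderators$filter_column[bad[1]]))
    }
  }
  invisible(ds)
}

#' Write a twin dataset back to CSV
#'
#' Emits `studies.csv`, `comparisons.csv`, `constructs.csv` and, when
#' present, `moderators.csv` in the schema read by [load_twin_dataset()].
#' Writing and reloading a dataset round-trips exactly.
#'
#' @param ds A `"twin_dataset"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_twin_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ds$studies, file.path(dir, "studies.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$constructs, file.path(dir, "constructs.csv"),
                   row.names = FALSE)
  if (!is.null(ds$moderators)) {
    utils::write.csv(ds$moderators, file.path(dir, "moderators.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Sample-size accounting across studies
#'
#' Totals and per-study distribution of twin-pair counts. The mean and
#' standard deviation are over per-study totals (MZ + DZ pairs), with the
#' sample (n - 1) denominator for the SD. For a single study the SD is
#' reported as 0 by convention. Source tables print these summaries
#' truncated to whole pairs; use `trunc()` on `mean_study` / `sd_study`
#' to match that display.
#'
#' @param studies A studies data frame (as in a `"twin_dataset"`).
#' @return A list with `n_studies`, `total_pairs`, `total_mz`, `total_dz`,
#'   `min_study`, `max_study`, `mean_study`, `sd_study`.
#' @examples
#' ds <- load_twin_dataset()
#' summarize_sample_sizes(ds$studies)$total_pairs  # 9119
#' @export
summarize_sample_sizes <- function(studies) {
  if (is.null(studies) || nrow(studies) == 0L) {
    stop("`studies` must contain at least one row", call. = FALSE)
  }
  totals <- studies$n_mz_pairs + studies$n_dz_pairs
  list(
    n_studies = nrow(studies),
    total_pairs = sum(totals),
    total_mz = sum(studies$n_mz_pairs),
    total_dz = sum(studies$n_dz_pairs),
    min_study = min(totals),
    max_study = max(totals),
    mean_study = mean(totals),
    sd_study = if (length(totals) > 1L) stats::sd(totals) else 0
  )
}

#' @export
print.twin_dataset <- function(x, ...) {
  s <- summarize_sample_sizes(x$studies)
  cat("Twin adversity dataset:", s$n_studies, "studies,",
      nrow(x$comparisons), "ICC comparisons,",
      nrow(x$constructs), "constructs\n")
  cat(sprintf("  %d twin pairs (%d MZ, %d DZ); study sizes %d-%d\n",
              s$total_pairs, s$total_mz, s$total_dz, s$min_study,
              s$max_study))
  invisible(x)
}
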