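# Shared helpers: copies of the builtin corpus that tests can corrupt,
# and a writer that round-trips a modified dataset through a temp dir so
# the CSV validation path is exercised.

builtin_dataset <- function() load_twin_dataset("builtin")

# Write a (possibly corrupted) dataset to a temp dir and reload it,
# returning the loader's result or error.
reload_via_csv <- function(ds) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_twin_dataset(ds, dir)
  load_twin_dataset(dir)
}

# Tiny two-study corpus used by pooling edge-case tests.
toy_dataset <- function() {
  studies <- data.frame(
    study_id = c("s1", "s2"),
    label = c("study one", "study two"),
    n_mz_pairs = c(100L, 200L),
    n_dz_pairs = c(80L, 150L),
    site = "us_canada",
    informant = "twins",
    interview_age_band = "proximate_le19",
    country = "nowhere",
    stringsAsFactors = FALSE
  )
  comparisons <- data.frame(
    comparison_id = c("c1", "c2"),
    study_id = c("s1", "s2"),
    construct = c("bullying", "bullying"),
    stratum_label = "all",
    r_mz = c(0.6, 0.5),
    r_dz = c(0.4, 0.3),
    n_mz_eff = c(100L, 200L),
    n_dz_eff = c(80L, 150L),
    gender = "mixed",
    uses_instrument = TRUE,
    informant = "twins",
    site = "us_canada",
    interview_age_band = "proximate_le19",
    size_group = c("below", "above"),
    measure_description = "toy",
    stringsAsFactors = FALSE
  )
  constructs <- data.frame(
    construct = "bullying",
    member_comparison_ids = "c1;c2",
    n_mz_unique = 300L,
    n_dz_unique = 230L,
    stringsAsFactors = FALSE
  )
  ds <- structure(list(studies = studies, comparisons = comparisons,
                       constructs = constructs, moderators = NULL),
                  class = "twin_dataset")
  validate_twin_dataset(ds)
  ds
}
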