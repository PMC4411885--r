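# Weighted pooling, construct and moderator analyses, summary counts.

test_that("pair-count weighting pools correlations as published", {
  # sexual abuse members: 0.60 over 896 pairs, 0.68 over 923 pairs
  pooled <- pool_weighted_r(c(0.60, 0.68), c(896, 923))
  expect_equal(pooled, 0.6406, tolerance = 5e-5)
  expect_equal(round(pooled, 2), 0.64)
})

test_that("pooling has the identity, mean and scale-invariance properties", {
  expect_identical(pool_weighted_r(0.37, 250), 0.37)
  expect_equal(pool_weighted_r(c(0.2, 0.6), c(100, 100)), 0.4)
  set.seed(41)
  for (i in 1:20) {
    r <- stats::runif(5, -0.9, 0.9)
    n <- sample(10:1000, 5)
    p <- pool_weighted_r(r, n)
    expect_equal(pool_weighted_r(r, n * 7), p)
    expect_gte(p, min(r))
    expect_lte(p, max(r))
  }
})

test_that("pooling rejects empty and malformed member lists", {
  expect_error(pool_weighted_r(numeric(0), numeric(0)), "empty")
  expect_error(pool_weighted_r(c(0.5, 0.4), 10), "equal length")
  expect_error(pool_weighted_r(1.0, 10), "strictly inside")
  expect_error(pool_weighted_r(0.5, 0), "at least 1")
})

test_that("all five construct z values reproduce from the fixture", {
  res <- analyze_constructs(builtin_dataset())
  expect_identical(res$group_label,
                   c("bullying", "sexual_abuse", "physical_maltreatment",
                     "emotional_abuse_neglect", "general_trauma"))
  expect_equal(res$weighted_r_mz, c(0.67, 0.64, 0.68, 0.47, 0.58))
  expect_equal(res$weighted_r_dz, c(0.39, 0.55, 0.55, 0.29, 0.41))
  expect_equal(res$z_display, c(10.13, 3.53, 5.87, 4.73, 4.60))
  expect_true(all(res$p_one_tailed < 0.001))
  # z range quoted for the construct table
  expect_equal(range(res$z_display), c(3.53, 10.13))
})

test_that("2-dp pre-rounding of pooled r is what yields the published z", {
  # unrounded pooling shifts sexual abuse from 3.53 to 3.60
  unrounded <- analyze_construct(builtin_dataset(), "sexual_abuse",
                                 digits = NULL)
  expect_equal(round(unrounded$z, 2), 3.60)
})

test_that("a single-member construct inherits its member's Fisher z", {
  ds <- toy_dataset()
  ds$constructs <- data.frame(
    construct = "bullying", member_comparison_ids = "c1",
    n_mz_unique = 100L, n_dz_unique = 80L, stringsAsFactors = FALSE
  )
  res <- analyze_construct(ds, "bullying", digits = NULL)
  member <- compare_correlations(0.6, 100, 0.4, 80)
  expect_equal(res$z, member$z)
  expect_identical(res$k_comparisons, 1L)
})

test_that("recomputed unique counts sum member studies once", {
  ds <- builtin_dataset()
  # sexual abuse: printed 1749 MZ pairs, member-study sum 1819
  fix <- analyze_construct(ds, "sexual_abuse", counts = "fixture")
  rec <- analyze_construct(ds, "sexual_abuse", counts = "recompute")
  expect_identical(fix$n_mz_unique, 1749L)
  expect_identical(rec$n_mz_unique, 1819L)
  expect_identical(rec$n_dz_unique, 1011L)
  # bullying: two stratified rows share one study; no double counting
  expect_identical(analyze_construct(ds, "bullying",
                                     counts = "recompute")$n_mz_unique, 1417L)
})

test_that("moderator subgroups reproduce published pooled correlations", {
  res <- analyze_moderators(builtin_dataset())
  expect_identical(nrow(res), 12L)
  expect_identical(res$k_comparisons,
                   c(14L, 10L, 20L, 4L, 12L, 12L, 9L, 15L, 4L, 4L, 13L, 11L))
  # recomputed pooled r matches the printed table in 21 of 24 cells;
  # the gender rows were pooled with unpublished stratum weights
  printed_mz <- c(0.62, 0.63, 0.60, 0.75, 0.51, 0.66, 0.73, 0.56, 0.56,
                  0.55, 0.56, 0.70)
  printed_dz <- c(0.51, 0.40, 0.46, 0.42, 0.31, 0.51, 0.51, 0.41, 0.31,
                  0.38, 0.41, 0.50)
  non_gender <- res$parameter != "gender"
  expect_equal(res$weighted_r_mz[non_gender], printed_mz[non_gender])
  expect_equal(res$weighted_r_dz[non_gender], printed_dz[non_gender])
})

test_that("printed-input moderator z values are recovered through the test", {
  res <- analyze_moderators(builtin_dataset(), pooled = "printed")
  # instrument=yes row: r 0.62 vs 0.51 with 2951/2280 unique pairs
  expect_equal(res$z_display[res$group_label == "yes"], 5.82)
  expect_equal(res$z_display[res$group_label == "male"], 4.92)
  expect_equal(res$z_display[res$group_label == "female"], 3.76)
  expect_equal(res$z_display[res$group_label == "europe_australia"], 10.75)
})

test_that("each moderator parameter partitions the eligible comparisons", {
  ds <- builtin_dataset()
  for (param in unique(ds$moderators$parameter)) {
    levels <- ds$moderators[ds$moderators$parameter == param, ]
    member_sets <- lapply(seq_len(nrow(levels)), function(i) {
      col <- as.character(ds$comparisons[[levels$filter_column[i]]])
      ds$comparisons$comparison_id[col == as.character(levels$filter_value[i])]
    })
    flat <- unlist(member_sets)
    expect_identical(anyDuplicated(flat), 0L)
    eligible <- if (param == "gender") {
      ds$comparisons$comparison_id[ds$comparisons$gender != "mixed"]
    } else {
      ds$comparisons$comparison_id
    }
    expect_setequal(flat, eligible)
  }
})

test_that("a moderator level equals the construct with the same members", {
  ds <- toy_dataset()
  ds$moderators <- data.frame(
    parameter = "instrument", level_label = "yes",
    filter_column = "uses_instrument", filter_value = TRUE,
    n_mz_unique = 300L, n_dz_unique = 230L,
    r_mz_printed = NA_real_, r_dz_printed = NA_real_,
    stringsAsFactors = FALSE
  )
  mod <- analyze_moderators(ds)
  con <- analyze_construct(ds, "bullying")
  expect_equal(mod$weighted_r_mz, con$weighted_r_mz)
  expect_equal(mod$z, con$z)
  expect_identical(mod$k_comparisons, con$k_comparisons)
})

test_that("summary counts match the corpus-level result", {
  s <- summary_counts(builtin_dataset())
  expect_identical(s$n_nominal_higher_mz, 23L)
  expect_identical(s$pct_nominal, 96)
  expect_identical(s$n_significant, 16L)
})

test_that("equal correlations are neither nominal nor significant", {
  ds <- toy_dataset()
  ds$comparisons$r_dz <- ds$comparisons$r_mz
  s <- summary_counts(ds)
  expect_identical(s$n_nominal_higher_mz, 0L)
  expect_identical(s$n_significant, 0L)
})

test_that("median split follows the documented tie convention", {
  st <- data.frame(study_id = c("a", "b", "c"),
                   n_mz_pairs = c(60L, 120L, 180L),
                   n_dz_pairs = c(40L, 80L, 120L))
  sp <- median_split(st)
  expect_identical(sp$size_group, c("below", "above", "above"))
  expect_identical(median_split(st, ties = "below")$size_group,
                   c("below", "below", "above"))
  two <- median_split(st[c(1, 3), ])
  expect_identical(two$size_group, c("below", "above"))
  expect_error(median_split(st[1, , drop = FALSE]), "at least 2")
})

test_that("the fixture size groups split the 24 comparisons 12/12", {
  cmp <- builtin_dataset()$comparisons
  expect_identical(as.vector(table(cmp$size_group)), c(12L, 12L))
})

test_that("per-comparison table flags significance at z > 1.645", {
  tab <- comparison_table(builtin_dataset())
  expect_identical(sum(tab$significant), 16L)
  expect_identical(tab$significant, tab$z > stats::qnorm(0.95))
})

test_that("the full corpus analysis writes idempotent artifacts", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  ds <- builtin_dataset()
  run_corpus_analysis(ds, out_dir = dir1)
  run_corpus_analysis(ds, out_dir = dir2)
  for (f in c("comparison_tests.csv", "construct_pooling.csv",
              "moderator_pooling.csv", "summary.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
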