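# The synthetic twin-pair generator and whole-corpus simulation.

test_that("configs validate their domains", {
  expect_error(sim_study_config(true_icc_mz = 1), "\\[0, 1\\)")
  expect_error(sim_study_config(true_icc_dz = -0.1), "\\[0, 1\\)")
  expect_error(sim_study_config(n_mz_pairs = 3), "at least 4")
  expect_error(sim_study_config(exposure_kind = "binary", prevalence = 0),
               "prevalence")
})

test_that("the same seed reproduces a study and a corpus exactly", {
  cf <- sim_study_config(seed = 99, n_mz_pairs = 50, n_dz_pairs = 50)
  s1 <- simulate_pairs(cf)
  s2 <- simulate_pairs(cf)
  expect_identical(s1$mz, s2$mz)
  expect_identical(s1$dz, s2$dz)

  cfgs <- corpus_configs()[1:3]
  d1 <- simulate_meta_corpus(cfgs, seed = 7)
  d2 <- simulate_meta_corpus(cfgs, seed = 7)
  expect_identical(d1$comparisons, d2$comparisons)
  # and byte-identical on disk
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_twin_dataset(d1, dir1)
  write_twin_dataset(d2, dir2)
  expect_identical(readLines(file.path(dir1, "comparisons.csv")),
                   readLines(file.path(dir2, "comparisons.csv")))
})

test_that("estimated ICCs recover the generating correlations", {
  # independence case
  cf0 <- sim_study_config(true_icc_mz = 0, true_icc_dz = 0,
                          n_mz_pairs = 4000, n_dz_pairs = 4000, seed = 3)
  s0 <- simulate_pairs(cf0)
  expect_lt(abs(icc_double_entry(s0$mz$x1, s0$mz$x2)), 0.05)
  # pooled corpus values used as simulation truth
  cf <- sim_study_config(true_icc_mz = 0.67, true_icc_dz = 0.39,
                         n_mz_pairs = 2000, n_dz_pairs = 2000, seed = 5)
  s <- simulate_pairs(cf)
  expect_lt(abs(icc_double_entry(s$mz$x1, s$mz$x2) - 0.67), 0.04)
  expect_lt(abs(icc_double_entry(s$dz$x1, s$dz$x2) - 0.39), 0.04)
})

test_that("binary exposures hit the target prevalence and attenuate the ICC", {
  mk <- function(prev, seed) {
    simulate_pairs(sim_study_config(true_icc_mz = 0.6, true_icc_dz = 0.6,
                                    n_mz_pairs = 20000, n_dz_pairs = 4,
                                    exposure_kind = "binary",
                                    prevalence = prev, seed = seed))
  }
  cont <- simulate_pairs(sim_study_config(true_icc_mz = 0.6,
                                          true_icc_dz = 0.6,
                                          n_mz_pairs = 20000,
                                          n_dz_pairs = 4, seed = 13))
  r_cont <- icc_double_entry(cont$mz$x1, cont$mz$x2)
  for (prev in c(0.1, 0.5)) {
    b <- mk(prev, 13)
    expect_lt(abs(mean(c(b$mz$x1, b$mz$x2)) - prev), 0.02)
    # phi-type ICC attenuated relative to the latent correlation
    expect_lt(icc_double_entry(b$mz$x1, b$mz$x2), r_cont)
  }
})

test_that("a simulated corpus loads and analyzes end to end", {
  cfgs <- list(
    sim_study_config("a", 300, 250, 0.6, 0.4),
    sim_study_config("b", 200, 150, 0.6, 0.4),
    sim_study_config("c", 250, 200, 0.5, 0.3)
  )
  dir <- withr::local_tempdir()
  ds <- simulate_meta_corpus(cfgs, c("bullying", "bullying",
                                     "general_trauma"),
                             seed = 17, dir = dir)
  back <- load_twin_dataset(dir)
  expect_identical(back$constructs$construct,
                   sort(c("bullying", "general_trauma")))
  res <- analyze_constructs(back, counts = "recompute")
  expect_identical(res$k_comparisons[res$group_label == "bullying"], 2L)
  expect_identical(res$n_mz_unique[res$group_label == "bullying"], 500L)
  expect_true(all(is.finite(res$z)))
})

test_that("a single config yields a single-member construct", {
  ds <- simulate_meta_corpus(list(sim_study_config("solo", 100, 100)),
                             "bullying", seed = 23)
  expect_identical(nrow(ds$constructs), 1L)
  expect_identical(ds$constructs$member_comparison_ids, "solo_cmp")
})

test_that("per-study seed substreams derive stably from the master seed", {
  expect_identical(derive_seed(1, "erisk"), derive_seed(1, "erisk"))
  expect_false(derive_seed(1, "erisk") == derive_seed(1, "shakoor"))
  expect_false(derive_seed(1, "erisk") == derive_seed(2, "erisk"))
  expect_lt(derive_seed(.Machine$integer.max - 1, "x"), 2^31)
})

test_that("the pooled one-tailed test is calibrated under the null", {
  # equal true ICCs at the packaged corpus sizes; modest replicate count
  # here, the acceptance suite runs the full 200-corpus version
  r <- estimate_rejection_rate(corpus_configs(icc_dz = 0.45, icc_gap = 0),
                               n_replicates = 60, seed = 301)
  expect_lt(abs(r$rejection_rate - 0.05), 0.03)
})

test_that("a 0.15 ICC gap is detected almost surely at corpus sizes", {
  r <- estimate_rejection_rate(corpus_configs(icc_dz = 0.45,
                                              icc_gap = 0.15),
                               n_replicates = 40, seed = 302)
  expect_gt(r$rejection_rate, 0.9)
})
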