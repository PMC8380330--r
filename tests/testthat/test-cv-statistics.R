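test_that("cv_ratio matches its definition, bounds and error cases", {
  expect_equal(cv_ratio(0.2, 0.2), 0.5)
  expect_equal(cv_ratio(0.1, 0.3), 0.25)
  # the 37%-difference benchmark: one CV equal to 63% of the other
  expect_equal(round(cv_ratio(1.0, 0.63), 2), 0.61)
  expect_equal(round(cv_ratio(0.63, 1.0), 2), 0.39)
  expect_error(cv_ratio(0, 0), "both CVs are zero")
  expect_error(cv_ratio(-0.1, 0.2), "non-negative")
})

test_that("cv_ratio antisymmetry and monotonicity hold over random pairs", {
  set.seed(7)
  a <- runif(1000, 0.001, 2)
  b <- runif(1000, 0.001, 2)
  expect_true(all(abs(cv_ratio(a, b) + cv_ratio(b, a) - 1) < 1e-12))
  expect_true(all(cv_ratio(a, a) == 0.5))
  expect_true(all((cv_ratio(a, b) > 0.5) == (a > b)))
  # strictly increasing in the female CV
  expect_true(all(cv_ratio(a + 0.1, b) > cv_ratio(a, b)))
})

test_that("a ferritin-like pool of 4 ratios summarizes to 75%/25%", {
  ds <- datasets_with_ratios(c(0.43, 0.52, 0.55, 0.58), param = "ferritin",
                             n = 15L)
  s <- summarize_parameter(ds, "ferritin", 5)
  expect_equal(s$n_datasets, 4)
  expect_equal(s$n_gt, 3)
  expect_equal(s$n_lt, 1)
  expect_equal(s$pct_gt, 75L)
  expect_equal(s$pct_lt, 25L)
  expect_equal(s$ratio_min, 0.43)
  expect_equal(s$ratio_max, 0.58)
  expect_equal(s$mean_cv_ratio, mean(c(0.43, 0.52, 0.55, 0.58)))
  expect_equal(s$sd_cv_ratio, sd(c(0.43, 0.52, 0.55, 0.58)))
  expect_equal(s$n_mice_total, 4 * 30L)
  expect_equal(s$n_projects, 1)
})

test_that("ties sit in neither bucket but stay in mean/SD/range", {
  ds <- datasets_with_ratios(c(0.5, 0.6, 0.4, 0.7), param = "mcv")
  s <- summarize_parameter(ds, "mcv", 5)
  expect_equal(s$n_tie, 1)
  expect_equal(s$n_gt + s$n_lt + s$n_tie, s$n_datasets)
  expect_equal(s$pct_gt, 67L)              # 2 of 3 non-tied, rounded half-up
  expect_equal(s$mean_cv_ratio, mean(c(0.5, 0.6, 0.4, 0.7)))
  expect_equal(s$ratio_min, 0.4)
})

test_that("an empty parameter yields an explicit empty summary", {
  ds <- datasets_with_ratios(0.5, param = "glucose")
  s <- summarize_parameter(ds, "ck", 5)
  expect_true(s$empty)
  expect_equal(s$n_datasets, 0)
  expect_true(is.na(s$mean_cv_ratio))
  expect_true(is.na(s$pct_gt))
})

test_that("summary mean/SD/conservation agree with a brute-force pass", {
  set.seed(13)
  ratios <- runif(500)
  ds <- datasets_with_ratios(ratios, param = "wbc",
                             project = sample(paste0("p", 1:12), 500,
                                              replace = TRUE))
  s <- summarize_parameter(ds, "wbc", 5)
  expect_equal(s$mean_cv_ratio, sum(ratios) / 500)
  expect_equal(s$sd_cv_ratio,
               sqrt(sum((ratios - mean(ratios))^2) / 499))
  expect_equal(s$n_gt + s$n_lt + s$n_tie, 500L)
  expect_equal(s$n_mice_total, sum(ds$n_f + ds$n_m))
  expect_equal(s$n_projects, length(unique(ds$project_id)))
})

test_that("the equal-split closed form matches generic Pearson on all pairs to 50", {
  grid <- expand.grid(a = 0:50, b = 0:50)
  grid <- grid[grid$a + grid$b > 0, ]
  got <- mapply(function(a, b) {
    r <- chi_squared_equal_split(a, b)
    c(r$statistic, r$p_value)
  }, grid$a, grid$b)
  ref <- mapply(function(a, b) {
    r <- suppressWarnings(stats::chisq.test(c(a, b), p = c(0.5, 0.5)))
    c(unname(r$statistic), unname(r$p.value))
  }, grid$a, grid$b)
  expect_equal(got, ref)
  expect_false(chi_squared_equal_split(0, 0)$evaluable)
})

test_that("equal-split test reproduces the ALT-only significance pattern", {
  t0 <- chi_squared_equal_split(10, 10)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  alt5 <- chi_squared_equal_split(5, 16)          # ALT, n >= 5 analysis
  expect_equal(alt5$statistic, 121 / 21)
  expect_equal(alt5$p_value, 0.0163773, tolerance = 1e-5)
  expect_true(alt5$significant)
  alt10 <- chi_squared_equal_split(1, 9)          # ALT, n >= 10 analysis
  expect_equal(alt10$statistic, 6.4)
  expect_equal(alt10$p_value, 0.0114120, tolerance = 1e-5)
  expect_true(alt10$significant)
  chol10 <- chi_squared_equal_split(62, 44)       # cholesterol, n >= 10
  expect_equal(chol10$statistic, 324 / 106)
  expect_false(chol10$significant)
})

test_that("mean-vs-proportion flag fires only on opposite sides of 0.5", {
  expect_true(flag_mean_vs_proportion(summary_stub(0.49, 183, 149)))  # MCV-like
  expect_false(flag_mean_vs_proportion(summary_stub(0.52, 220, 111)))
  expect_false(flag_mean_vs_proportion(summary_stub(0.5, 30, 10)))    # neutral mean
  expect_false(flag_mean_vs_proportion(summary_stub(0.55, 20, 20)))   # neutral counts
  expect_true(is.na(flag_mean_vs_proportion(summary_stub(NA, 0, 0, empty = TRUE))))
})

test_that("cross-threshold flag needs a strict sign flip of the mean", {
  expect_true(flag_cross_threshold(summary_stub(0.51, 66, 50),
                                   summary_stub(0.46, 6, 9)))   # chloride-like
  expect_false(flag_cross_threshold(summary_stub(0.52, 220, 111),
                                    summary_stub(0.51, 62, 44)))
  expect_false(flag_cross_threshold(summary_stub(0.5, 10, 10),
                                    summary_stub(0.55, 12, 8)))
  expect_true(is.na(flag_cross_threshold(summary_stub(0.5, 1, 1),
                                         summary_stub(NA, 0, 0, empty = TRUE))))
  expect_error(flag_cross_threshold(summary_stub(0.5, 1, 1, key = "a"),
                                    summary_stub(0.5, 1, 1, key = "b")),
               "different parameters")
})

test_that("consistent significance requires rejection in both analyses", {
  expect_true(significant_in_both(summary_stub(0.44, 5, 16),
                                  summary_stub(0.39, 1, 9)))    # ALT counts
  expect_false(significant_in_both(summary_stub(0.52, 220, 111),
                                   summary_stub(0.51, 62, 44))) # cholesterol
  expect_false(significant_in_both(summary_stub(0.5, 10, 10),
                                   summary_stub(0.5, 10, 10)))
  expect_false(significant_in_both(summary_stub(0.44, 5, 16),
                                   summary_stub(NA, 0, 0, empty = TRUE)))
})

test_that("consistency_flags assembles per-parameter flags over both analyses", {
  s5 <- dplyr::bind_rows(summary_stub(0.49, 183, 149, key = "mcv"),
                         summary_stub(0.51, 66, 50, key = "chloride"),
                         summary_stub(0.44, 5, 16, key = "alt"))
  s10 <- dplyr::bind_rows(summary_stub(0.496, 69, 52, key = "mcv"),
                          summary_stub(0.46, 6, 9, key = "chloride"),
                          summary_stub(0.39, 1, 9, key = "alt"))
  fl <- consistency_flags(s5, s10)
  expect_equal(fl$parameter_key, c("mcv", "chloride", "alt"))
  expect_true(fl$mean_vs_proportion_inconsistent[fl$parameter_key == "mcv"])
  expect_true(fl$cross_threshold_inconsistent[fl$parameter_key == "chloride"])
  expect_equal(fl$significant_in_both, c(FALSE, FALSE, TRUE))
})
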