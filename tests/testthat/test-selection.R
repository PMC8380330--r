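test_that("group summaries match hand-computed n/mean/sd/cv", {
  animals <- dplyr::bind_rows(
    animal_group("p1", "glucose", "A/J", "f", c(8, 10, 12)),
    animal_group("p1", "glucose", "A/J", "m", c(5, 5, 5, 5, 5)),
    animal_group("p1", "glucose", "B6", "f", 7))   # singleton group
  g <- summarize_groups(animals)
  f <- g[g$strain == "A/J" & g$sex == "f", ]
  expect_equal(f$n, 3L)
  expect_equal(f$mean, 10)
  expect_equal(f$sd, 2)
  expect_equal(f$cv, 0.2)
  m <- g[g$strain == "A/J" & g$sex == "m", ]
  expect_equal(m$cv, 0)                            # constant values
  s <- g[g$strain == "B6", ]
  expect_true(s$degenerate)
  expect_equal(s$sd, 0)
})

test_that("age window is inclusive and rejection reasons follow the fixed order", {
  animals <- dplyr::bind_rows(
    animal_group("p", "alt", "A/J", "f", 1, age = 7),
    animal_group("p", "alt", "A/J", "f", 1, age = 26),
    animal_group("p", "alt", "A/J", "f", 1, age = 6.9),
    animal_group("p", "alt", "A/J", "f", 1, age = 26.1),
    animal_group("p", "alt", "A/J", "f", 1, age = 10, treated = TRUE),
    animal_group("p", "alt", "A/J", "f", 1, age = 50, treated = TRUE,
                 class = "other"))
  fr <- filter_animals(animals, selection_criteria())
  expect_equal(nrow(fr$kept), 2)
  expect_equal(fr$kept$age_weeks, c(7, 26))
  expect_equal(fr$rejected$reason, c("age", "age", "treatment",
                                     "strain_class"))  # first failing rule
})

test_that("filter kept/rejected counts equal the generator's truth", {
  cfg <- simulation_config(n_projects = 4, strains_per_project = 5,
                           parameters = c("glucose", "alt"),
                           n_per_sex = c(5, 10), treated_fraction = 0.3,
                           seed = 11)
  sim <- simulate_animals(cfg)
  fr <- filter_animals(sim$animals, selection_criteria())
  expected_kept <- sum(sim$truth$n[sim$truth$expect_kept])
  expect_equal(nrow(fr$kept), expected_kept)
  expect_equal(nrow(fr$rejected), nrow(sim$animals) - expected_kept)
  expect_true(all(fr$rejected$reason == "treatment"))
})

test_that("pairing requires both sexes at the group-size threshold", {
  groups <- tibble::tibble(
    project_id = "p1", parameter_key = "glucose",
    strain = c("A/J", "A/J", "B6", "B6", "C3H/HeJ"),
    sex = c("f", "m", "f", "m", "f"),
    n = c(5L, 5L, 5L, 4L, 8L),
    mean = 100, sd = c(10, 30, 10, 20, 10))
  groups$cv <- groups$sd / groups$mean
  groups$valid <- TRUE
  ds <- pair_datasets(groups, selection_criteria())
  expect_equal(nrow(ds), 1)                      # B6 under-sized, C3H unpaired
  expect_equal(ds$strain, "A/J")
  expect_equal(ds$cv_ratio, 0.1 / 0.4)           # 0.25
  dropped <- attr(ds, "dropped")
  expect_equal(unname(dropped["ineligible_groups"]), 1)  # B6 male, n = 4
  expect_equal(unname(dropped["unpaired"]), 2)  # orphaned B6 female + C3H female
})

test_that("data sets at n >= 10 are a subset of those at n >= 5", {
  cfg <- scenario("with_outliers", n_projects = 5, strains_per_project = 8,
                  seed = 3)
  sim <- simulate_animals(cfg)
  groups <- summarize_groups(sim$animals)
  ds5 <- pair_datasets(groups, selection_criteria(min_n_per_sex = 5))
  ds10 <- pair_datasets(groups, selection_criteria(min_n_per_sex = 10))
  key <- function(d) paste(d$project_id, d$parameter_key, d$strain)
  expect_true(all(key(ds10) %in% key(ds5)))
  expect_lte(nrow(ds10), nrow(ds5))
  # raising the threshold further never increases the count
  ds20 <- pair_datasets(groups, selection_criteria(min_n_per_sex = 20))
  expect_lte(nrow(ds20), nrow(ds10))
})

test_that("a data set with both CVs zero is dropped, not divided", {
  groups <- tibble::tibble(
    project_id = "p1", parameter_key = "glucose", strain = "A/J",
    sex = c("f", "m"), n = 5L, mean = 100, sd = 0, cv = 0, valid = TRUE)
  ds <- pair_datasets(groups, selection_criteria())
  expect_equal(nrow(ds), 0)
  expect_equal(unname(attr(ds, "dropped")["degenerate"]), 1)
})

test_that("outlier exclusion is strict at the threshold and codes the sex", {
  ds <- tibble::tibble(
    project_id = "p", parameter_key = "alt", strain = paste0("S", 1:4),
    n_f = 10L, mean_f = 100, sd_f = c(51, 50, 20, 60),
    cv_f = c(0.51, 0.50, 0.20, 0.60),
    n_m = 10L, mean_m = 100, sd_m = c(20, 20, 55, 70),
    cv_m = c(0.20, 0.20, 0.55, 0.70),
    cv_ratio = 0.5, excluded = FALSE, exclusion_reason = "none")
  ds$cv_ratio <- cv_ratio(ds$cv_f, ds$cv_m)
  split <- apply_outlier_exclusion(ds, 0.5)
  expect_equal(nrow(split$kept), 1)
  expect_equal(split$kept$cv_f, 0.5)             # exactly 0.5 is kept
  expect_equal(sort(split$excluded$exclusion_reason),
               c("both_cv", "female_cv", "male_cv"))
  # partition invariant
  expect_equal(nrow(split$kept) + nrow(split$excluded), nrow(ds))
  # no retained data set violates the rule
  expect_true(all(split$kept$cv_f <= 0.5 & split$kept$cv_m <= 0.5))
  # raising the threshold never decreases the kept count
  split2 <- apply_outlier_exclusion(ds, 0.65)
  expect_gte(nrow(split2$kept), nrow(split$kept))
  # idempotence: excluding again removes nothing further
  again <- apply_outlier_exclusion(split$kept, 0.5)
  expect_equal(nrow(again$excluded), 0)
  expect_equal(again$kept, split$kept)
})

test_that("excluded fraction tracks the injected outlier rate", {
  cfg <- scenario("with_outliers", outlier_fraction = 0.1, n_projects = 10,
                  strains_per_project = 10, parameters = "glucose",
                  seed = 5)
  sim <- simulate_animals(cfg)
  groups <- summarize_groups(sim$animals)
  ds <- pair_datasets(groups, selection_criteria())
  split <- apply_outlier_exclusion(ds, 0.5)
  n <- nrow(ds)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.1) / n
  frac <- nrow(split$excluded) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("empirical group CV converges to the configured CV at large n", {
  set.seed(101)
  r <- simulate_cv_ratios(5, 10000, cv_female = 0.2, cv_male = 0.3)
  expect_true(all(abs(r$cv_f - 0.2) < 0.01))
  expect_true(all(abs(r$cv_m - 0.3) < 0.01))
})
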