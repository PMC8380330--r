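#' @keywords internal
# Typical magnitudes of the 25 blood parameters in conventional mouse units.
# CVs are scale-free, so these only anchor the simulated values at realistic
# magnitudes; they never influence a CV ratio.
default_base_means <- function() {
  c(cholesterol = 100, creatinine = 0.4, glucose = 180, total_protein = 5.5,
    triglycerides = 120, urea = 50, uric_acid = 3, ferritin = 500,
    transferrin = 150, calcium = 9.5, chloride = 110, phosphorus = 8,
    potassium = 5, sodium = 150, alt = 40, ast = 80, alpha_amylase = 2000,
    ap = 100, ck = 300, lipase = 50, hemoglobin = 14, mcv = 50, rbc = 9,
    wbc = 7, platelets = 1000)
}

# Inbred strain designations used for simulated cohorts; the first ten carry
# the default family prefixes so family assignment is exercised.
strain_pool <- function() {
  c("A/J", "BALB/cJ", "BALB/cByJ", "C3H/HeJ", "C57BL/6J", "C57BL/6NJ",
    "CBA/J", "CBA/CaJ", "DBA/2J", "DBA/2HaSmnJ", "129S1/SvImJ", "AKR/J",
    "FVB/NJ", "NOD/ShiLtJ", "NZO/HlLtJ", "PWK/PhJ", "WSB/EiJ", "CAST/EiJ",
    "SJL/J", "LP/J")
}

#' Configuration of the synthetic MPD-style generator
#'
#' Describes a multi-project, multi-strain, two-sex cohort with known ground
#' truth. Each project contributes `strains_per_project` strains; each
#' (project, strain, parameter) combination yields one strain data set of a
#' female and a male group. Female CVs are `cv_female_factor` times the male
#' CV, so `cv_female_factor = 1` is the equal-variability null and the
#' pooled mean CV ratio converges to `k / (1 + k)` for factor `k`. A
#' fraction `outlier_fraction` of data sets is regenerated as
#' high-variability outliers: the affected sex group(s) -- female only, male
#' only, or both, drawn according to `outlier_sex_split` -- get a target CV
#' drawn uniformly from (0.5, 0.9\] and are redrawn until their realized CV
#' exceeds `outlier_cv_threshold`, so injected outliers are outliers in the
#' sense the exclusion rule sees.
#'
#' @param n_projects Number of simulated projects.
#' @param strains_per_project Strains per project (at most the built-in
#'   strain pool of 20).
#' @param parameters Character vector of registry parameter keys.
#' @param n_per_sex Group size per sex: a single count or a `c(min, max)`
#'   range sampled uniformly per group.
#' @param base_mean Named vector of group means per parameter; defaults to
#'   built-in typical magnitudes.
#' @param cv_male Male group CV.
#' @param cv_female_factor Multiplier `k` with `cv_female = k * cv_male`.
#' @param outlier_fraction Fraction of data sets injected as outliers.
#' @param outlier_sex_split Probabilities that an injected outlier affects
#'   the female group only, the male group only, or both. The default
#'   11:6:6 split mirrors the observed outlier breakdown in real strain
#'   surveys (about 1.1% female-only, 0.6% male-only, 0.6% both).
#' @param outlier_cv_threshold Realized CV an injected group must exceed.
#' @param age_range Age window (weeks) the simulated groups are drawn from.
#' @param treated_fraction Fraction of data sets marked as treated (their
#'   animals are expected to be rejected by the default criteria).
#' @param distribution `"lognormal"` (positive, right-skewed, the default
#'   for blood analytes) or `"truncated_normal"` (negatives resampled).
#' @param seed Integer seed; a fixed seed makes output byte-identical.
#' @return List of class `"simulation_config"`.
#' @seealso [scenario()] for named presets, [simulate_animals()].
#' @export
simulation_config <- function(n_projects = 10,
                              strains_per_project = 10,
                              parameters = "cholesterol",
                              n_per_sex = c(5, 30),
                              base_mean = NULL,
                              cv_male = 0.15,
                              cv_female_factor = 1,
                              outlier_fraction = 0,
                              outlier_sex_split = c(female = 11, male = 6,
                                                    both = 6) / 23,
                              outlier_cv_threshold = 0.5,
                              age_range = c(7, 26),
                              treated_fraction = 0,
                              distribution = c("lognormal",
                                               "truncated_normal"),
                              seed = 1L) {
  distribution <- match.arg(distribution)
  if (is.null(base_mean)) base_mean <- default_base_means()
  missing_means <- setdiff(parameters, names(base_mean))
  if (length(missing_means) > 0) {
    stop("no base_mean for parameter(s): ",
         paste(missing_means, collapse = ", "), call. = FALSE)
  }
  if (length(n_per_sex) == 1) n_per_sex <- rep(n_per_sex, 2)
  stopifnot(n_projects >= 1, strains_per_project >= 1,
            strains_per_project <= length(strain_pool()),
            length(parameters) >= 1,
            n_per_sex[1] >= 2, n_per_sex[1] <= n_per_sex[2],
            cv_male > 0, cv_female_factor > 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            abs(sum(outlier_sex_split) - 1) < 1e-8,
            treated_fraction >= 0, treated_fraction < 1,
            age_range[1] >= 0, age_range[1] <= age_range[2])
  structure(list(n_projects = as.integer(n_projects),
                 strains_per_project = as.integer(strains_per_project),
                 parameters = parameters,
                 n_per_sex = as.integer(n_per_sex),
                 base_mean = base_mean,
                 cv_male = cv_male,
                 cv_female_factor = cv_female_factor,
                 outlier_fraction = outlier_fraction,
                 outlier_sex_split = outlier_sex_split,
                 outlier_cv_threshold = outlier_cv_threshold,
                 age_range = age_range,
                 treated_fraction = treated_fraction,
                 distribution = distribution,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Named simulation scenarios
#'
#' Presets for the study conditions used throughout validation:
#' \describe{
#'   \item{`null_equal_cv`}{Equal per-sex CVs (`k = 1`); 500 data sets of
#'     200 animals per sex. The pooled mean CV ratio is 0.5 by symmetry.}
#'   \item{`female_inflated_37`}{Female CV 37% above the male CV
#'     (`k = 1.37`), same scale; pooled mean ratio near 1.37/2.37 = 0.578.}
#'   \item{`male_inflated_37`}{The mirror image (`k = 1/1.37`).}
#'   \item{`with_outliers`}{Equal CVs with 2.3% of data sets injected as
#'     high-variability outliers, the rate observed in real strain surveys;
#'     2000 data sets of 10-30 animals per sex across four parameters.}
#' }
#'
#' @param name Scenario name.
#' @param ... Overrides passed to [simulation_config()] (e.g. `seed`).
#' @return A [simulation_config()].
#' @export
scenario <- function(name = c("null_equal_cv", "female_inflated_37",
                              "male_inflated_37", "with_outliers"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    null_equal_cv = list(n_projects = 25, strains_per_project = 20,
                         parameters = "cholesterol", n_per_sex = 200,
                         cv_male = 0.15, cv_female_factor = 1,
                         outlier_fraction = 0),
    female_inflated_37 = list(n_projects = 25, strains_per_project = 20,
                              parameters = "cholesterol", n_per_sex = 200,
                              cv_male = 0.15, cv_female_factor = 1.37,
                              outlier_fraction = 0),
    male_inflated_37 = list(n_projects = 25, strains_per_project = 20,
                            parameters = "cholesterol", n_per_sex = 200,
                            cv_male = 0.15, cv_female_factor = 1 / 1.37,
                            outlier_fraction = 0),
    with_outliers = list(n_projects = 25, strains_per_project = 20,
                         parameters = c("cholesterol", "glucose",
                                        "triglycerides", "urea"),
                         n_per_sex = c(10, 30), cv_male = 0.15,
                         cv_female_factor = 1, outlier_fraction = 0.023)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# One group of measurement values at a target mean and CV.
draw_group_values <- function(n, mean, cv, distribution) {
  if (distribution == "lognormal") {
    sigma <- sqrt(log(1 + cv^2))
    mu <- log(mean) - sigma^2 / 2
    stats::rlnorm(n, mu, sigma)
  } else {
    x <- stats::rnorm(n, mean, cv * mean)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), mean, cv * mean)
    }
    x
  }
}

# An outlier group: target CV from (0.5, 0.9], redrawn until the realized
# CV exceeds the threshold so the injected truth matches the exclusion rule.
draw_outlier_group <- function(n, mean, threshold, distribution) {
  for (attempt in 1:1000) {
    cv_t <- stats::runif(1, 0.5, 0.9)
    x <- draw_group_values(n, mean, cv_t, distribution)
    if (stats::sd(x) / base::mean(x) > threshold) {
      return(list(values = x, target_cv = cv_t))
    }
  }
  stop("failed to realize an outlier group in 1000 attempts", call. = FALSE)
}

#' Generate a synthetic MPD-style animal table with ground truth
#'
#' Emits a per-animal table in the format [read_animal_table()] consumes,
#' together with a truth table holding one row per sex group: its configured
#' size, mean and CV, whether it was injected as an outlier, and whether its
#' animals are expected to be kept by the default selection criteria. Tests
#' validate the pipeline against this truth instead of re-deriving it from
#' the data.
#'
#' @param config A [simulation_config()] or [scenario()].
#' @return List with `animals` (tibble of per-animal rows) and `truth`
#'   (tibble of per-group truth records).
#' @export
simulate_animals <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_animals_impl(config))
}

simulate_animals_impl <- function(cfg) {
  pool <- strain_pool()
  cv_m <- cfg$cv_male
  cv_f <- cfg$cv_female_factor * cv_m
  animal_chunks <- list()
  truth_chunks <- list()
  idx <- 0L
  for (p in seq_len(cfg$n_projects)) {
    project_id <- sprintf("proj%02d", p)
    strains <- sample(pool, cfg$strains_per_project)
    for (strain in strains) {
      for (param in cfg$parameters) {
        base <- cfg$base_mean[[param]]
        is_outlier_ds <- stats::runif(1) < cfg$outlier_fraction
        outlier_sexes <- if (is_outlier_ds) {
          switch(sample(names(cfg$outlier_sex_split), 1,
                        prob = cfg$outlier_sex_split),
                 female = "f", male = "m", both = c("f", "m"))
        } else character()
        treated <- stats::runif(1) < cfg$treated_fraction
        for (sex in c("f", "m")) {
          n <- if (cfg$n_per_sex[1] == cfg$n_per_sex[2]) cfg$n_per_sex[1]
               else sample(cfg$n_per_sex[1]:cfg$n_per_sex[2], 1)
          age <- round(stats::runif(1, cfg$age_range[1], cfg$age_range[2]), 1)
          target_cv <- if (sex == "f") cv_f else cv_m
          if (sex %in% outlier_sexes) {
            g <- draw_outlier_group(n, base, cfg$outlier_cv_threshold,
                                    cfg$distribution)
            values <- g$values
            target_cv <- g$target_cv
            is_outlier <- TRUE
          } else {
            values <- draw_group_values(n, base, target_cv, cfg$distribution)
            is_outlier <- FALSE
          }
          idx <- idx + 1L
          animal_chunks[[idx]] <- tibble::tibble(
            project_id = project_id, parameter_key = param, strain = strain,
            strain_class = "inbred", sex = sex, age_weeks = age,
            treated = treated, value = values)
          truth_chunks[[idx]] <- tibble::tibble(
            project_id = project_id, parameter_key = param, strain = strain,
            sex = sex, n = as.integer(n), target_mean = base,
            target_cv = target_cv, is_outlier = is_outlier,
            treated = treated, age_weeks = age,
            expect_kept = !treated && age >= 7 && age <= 26)
        }
      }
    }
  }
  list(animals = dplyr::bind_rows(animal_chunks),
       truth = dplyr::bind_rows(truth_chunks))
}

#' Fast simulation of CV-ratio pools
#'
#' Draws `n_datasets` paired female/male groups at the given target CVs and
#' returns their empirical CVs and CV ratios, without materializing animal
#' records. This is the workhorse for calibration studies (type-I error of
#' the equal-split test, convergence of the pooled mean ratio) where many
#' thousands of data sets are needed and only the ratios matter.
#'
#' @param n_datasets Number of strain data sets.
#' @param n_per_sex Animals per sex group (single count).
#' @param cv_female,cv_male Target CVs.
#' @param base_mean Group mean (irrelevant to ratios; anchors the scale).
#' @param distribution As in [simulation_config()].
#' @return Tibble with columns `cv_f`, `cv_m`, `cv_ratio`.
#' @export
simulate_cv_ratios <- function(n_datasets, n_per_sex, cv_female, cv_male,
                               base_mean = 100,
                               distribution = c("lognormal",
                                                "truncated_normal")) {
  distribution <- match.arg(distribution)
  draw_cvs <- function(cv) {
    x <- matrix(draw_group_values(n_datasets * n_per_sex, base_mean, cv,
                                  distribution),
                nrow = n_datasets)
    m <- rowMeans(x)
    ss <- rowSums((x - m)^2)
    sqrt(ss / (n_per_sex - 1)) / m
  }
  cv_f <- draw_cvs(cv_female)
  cv_m <- draw_cvs(cv_male)
  tibble::tibble(cv_f = cv_f, cv_m = cv_m, cv_ratio = cv_ratio(cv_f, cv_m))
}

#' Write a generator truth table
#'
#' Tab-separated, alongside the data file, so downstream checks read the
#' configured truth instead of re-deriving it.
#'
#' @param truth Truth tibble from [simulate_animals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
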