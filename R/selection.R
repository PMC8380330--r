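#' Data-set selection criteria
#'
#' Bundles the rules deciding which animals and which strain data sets enter
#' the analysis. Defaults reproduce the published selection: inbred-type
#' strains only (inbred, Collaborative-Cross-derived inbred, F1 hybrid,
#' recombinant inbred), untreated animals, age 7-26 weeks (inclusive), at
#' least 5 animals per sex, and exclusion of data sets where either sex
#' group has CV > 0.5.
#'
#' @param allowed_strain_classes Character vector of admissible strain
#'   classes.
#' @param require_untreated Drop treated animals?
#' @param age_min_weeks,age_max_weeks Inclusive age window in weeks.
#' @param min_n_per_sex Minimum group size per sex for a strain data set.
#' @param outlier_cv_threshold A sex group with CV strictly above this marks
#'   its data set as an outlier.
#' @param apply_outlier_exclusion Apply the outlier rule? The strain-family
#'   analysis runs with it disabled.
#' @return A list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(allowed_strain_classes = c("inbred", "cc_inbred",
                                                          "f1_hybrid",
                                                          "recombinant_inbred"),
                               require_untreated = TRUE,
                               age_min_weeks = 7,
                               age_max_weeks = 26,
                               min_n_per_sex = 5L,
                               outlier_cv_threshold = 0.5,
                               apply_outlier_exclusion = TRUE) {
  stopifnot(age_min_weeks <= age_max_weeks, min_n_per_sex >= 1,
            outlier_cv_threshold > 0)
  structure(list(allowed_strain_classes = allowed_strain_classes,
                 require_untreated = require_untreated,
                 age_min_weeks = age_min_weeks,
                 age_max_weeks = age_max_weeks,
                 min_n_per_sex = as.integer(min_n_per_sex),
                 outlier_cv_threshold = outlier_cv_threshold,
                 apply_outlier_exclusion = apply_outlier_exclusion),
            class = "selection_criteria")
}

#' @export
print.selection_criteria <- function(x, ...) {
  cat("Selection criteria:\n",
      "  strain classes: ", paste(x$allowed_strain_classes, collapse = ", "), "\n",
      "  untreated only: ", x$require_untreated, "\n",
      "  age window:     ", x$age_min_weeks, "-", x$age_max_weeks, " weeks\n",
      "  min n per sex:  ", x$min_n_per_sex, "\n",
      "  outlier rule:   ",
      if (x$apply_outlier_exclusion)
        paste0("exclude if either sex CV > ", x$outlier_cv_threshold)
      else "disabled", "\n", sep = "")
  invisible(x)
}

#' Filter animals by strain class, treatment and age
#'
#' Each rejected animal carries exactly one reason code: the first failing
#' rule in the fixed order strain_class, treatment, age. The age window is
#' inclusive on both ends and applied per animal, so in a group with mixed
#' ages every animal must satisfy the window individually.
#'
#' @param animals Tibble from [read_animal_table()] or [simulate_animals()].
#' @param criteria A [selection_criteria()] object.
#' @return List with `kept` (tibble of admissible animals) and `rejected`
#'   (same columns plus `reason` in `strain_class`/`treatment`/`age`).
#' @export
filter_animals <- function(animals, criteria = selection_criteria()) {
  bad_class <- !animals$strain_class %in% criteria$allowed_strain_classes
  bad_treat <- criteria$require_untreated & animals$treated
  bad_age <- animals$age_weeks < criteria$age_min_weeks |
    animals$age_weeks > criteria$age_max_weeks
  reason <- rep(NA_character_, nrow(animals))
  reason[bad_age] <- "age"
  reason[bad_treat] <- "treatment"   # later assignments win: fixed order
  reason[bad_class] <- "strain_class"
  kept <- is.na(reason)
  rejected <- animals[!kept, , drop = FALSE]
  rejected$reason <- reason[!kept]
  list(kept = animals[kept, , drop = FALSE], rejected = rejected)
}

#' Summarize animals into sex groups
#'
#' One summary per distinct (project, parameter, strain, sex): group size,
#' mean, sample SD (n - 1 denominator) and CV = sd/mean. Groups of a single
#' animal get `sd = 0` and are flagged `degenerate` (they cannot survive any
#' sensible `min_n_per_sex` anyway); groups with non-positive mean are
#' flagged `valid = FALSE` since a CV is meaningless there.
#'
#' @param animals Tibble of admissible animals (see [filter_animals()]).
#' @return Tibble with one row per sex group: key columns plus `n`, `mean`,
#'   `sd`, `cv`, `valid`, `degenerate`.
#' @export
summarize_groups <- function(animals) {
  out <- animals |>
    dplyr::group_by(.data$project_id, .data$parameter_key, .data$strain,
                    .data$sex) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::mutate(degenerate = .data$n == 1L,
                  valid = .data$mean > 0,
                  cv = ifelse(.data$valid, .data$sd / .data$mean, NA_real_))
  out[, c("project_id", "parameter_key", "strain", "sex", "n", "mean", "sd",
          "cv", "valid", "degenerate")]
}

#' Pair female and male groups into strain data sets
#'
#' The atomic unit of the analysis is the strain data set: the female and
#' male group of one strain for one parameter within one project. A data set
#' is formed only when both sexes are present with `n >= min_n_per_sex` and
#' valid CVs; data sets where both CVs are exactly zero are dropped as
#' degenerate (the ratio would be 0/0). Drop tallies are attached as
#' attribute `"dropped"`.
#'
#' @param groups Tibble from [summarize_groups()] or
#'   [read_group_summary_table()].
#' @param criteria A [selection_criteria()] object; only `min_n_per_sex` is
#'   used here.
#' @return Tibble with one row per strain data set: key columns, per-sex
#'   `n_f`/`mean_f`/`sd_f`/`cv_f` and `n_m`/..., `cv_ratio`, `excluded`
#'   (all `FALSE`) and `exclusion_reason` (all `"none"`).
#' @export
pair_datasets <- function(groups, criteria = selection_criteria()) {
  g <- groups
  if (!"valid" %in% names(g)) g$valid <- TRUE
  eligible <- g$valid & g$n >= criteria$min_n_per_sex & !is.na(g$cv)
  g <- g[eligible, c("project_id", "parameter_key", "strain", "sex", "n",
                     "mean", "sd", "cv")]
  wide <- tidyr::pivot_wider(g,
                             id_cols = c("project_id", "parameter_key", "strain"),
                             names_from = "sex",
                             values_from = c("n", "mean", "sd", "cv"))
  for (col in c("n_f", "n_m", "mean_f", "mean_m", "sd_f", "sd_m",
                "cv_f", "cv_m")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  unpaired <- is.na(wide$cv_f) | is.na(wide$cv_m)
  degenerate <- !unpaired & wide$cv_f == 0 & wide$cv_m == 0
  dropped <- c(ineligible_groups = sum(!eligible),
               unpaired = sum(unpaired),
               degenerate = sum(degenerate))
  out <- wide[!unpaired & !degenerate, , drop = FALSE]
  out$cv_ratio <- cv_ratio(out$cv_f, out$cv_m)
  out$excluded <- FALSE
  out$exclusion_reason <- "none"
  out <- out[, c("project_id", "parameter_key", "strain",
                 "n_f", "mean_f", "sd_f", "cv_f",
                 "n_m", "mean_m", "sd_m", "cv_m",
                 "cv_ratio", "excluded", "exclusion_reason")]
  attr(out, "dropped") <- dropped
  out
}

#' Exclude high-variability outlier data sets
#'
#' A strain data set is an outlier when the female and/or the male group has
#' CV strictly above the threshold (default 0.5) -- unusually high
#' variability from technical outliers or unrecognized causes. The reason
#' code records which sex triggered the rule (`female_cv`, `male_cv`,
#' `both_cv`), supporting the female/male/both outlier breakdown.
#'
#' @param datasets Tibble from [pair_datasets()].
#' @param threshold Strict CV threshold; a CV exactly equal to it is kept.
#' @return List with `kept` and `excluded` tibbles partitioning the input;
#'   `excluded` rows carry `excluded = TRUE` and their reason code.
#' @export
apply_outlier_exclusion <- function(datasets, threshold = 0.5) {
  f_out <- datasets$cv_f > threshold
  m_out <- datasets$cv_m > threshold
  reason <- dplyr::case_when(f_out & m_out ~ "both_cv",
                             f_out ~ "female_cv",
                             m_out ~ "male_cv",
                             .default = "none")
  excl <- reason != "none"
  excluded <- datasets[excl, , drop = FALSE]
  excluded$excluded <- TRUE
  excluded$exclusion_reason <- reason[excl]
  list(kept = datasets[!excl, , drop = FALSE], excluded = excluded)
}
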