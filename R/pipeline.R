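#' Per-parameter analysis across group-size thresholds
#'
#' End-to-end orchestration of the parameter-level analysis: filter animals,
#' summarize sex groups, pair them into strain data sets at each group-size
#' threshold, exclude outlier data sets, and summarize every registry
#' parameter. By construction the data sets of a higher threshold are a
#' subset of those of a lower one. Consistency flags (mean-vs-proportion,
#' cross-threshold, significant-in-both) are computed when exactly the
#' thresholds 5 and 10 are requested.
#'
#' @param animals Per-animal tibble ([read_animal_table()] /
#'   [simulate_animals()]).
#' @param criteria Base [selection_criteria()]; `min_n_per_sex` is
#'   overridden by each entry of `thresholds`.
#' @param thresholds Integer vector of per-sex group-size thresholds.
#' @param registry Parameter registry.
#' @param alpha Significance level for the chi-squared tests.
#' @return List with `summaries` (named list of per-parameter tibbles, one
#'   per threshold), `flags` (tibble or `NULL`), `datasets` (named list of
#'   kept data-set tibbles), `excluded` (named list of excluded data-set
#'   tibbles) and `log` (tibble of selection and exclusion tallies).
#' @export
analyze_parameters <- function(animals,
                               criteria = selection_criteria(),
                               thresholds = c(5L, 10L),
                               registry = parameter_registry(),
                               alpha = 0.05) {
  fa <- filter_animals(animals, criteria)
  groups <- summarize_groups(fa$kept)
  summaries <- list()
  datasets <- list()
  excluded <- list()
  log_rows <- list()
  for (th in thresholds) {
    crit_th <- criteria
    crit_th$min_n_per_sex <- as.integer(th)
    ds <- pair_datasets(groups, crit_th)
    if (criteria$apply_outlier_exclusion) {
      split <- apply_outlier_exclusion(ds, criteria$outlier_cv_threshold)
    } else {
      split <- list(kept = ds, excluded = ds[0, , drop = FALSE])
    }
    key <- paste0("n", th)
    summaries[[key]] <- summarize_parameters(split$kept, th, registry)
    datasets[[key]] <- split$kept
    excluded[[key]] <- split$excluded
    log_rows[[key]] <- tibble::tibble(
      threshold = as.integer(th),
      animals_rejected = nrow(fa$rejected),
      datasets_formed = nrow(ds),
      datasets_excluded = nrow(split$excluded),
      excluded_female_cv = sum(split$excluded$exclusion_reason == "female_cv"),
      excluded_male_cv = sum(split$excluded$exclusion_reason == "male_cv"),
      excluded_both_cv = sum(split$excluded$exclusion_reason == "both_cv"))
  }
  flags <- NULL
  if (identical(sort(as.integer(thresholds)), c(5L, 10L))) {
    flags <- consistency_flags(summaries[["n5"]], summaries[["n10"]], alpha)
  }
  list(summaries = summaries, flags = flags, datasets = datasets,
       excluded = excluded, log = dplyr::bind_rows(log_rows))
}

#' Strain-family analysis
#'
#' The strain-level view: data sets selected at `min_n_per_sex = 5` with the
#' outlier-exclusion rule disabled (high-variability data sets stay in),
#' pooled into inbred-strain families by designation prefix, and summarized
#' per family and parameter. Overview counts report, per family, how many
#' parameters with at least 5 (and at least 1) data sets show a mean CV
#' ratio above 0.5.
#'
#' @param animals Per-animal tibble.
#' @param criteria [selection_criteria()]; defaults to the published rules
#'   with outlier exclusion disabled. A criteria object with the exclusion
#'   enabled is honoured but warned about, since the strain analysis is
#'   defined without it.
#' @param family_config A [strain_family_config()].
#' @param registry Parameter registry.
#' @return List with `grid` (family x parameter summaries), `overview`
#'   (tibble: family, min_datasets, count_gt_half, count_total) and
#'   `datasets` (the underlying data sets with a `strain_family` column).
#' @export
analyze_strains <- function(animals,
                            criteria = selection_criteria(
                              apply_outlier_exclusion = FALSE),
                            family_config = strain_family_config(),
                            registry = parameter_registry()) {
  if (criteria$apply_outlier_exclusion) {
    warning("strain-family analysis is defined without outlier exclusion; ",
            "applying it anyway as requested", call. = FALSE)
  }
  fa <- filter_animals(animals, criteria)
  groups <- summarize_groups(fa$kept)
  ds <- pair_datasets(groups, criteria)
  if (criteria$apply_outlier_exclusion) {
    ds <- apply_outlier_exclusion(ds, criteria$outlier_cv_threshold)$kept
  }
  ds$strain_family <- assign_family(ds$strain, family_config)
  grid <- summarize_strain_parameters(ds, family_config, registry)
  overview_rows <- list()
  for (fam in family_config$family) {
    fam_rows <- grid[grid$strain_family == fam, , drop = FALSE]
    for (md in c(5L, 1L)) {
      ov <- strain_overview(fam_rows, md)
      overview_rows[[paste(fam, md)]] <- tibble::tibble(
        strain_family = fam, min_datasets = md,
        count_gt_half = ov$count_gt_half, count_total = ov$count_total)
    }
  }
  list(grid = grid, overview = dplyr::bind_rows(overview_rows),
       datasets = ds)
}
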