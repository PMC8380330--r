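#' Strain-family configuration
#'
#' The strain-level analysis pools strain data sets into named inbred-strain
#' families by designation prefix (all C57BL/6-designated substrains count
#' as C57BL/6, and so on). The default reproduces the six most-examined
#' families; the CBA prefix carries the slash so that e.g. "CBA/J" matches
#' but a hypothetical "CBAX" strain would not.
#'
#' @param families Tibble or data frame with columns `family` and `prefix`.
#' @return Tibble of class `"strain_family_config"`.
#' @export
strain_family_config <- function(families = NULL) {
  if (is.null(families)) {
    families <- tibble::tibble(
      family = c("A/J", "BALB/c", "C3H", "C57BL/6", "CBA", "DBA/2J"),
      prefix = c("A/J", "BALB/c", "C3H", "C57BL/6", "CBA/", "DBA/2")
    )
  }
  families <- tibble::as_tibble(families)
  stopifnot(all(c("family", "prefix") %in% names(families)),
            all(nzchar(families$prefix)))
  class(families) <- c("strain_family_config", class(families))
  families
}

#' Assign strains to families by designation prefix
#'
#' Case-sensitive prefix match on the canonical strain designation; when a
#' strain matches several prefixes the longest prefix wins (this lets a
#' config carry e.g. both "C57BL/6" and "C57BL/6N" as distinct families).
#'
#' @param strain Character vector of strain designations.
#' @param config A [strain_family_config()].
#' @return Character vector of family names, `NA` where no prefix matches.
#' @examples
#' assign_family(c("C57BL/6J", "CBA/J", "NOD/ShiLtJ"))
#' @export
assign_family <- function(strain, config = strain_family_config()) {
  ord <- order(nchar(config$prefix), decreasing = TRUE)
  prefixes <- config$prefix[ord]
  fams <- config$family[ord]
  out <- rep(NA_character_, length(strain))
  for (i in seq_along(prefixes)) {
    hit <- is.na(out) & startsWith(strain, prefixes[i])
    out[hit] <- fams[i]
  }
  out
}

#' Summarize one strain family for one parameter
#'
#' Unweighted mean and sample SD of the CV ratios over the family's strain
#' data sets for that parameter. This analysis runs without outlier
#' exclusion, so callers pass data sets selected at `min_n_per_sex = 5`
#' with the exclusion rule disabled. With a single data set the SD is
#' reported absent. `gt_half` compares the UNROUNDED mean to 0.5: a mean of
#' 0.5008 prints as "0.50" but still counts as female-more-variable.
#'
#' @param datasets Strain data sets (no outlier exclusion applied).
#' @param family Family name to summarize.
#' @param parameter_key Parameter to summarize.
#' @param config A [strain_family_config()].
#' @return One-row tibble (`strain_family`, `parameter_key`, `n_datasets`,
#'   `mean_cv_ratio`, `sd_cv_ratio`, `gt_half`), or a zero-row tibble when
#'   the family has no data sets for the parameter (an absent cell).
#' @export
summarize_strain_parameter <- function(datasets, family, parameter_key,
                                       config = strain_family_config()) {
  fam <- assign_family(datasets$strain, config)
  d <- datasets[!is.na(fam) & fam == family &
                  datasets$parameter_key == parameter_key, , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble::tibble(strain_family = character(),
                          parameter_key = character(),
                          n_datasets = integer(),
                          mean_cv_ratio = numeric(),
                          sd_cv_ratio = numeric(),
                          gt_half = logical()))
  }
  r <- d$cv_ratio
  m <- mean(r)
  tibble::tibble(strain_family = family,
                 parameter_key = parameter_key,
                 n_datasets = nrow(d),
                 mean_cv_ratio = m,
                 sd_cv_ratio = if (nrow(d) > 1) stats::sd(r) else NA_real_,
                 gt_half = m > 0.5)
}

#' Summarize every family x parameter combination
#'
#' Builds the full strain-family grid: one row per (family, registry
#' parameter) combination that has at least one data set.
#'
#' @inheritParams summarize_strain_parameter
#' @param registry Parameter registry, see [parameter_registry()].
#' @return Tibble of [summarize_strain_parameter()] rows.
#' @export
summarize_strain_parameters <- function(datasets,
                                        config = strain_family_config(),
                                        registry = parameter_registry()) {
  rows <- list()
  for (fam in config$family) {
    for (k in registry$key) {
      rows[[length(rows) + 1L]] <-
        summarize_strain_parameter(datasets, fam, k, config)
    }
  }
  dplyr::bind_rows(rows)
}

#' Family overview counts
#'
#' For one family, counts how many parameters with at least `min_datasets`
#' data sets have a mean CV ratio above 0.5. `min_datasets = 5` gives the
#' stricter overview (only parameters backed by five or more data sets),
#' `min_datasets = 1` the inclusive one.
#'
#' @param family_summaries Rows of [summarize_strain_parameters()] for a
#'   single family.
#' @param min_datasets Minimum number of data sets for a parameter to count.
#' @return Named list `count_gt_half`, `count_total`.
#' @export
strain_overview <- function(family_summaries, min_datasets = 1L) {
  if (nrow(family_summaries) > 0 &&
      length(unique(family_summaries$strain_family)) > 1) {
    stop("family_summaries must belong to a single family", call. = FALSE)
  }
  s <- family_summaries[family_summaries$n_datasets >= min_datasets, ,
                        drop = FALSE]
  list(count_gt_half = sum(s$gt_half), count_total = nrow(s))
}
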