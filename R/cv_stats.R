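#' Coefficient-of-variation ratio
#'
#' The core statistic: `cv_female / (cv_female + cv_male)`. It lies in
#' \[0, 1\], equals 0.5 when both sexes are equally variable, exceeds 0.5
#' iff the female CV is larger, and satisfies the antisymmetry
#' `cv_ratio(a, b) + cv_ratio(b, a) = 1`. Unlike the plain CV quotient it is
#' bounded, so a near-zero male CV cannot blow the statistic up.
#'
#' @param cv_female,cv_male Non-negative CVs, recycled to common length.
#' @return Numeric vector of ratios in \[0, 1\].
#' @examples
#' cv_ratio(0.2, 0.2)  # 0.5
#' cv_ratio(1.0, 0.63) # 0.6135...
#' @export
cv_ratio <- function(cv_female, cv_male) {
  if (any(cv_female < 0, na.rm = TRUE) || any(cv_male < 0, na.rm = TRUE)) {
    stop("CVs must be non-negative", call. = FALSE)
  }
  total <- cv_female + cv_male
  if (any(!is.na(total) & total == 0)) {
    stop("cv_ratio undefined when both CVs are zero", call. = FALSE)
  }
  cv_female / total
}

# Commercial rounding: halves away from zero (printed percentages use this,
# not banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize the CV ratios of one parameter
#'
#' Aggregates the kept strain data sets of one parameter at one group-size
#' threshold into a single summary row: unweighted mean and sample SD of the
#' CV ratios (each data set counts once regardless of group size), strict
#' counts above/below 0.5, integer percentages, the ratio range, the total
#' number of mice and the number of contributing projects. Ties (ratio
#' exactly 0.5) are counted in neither bucket and excluded from the
#' percentage denominator, but enter mean/SD/range. No data sets is a valid
#' outcome: the summary is emitted with `empty = TRUE`.
#'
#' @param datasets Kept data sets (after selection and, where applicable,
#'   outlier exclusion); rows of other parameters are ignored.
#' @param parameter_key Parameter to summarize.
#' @param threshold The per-sex group-size threshold the data sets were
#'   selected at (recorded, not re-applied).
#' @return One-row tibble (see fields above).
#' @export
summarize_parameter <- function(datasets, parameter_key, threshold = 5L) {
  d <- datasets[datasets$parameter_key == parameter_key, , drop = FALSE]
  r <- d$cv_ratio
  n <- length(r)
  n_gt <- sum(r > 0.5)
  n_lt <- sum(r < 0.5)
  n_tie <- n - n_gt - n_lt
  denom <- n_gt + n_lt
  tibble::tibble(
    parameter_key = parameter_key,
    threshold = as.integer(threshold),
    n_datasets = n,
    mean_cv_ratio = if (n > 0) mean(r) else NA_real_,
    sd_cv_ratio = if (n > 1) stats::sd(r) else NA_real_,
    n_gt = n_gt,
    n_lt = n_lt,
    n_tie = n_tie,
    pct_gt = if (denom > 0) as.integer(round_half_up(100 * n_gt / denom)) else NA_integer_,
    pct_lt = if (denom > 0) as.integer(round_half_up(100 * n_lt / denom)) else NA_integer_,
    ratio_min = if (n > 0) min(r) else NA_real_,
    ratio_max = if (n > 0) max(r) else NA_real_,
    n_mice_total = if (n > 0) as.integer(sum(d$n_f + d$n_m)) else 0L,
    n_projects = length(unique(d$project_id)),
    empty = n == 0L
  )
}

#' Summarize all registry parameters
#'
#' One row per registry parameter in registry order, including empty rows
#' for parameters without surviving data sets.
#'
#' @inheritParams summarize_parameter
#' @param registry Parameter registry, see [parameter_registry()].
#' @return Tibble with one [summarize_parameter()] row per parameter.
#' @export
summarize_parameters <- function(datasets, threshold = 5L,
                                 registry = parameter_registry()) {
  dplyr::bind_rows(lapply(registry$key, function(k) {
    summarize_parameter(datasets, k, threshold)
  }))
}

#' Equal-split chi-squared test on data-set counts
#'
#' Tests the counts of data sets with ratio above vs below 0.5 against the
#' null of an equal split. For two cells with expected counts `(a+b)/2` the
#' Pearson statistic collapses to the closed form `(a - b)^2 / (a + b)`,
#' with 1 degree of freedom and an upper-tail p-value. No continuity
#' correction is applied (classical Pearson).
#'
#' @param n_gt,n_lt Counts of data sets with CV ratio above / below 0.5.
#' @param alpha Significance level.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `significant`,
#'   `evaluable` (`FALSE` when both counts are zero, in which case the other
#'   fields are `NA`).
#' @export
chi_squared_equal_split <- function(n_gt, n_lt, alpha = 0.05) {
  total <- n_gt + n_lt
  if (length(total) != 1 || is.na(total)) {
    stop("n_gt and n_lt must be single counts", call. = FALSE)
  }
  if (total == 0) {
    return(tibble::tibble(statistic = NA_real_, df = 1L, p_value = NA_real_,
                          significant = NA, evaluable = FALSE))
  }
  stat <- (n_gt - n_lt)^2 / total
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = 1L, p_value = p,
                 significant = p < alpha, evaluable = TRUE)
}

# sign() with the neutral point mapped to "agrees with nothing".
.side <- function(x) sign(x)

#' Mean-vs-proportion inconsistency flag
#'
#' A parameter is flagged when its mean CV ratio falls on the opposite side
#' of 0.5 from the majority of its individual data sets (e.g. a mean ratio
#' just below 0.5 while most data sets lie above it). Either quantity
#' exactly at its neutral point (mean = 0.5, or equal counts) flags nothing.
#'
#' @param summary One-row tibble from [summarize_parameter()].
#' @return Logical; `NA` for an empty summary.
#' @export
flag_mean_vs_proportion <- function(summary) {
  if (summary$empty) return(NA)
  s_mean <- .side(summary$mean_cv_ratio - 0.5)
  s_count <- .side(summary$n_gt - summary$n_lt)
  s_mean != 0 && s_count != 0 && s_mean != s_count
}

#' Cross-threshold inconsistency flag
#'
#' Flags a parameter whose mean CV ratio lies strictly above 0.5 in the
#' n >= 5 analysis and strictly below in the n >= 10 analysis, or vice
#' versa. A mean exactly at 0.5 in either analysis is no strict sign flip.
#'
#' @param summary5,summary10 One-row tibbles from [summarize_parameter()]
#'   for the same parameter at thresholds 5 and 10.
#' @return Logical; `NA` when either summary is empty.
#' @export
flag_cross_threshold <- function(summary5, summary10) {
  if (summary5$parameter_key != summary10$parameter_key) {
    stop("summaries refer to different parameters", call. = FALSE)
  }
  if (summary5$empty || summary10$empty) return(NA)
  s5 <- .side(summary5$mean_cv_ratio - 0.5)
  s10 <- .side(summary10$mean_cv_ratio - 0.5)
  s5 != 0 && s10 != 0 && s5 != s10
}

#' Consistent significance across both analyses
#'
#' `TRUE` iff the equal-split chi-squared test rejects at `alpha` for the
#' data-set counts of both the n >= 5 and the n >= 10 analysis of a
#' parameter -- the criterion for a consistent, significant departure from
#' equal numbers above and below 0.5.
#'
#' @inheritParams flag_cross_threshold
#' @param alpha Significance level.
#' @return Logical; `FALSE` (not evaluable) when either summary is empty.
#' @export
significant_in_both <- function(summary5, summary10, alpha = 0.05) {
  if (summary5$empty || summary10$empty) return(FALSE)
  t5 <- chi_squared_equal_split(summary5$n_gt, summary5$n_lt, alpha)
  t10 <- chi_squared_equal_split(summary10$n_gt, summary10$n_lt, alpha)
  isTRUE(t5$significant) && isTRUE(t10$significant)
}

#' Consistency flags for all parameters
#'
#' Combines the three per-parameter checks across the two analyses into one
#' table. `mean_vs_proportion_inconsistent` is the OR of the per-threshold
#' flags, which are also reported individually.
#'
#' @param summaries5,summaries10 Tibbles from [summarize_parameters()] at
#'   thresholds 5 and 10 (same parameter order).
#' @param alpha Significance level for the chi-squared tests.
#' @return Tibble with one row per parameter and logical flag columns.
#' @export
consistency_flags <- function(summaries5, summaries10, alpha = 0.05) {
  stopifnot(identical(summaries5$parameter_key, summaries10$parameter_key))
  rows <- lapply(seq_len(nrow(summaries5)), function(i) {
    s5 <- summaries5[i, ]
    s10 <- summaries10[i, ]
    mvp5 <- flag_mean_vs_proportion(s5)
    mvp10 <- flag_mean_vs_proportion(s10)
    tibble::tibble(
      parameter_key = s5$parameter_key,
      mean_vs_proportion_inconsistent_n5 = mvp5,
      mean_vs_proportion_inconsistent_n10 = mvp10,
      mean_vs_proportion_inconsistent = isTRUE(mvp5) | isTRUE(mvp10),
      cross_threshold_inconsistent = flag_cross_threshold(s5, s10),
      significant_in_both = significant_in_both(s5, s10, alpha)
    )
  })
  dplyr::bind_rows(rows)
}
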