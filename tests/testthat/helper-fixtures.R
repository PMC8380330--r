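# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# n values with exactly the requested mean and sample SD (hence exact CV),
# so per-animal inputs can be driven to exact CV ratios.
group_values <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# Animal rows for one sex group.
animal_group <- function(project, param, strain, sex, values,
                         age = 10, treated = FALSE, class = "inbred") {
  tibble::tibble(project_id = project, parameter_key = param, strain = strain,
                 strain_class = class, sex = sex, age_weeks = age,
                 treated = treated, value = values)
}

# A full strain data set (female + male animals) with exact group CVs.
animal_dataset <- function(project, param, strain, n_f = 5, n_m = 5,
                           cv_f = 0.2, cv_m = 0.2, mean = 100, age = 10,
                           treated = FALSE, class = "inbred") {
  dplyr::bind_rows(
    animal_group(project, param, strain, "f", group_values(n_f, mean, cv_f * mean),
                 age, treated, class),
    animal_group(project, param, strain, "m", group_values(n_m, mean, cv_m * mean),
                 age, treated, class))
}

# Data-set rows with prescribed CV ratios (cv_f = r, cv_m = 1 - r).
datasets_with_ratios <- function(ratios, param = "cholesterol",
                                 project = "p1", n = 10L) {
  tibble::tibble(
    project_id = project, parameter_key = param,
    strain = paste0("S", seq_along(ratios)),
    n_f = as.integer(n), mean_f = 100, sd_f = 100 * ratios, cv_f = ratios,
    n_m = as.integer(n), mean_m = 100, sd_m = 100 * (1 - ratios),
    cv_m = 1 - ratios,
    cv_ratio = cv_ratio(ratios, 1 - ratios),
    excluded = FALSE, exclusion_reason = "none")
}

# A minimal one-row parameter summary carrying just what the consistency
# flags consume.
summary_stub <- function(mean, n_gt, n_lt, key = "x", empty = FALSE) {
  tibble::tibble(parameter_key = key, mean_cv_ratio = mean,
                 n_gt = as.integer(n_gt), n_lt = as.integer(n_lt),
                 empty = empty)
}

# The A/J column of the published strain-family table: printed mean CV
# ratio, number of data sets, and whether the entry was marked as female
# more variable (mean above 0.5 before rounding). Parameters without any
# A/J data set (ferritin, transferrin, CK) are absent.
aj_family_column <- function() {
  tibble::tribble(
    ~parameter_key,  ~mean_cv_ratio, ~n_datasets, ~gt_half,
    "cholesterol",   0.56,  9L, TRUE,
    "creatinine",    0.49,  2L, FALSE,
    "glucose",       0.60,  7L, TRUE,
    "total_protein", 0.49,  3L, FALSE,
    "triglycerides", 0.55,  9L, TRUE,
    "urea",          0.50,  5L, TRUE,
    "uric_acid",     0.44,  1L, FALSE,
    "calcium",       0.49,  5L, FALSE,
    "chloride",      0.53,  3L, TRUE,
    "phosphorus",    0.54,  3L, TRUE,
    "potassium",     0.54,  3L, TRUE,
    "sodium",        0.48,  3L, FALSE,
    "alt",           0.47,  1L, FALSE,
    "ast",           0.45,  3L, FALSE,
    "alpha_amylase", 0.55,  2L, TRUE,
    "ap",            0.50,  3L, TRUE,
    "lipase",        0.44,  1L, FALSE,
    "hemoglobin",    0.51, 10L, TRUE,
    "mcv",           0.56, 10L, TRUE,
    "rbc",           0.52,  9L, TRUE,
    "wbc",           0.51, 11L, TRUE,
    "platelets",     0.56, 10L, TRUE) |>
    dplyr::mutate(strain_family = "A/J", sd_cv_ratio = NA_real_,
                  .before = 1)
}
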