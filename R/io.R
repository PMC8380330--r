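#' Default column-header dialect
#'
#' Input tables come from heterogeneous exports, so column headers are mapped
#' to canonical field names through a "dialect": a named list whose names are
#' the canonical fields and whose values are the headers present in the file.
#' The default follows MPD-style exports (`projsym`, `strain`, `sex`,
#' `value`, `age_weeks`, ...).
#'
#' @return Named list mapping canonical field names to file headers.
#' @seealso [read_dialect()] to load a dialect from a YAML file.
#' @export
default_dialect <- function() {
  list(
    project_id    = "projsym",
    parameter_key = "parameter",
    strain        = "strain",
    strain_class  = "strain_class",
    sex           = "sex",
    age_weeks     = "age_weeks",
    treated       = "treated",
    value         = "value",
    n             = "n",
    mean          = "mean",
    sd            = "sd"
  )
}

#' Read a column-header dialect from a YAML file
#'
#' Fields absent from the file fall back to the default dialect, so a config
#' only needs to name the headers that differ.
#'
#' @param path Path to a YAML file of `canonical_field: file_header` pairs.
#' @return Named list as in [default_dialect()].
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) {
    stop("dialect config not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  d <- default_dialect()
  unknown <- setdiff(names(user), names(d))
  if (length(unknown) > 0) {
    stop("unknown dialect fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d[names(user)] <- user
  d
}

# Delimiter sniffing: tab wins over comma if present in the header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_raw_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  readr::read_delim(path, delim = delim,
                    col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

# Map file headers to canonical names; `required` must all be present.
map_headers <- function(raw, dialect, required, context) {
  missing <- required[!unlist(dialect[required]) %in% names(raw)]
  if (length(missing) > 0) {
    stop("cannot map required column(s) for ", context, ": ",
         paste(sprintf("%s (header '%s')", missing,
                       unlist(dialect[missing])), collapse = ", "),
         call. = FALSE)
  }
  present <- names(dialect)[unlist(dialect) %in% names(raw)]
  out <- raw[, unlist(dialect[present]), drop = FALSE]
  names(out) <- present
  out
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("f", "female")] <- "f"
  out[x %in% c("m", "male")] <- "m"
  out
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

STRAIN_CLASSES <- c("inbred", "cc_inbred", "f1_hybrid", "recombinant_inbred",
                    "other")

#' Read a per-animal measurement table
#'
#' One row per animal and parameter. Rows with a missing or unparseable
#' value, or an unrecognizable sex code, are skipped (not fatal); the number
#' of skipped rows is reported and attached as attribute `"skipped"`.
#' A missing `strain_class` column defaults every animal to `"inbred"` with
#' a warning; a missing `treated` column defaults to untreated.
#'
#' @param path Path to a comma- or tab-separated file with one header row.
#' @param dialect Header mapping, see [default_dialect()].
#' @return Tibble with columns `project_id`, `parameter_key`, `strain`,
#'   `strain_class`, `sex` (`"f"`/`"m"`), `age_weeks`, `treated`, `value`.
#' @export
read_animal_table <- function(path, dialect = default_dialect()) {
  raw <- read_raw_table(path)
  x <- map_headers(raw, dialect,
                   required = c("project_id", "parameter_key", "strain",
                                "sex", "age_weeks", "value"),
                   context = "animal table")
  n0 <- nrow(x)
  if (!"strain_class" %in% names(x)) {
    warning("no strain_class column; defaulting all animals to 'inbred'",
            call. = FALSE)
    x$strain_class <- "inbred"
  }
  if (!"treated" %in% names(x)) x$treated <- "false"

  x$sex <- normalize_sex(x$sex)
  x$value <- suppressWarnings(as.numeric(x$value))
  x$age_weeks <- suppressWarnings(as.numeric(x$age_weeks))
  x$treated <- parse_logical(x$treated)
  x$treated[is.na(x$treated)] <- FALSE
  x$strain_class <- tolower(trimws(x$strain_class))
  bad_class <- !x$strain_class %in% STRAIN_CLASSES
  if (any(bad_class)) x$strain_class[bad_class] <- "other"

  keep <- !is.na(x$sex) & !is.na(x$value) & !is.na(x$age_weeks) &
    x$age_weeks >= 0
  skipped <- n0 - sum(keep)
  if (skipped > 0) {
    rlang::inform(sprintf("read_animal_table: skipped %d of %d row(s) with missing/invalid sex, value or age",
                          skipped, n0))
  }
  out <- tibble::as_tibble(x[keep, c("project_id", "parameter_key", "strain",
                                     "strain_class", "sex", "age_weeks",
                                     "treated", "value")])
  attr(out, "skipped") <- skipped
  out
}

#' Read a per-group summary table
#'
#' One row per strain x sex group with `n`, `mean` and `sd`. The CV is
#' always recomputed as `sd/mean`, overriding any CV column in the file.
#' Groups with `mean <= 0` are kept but flagged `valid = FALSE` (every
#' parameter in scope is strictly positive, so a non-positive mean signals a
#' broken record rather than a usable CV); rows with `n < 1` are rejected.
#'
#' @inheritParams read_animal_table
#' @return Tibble with columns `project_id`, `parameter_key`, `strain`,
#'   `sex`, `n`, `mean`, `sd`, `cv`, `valid`.
#' @export
read_group_summary_table <- function(path, dialect = default_dialect()) {
  raw <- read_raw_table(path)
  x <- map_headers(raw, dialect,
                   required = c("project_id", "parameter_key", "strain",
                                "sex", "n", "mean", "sd"),
                   context = "group summary table")
  n0 <- nrow(x)
  x$sex <- normalize_sex(x$sex)
  x$n <- suppressWarnings(as.integer(x$n))
  x$mean <- suppressWarnings(as.numeric(x$mean))
  x$sd <- suppressWarnings(as.numeric(x$sd))

  keep <- !is.na(x$sex) & !is.na(x$n) & x$n >= 1L &
    !is.na(x$mean) & !is.na(x$sd) & x$sd >= 0
  rejected <- n0 - sum(keep)
  if (rejected > 0) {
    rlang::inform(sprintf("read_group_summary_table: rejected %d of %d row(s) (n < 1 or unparseable fields)",
                          rejected, n0))
  }
  x <- x[keep, , drop = FALSE]
  x$valid <- x$mean > 0
  x$cv <- ifelse(x$valid, x$sd / x$mean, NA_real_)
  out <- tibble::as_tibble(x[, c("project_id", "parameter_key", "strain",
                                 "sex", "n", "mean", "sd", "cv", "valid")])
  attr(out, "rejected") <- rejected
  out
}

#' Write an animal or group-summary table
#'
#' Tab-separated, full double precision, so write-then-read round-trips
#' exactly. `write_animal_table()` emits the default-dialect headers so its
#' output is readable by [read_animal_table()] without configuration.
#'
#' @param x Tibble as returned by [read_animal_table()] /
#'   [read_group_summary_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_animal_table <- function(x, path) {
  out <- x[, c("project_id", "parameter_key", "strain", "strain_class",
               "sex", "age_weeks", "treated", "value")]
  names(out) <- c("projsym", "parameter", "strain", "strain_class", "sex",
                  "age_weeks", "treated", "value")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_animal_table
#' @export
write_group_summary_table <- function(x, path) {
  out <- x[, c("project_id", "parameter_key", "strain", "sex", "n", "mean",
               "sd", "cv")]
  names(out)[1:2] <- c("projsym", "parameter")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Format a CV ratio for tabular output
#'
#' Ratios are printed to 2 decimals, except that a value whose 2-decimal
#' rounding would print exactly `"0.50"` is printed to 3 decimals instead:
#' whether a mean ratio falls above or below 0.5 is the quantity of interest,
#' and 2-decimal rounding would erase it (a mean of 0.496 must not read as
#' 0.50).
#'
#' @param x Numeric vector of ratios; `NA` renders as the empty-cell marker.
#' @param na Marker used for `NA` entries.
#' @return Character vector.
#' @examples
#' format_cv_ratio(c(0.4961, 0.52, 0.5)) # "0.496" "0.52" "0.500"
#' @export
format_cv_ratio <- function(x, na = "-") {
  out <- sprintf("%.2f", x)
  three <- !is.na(x) & out == "0.50"
  out[three] <- sprintf("%.3f", x[three])
  out[is.na(x)] <- na
  out
}

#' Write parameter-level and strain-level summary tables
#'
#' Emits one row per summary in the column order of the per-parameter
#' analysis. Empty summaries (no data sets survived selection) are rendered
#' with `"-"` markers. Ratio columns follow the [format_cv_ratio()] rule;
#' every flag is also emitted as an explicit boolean column so no
#' information is carried by formatting alone.
#'
#' @param summaries Tibble from [summarize_parameters()] (optionally joined
#'   with [consistency_flags()]) or [summarize_strain_parameters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_summary_table <- function(summaries, path) {
  s <- summaries
  out <- tibble::tibble(
    parameter     = s$parameter_key,
    threshold     = s$threshold,
    n_datasets    = s$n_datasets,
    mean_cv_ratio = format_cv_ratio(s$mean_cv_ratio),
    sd_cv_ratio   = ifelse(is.na(s$sd_cv_ratio), "-",
                           sprintf("%.2f", s$sd_cv_ratio)),
    pct_gt        = ifelse(is.na(s$pct_gt), "-", as.character(s$pct_gt)),
    n_gt          = s$n_gt,
    pct_lt        = ifelse(is.na(s$pct_lt), "-", as.character(s$pct_lt)),
    n_lt          = s$n_lt,
    n_tie         = s$n_tie,
    range         = ifelse(s$empty, "-",
                           paste0(format_cv_ratio(s$ratio_min), "-",
                                  format_cv_ratio(s$ratio_max))),
    n_mice_total  = s$n_mice_total,
    n_projects    = s$n_projects,
    empty         = s$empty
  )
  flag_cols <- intersect(c("mean_vs_proportion_inconsistent",
                           "cross_threshold_inconsistent",
                           "significant_in_both"), names(s))
  for (fc in flag_cols) out[[fc]] <- s[[fc]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_parameter_summary_table
#' @export
write_strain_summary_table <- function(summaries, path) {
  s <- summaries
  out <- tibble::tibble(
    strain_family = s$strain_family,
    parameter     = s$parameter_key,
    n_datasets    = s$n_datasets,
    mean_cv_ratio = format_cv_ratio(s$mean_cv_ratio),
    sd_cv_ratio   = ifelse(is.na(s$sd_cv_ratio), "-",
                           sprintf("%.2f", s$sd_cv_ratio)),
    gt_half       = s$gt_half
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
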