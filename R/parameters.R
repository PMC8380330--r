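#' Registry of the 25 blood parameters
#'
#' The analysis covers a comprehensive blood screen of 25 clinical-chemical
#' and hematological parameters, each selected in the Mouse Phenome Database
#' by a vertebrate-trait (VT) ontology term. Mean corpuscular volume (MCV)
#' is the one parameter without a VT term. Derived quantities (hematocrit,
#' MCH, MCHC) are deliberately absent: they are computed from directly
#' measured parameters and would double-count their variability.
#'
#' @param path Optional path to a tab-separated registry file with columns
#'   `key`, `vt_term`, `display_name`. Defaults to the registry bundled with
#'   the package.
#' @return A tibble with columns `key` (unique short name), `vt_term`
#'   (`NA` where no ontology term applies) and `display_name`.
#' @examples
#' reg <- parameter_registry()
#' nrow(reg) # 25
#' @export
parameter_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parameters.tsv", package = "micecvr",
                        mustWork = TRUE)
  }
  reg <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("key", "vt_term", "display_name")
  if (!all(required %in% names(reg))) {
    stop("parameter registry must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  reg$vt_term[!is.na(reg$vt_term) & reg$vt_term == ""] <- NA_character_
  if (anyDuplicated(reg$key)) {
    stop("parameter registry keys must be unique", call. = FALSE)
  }
  tibble::as_tibble(reg)
}
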