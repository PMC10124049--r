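#' Write a cohort to CSV with a JSON schema sidecar
#'
#' The patient table is written as plain CSV (missing cells empty); the
#' feature schema (and generator config, when present) goes to
#' `<path>.schema.json` so a cohort can be read back without loss.
#'
#' @param cohort An `icu_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  sidecar <- lapply(cohort$schema, function(s) s[!vapply(s, is.null, TRUE)])
  jsonlite::write_json(sidecar, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path; `<path>.schema.json` must exist alongside it.
#' @return An `icu_cohort`.
#' @export
read_cohort <- function(path) {
  raw <- jsonlite::read_json(paste0(path, ".schema.json"))
  schema <- lapply(raw, function(s) {
    feature_spec(
      name = s$name, kind = s$kind,
      reference_value = s$reference_value %||% NA_real_,
      low_mode = s$low_mode %||% NA_real_,
      high_mode = s$high_mode %||% NA_real_,
      sd = s$sd %||% NULL,
      categories = if (!is.null(s$categories)) unlist(s$categories),
      base_rate = s$base_rate %||% NA_real_,
      missing_rate = s$missing_rate %||% 0,
      severity_loading = s$severity_loading %||% 0
    )
  })
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  # categorical columns must stay character even if fully missing
  for (s in schema) {
    if (s$kind == "categorical") dat[[s$name]] <- as.character(dat[[s$name]])
  }
  new_cohort(dat, schema)
}
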