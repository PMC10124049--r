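#' Describe one cohort feature
#'
#' A feature specification drives both the synthetic generator and the
#' preprocessing stages. Continuous features model "worst value in the first
#' 24 h" measurements: the recorded value is the one furthest from a clinical
#' reference value, which produces characteristically bimodal distributions
#' (one peak below and one above the reference). The two mixture components
#' are centred at `low_mode` and `high_mode`; the probability of drawing from
#' the mode further from the reference grows with the patient's latent
#' severity scaled by `severity_loading`.
#'
#' @param name Feature name (unique within a schema).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param reference_value Clinical reference value, in feature units
#'   (continuous only; required).
#' @param low_mode,high_mode Locations of the two worst-value peaks
#'   (continuous only). Equal modes give a unimodal feature.
#' @param sd Standard deviation of each mixture component. Defaults to 10% of
#'   `|high_mode - low_mode|`, or 5% of `max(|reference_value|, 1)` when the
#'   modes coincide.
#' @param categories Character vector of at least two category labels
#'   (categorical only).
#' @param base_rate Baseline probability of a 1 (binary only).
#' @param missing_rate Fraction of values missing, in `[0, 1]`.
#' @param severity_loading Effect of the latent severity on this feature:
#'   for continuous features it tilts draws toward the extreme mode, for
#'   binary features it shifts the log-odds of a 1, for categorical features
#'   it tilts the category distribution toward later categories.
#'
#' @return An object of class `feature_spec`.
#' @export
#' @examples
#' feature_spec("bun", "continuous", reference_value = 12,
#'              low_mode = 12, high_mode = 70, severity_loading = 1.6)
feature_spec <- function(name,
                         kind = c("continuous", "binary", "categorical"),
                         reference_value = NA_real_,
                         low_mode = NA_real_,
                         high_mode = NA_real_,
                         sd = NULL,
                         categories = NULL,
                         base_rate = NA_real_,
                         missing_rate = 0,
                         severity_loading = 0) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("feature name must be a non-empty string")
  }
  if (!is_scalar_number(missing_rate) || missing_rate < 0 || missing_rate > 1) {
    stopf("missing_rate for '%s' must lie in [0, 1]", name)
  }
  if (kind == "continuous") {
    if (!is_scalar_number(reference_value)) {
      stopf("continuous feature '%s' must carry a reference_value", name)
    }
    if (!is_scalar_number(low_mode) || !is_scalar_number(high_mode)) {
      stopf("continuous feature '%s' needs low_mode and high_mode", name)
    }
    if (is.null(sd)) {
      sd <- if (high_mode != low_mode) {
        0.1 * abs(high_mode - low_mode)
      } else {
        0.05 * max(abs(reference_value), 1)
      }
    }
  }
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L) {
      stopf("categorical feature '%s' must list at least 2 categories", name)
    }
    categories <- as.character(categories)
  }
  if (kind == "binary") {
    if (!is_scalar_number(base_rate) || base_rate <= 0 || base_rate >= 1) {
      stopf("binary feature '%s' needs a base_rate in (0, 1)", name)
    }
  }
  structure(
    list(
      name = name, kind = kind,
      reference_value = reference_value,
      low_mode = low_mode, high_mode = high_mode, sd = sd,
      categories = categories, base_rate = base_rate,
      missing_rate = missing_rate, severity_loading = severity_loading
    ),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s (%s)\n", x$name, x$kind))
  invisible(x)
}

#' Default eICU/APACHE-like feature schema
#'
#' A schema emulating the feature table used for APACHE-style mortality
#' prediction: worst-in-24h physiology and lab values (several bimodal),
#' Glasgow Coma Scale components, anthropometrics, binary ventilation /
#' chronic-health flags, and categorical admission features. FiO2 carries a
#' 73.2% missing rate, matching the high missingness that oxygenation
#' variables show in ICU feature tables. Blood urea nitrogen (`bun`) carries
#' the largest severity loading, making it the planted "most informative"
#' feature for attribution tests.
#'
#' @return A list of [feature_spec()] objects.
#' @export
default_feature_specs <- function() {
  list(
    feature_spec("age", "continuous", reference_value = 62,
                 low_mode = 62, high_mode = 62, sd = 15,
                 missing_rate = 0, severity_loading = 0.15),
    feature_spec("heartrate", "continuous", reference_value = 75,
                 low_mode = 48, high_mode = 130, missing_rate = 0,
                 severity_loading = 0.5),
    feature_spec("meanbp", "continuous", reference_value = 90,
                 low_mode = 52, high_mode = 148, missing_rate = 0.02,
                 severity_loading = 0.5),
    feature_spec("respiratoryrate", "continuous", reference_value = 16,
                 low_mode = 8, high_mode = 36, missing_rate = 0,
                 severity_loading = 0.45),
    feature_spec("temperature", "continuous", reference_value = 37,
                 low_mode = 34.6, high_mode = 39.4, missing_rate = 0.05,
                 severity_loading = 0.5),
    feature_spec("bun", "continuous", reference_value = 12,
                 low_mode = 12, high_mode = 70, missing_rate = 0.05,
                 severity_loading = 2.6),
    feature_spec("creatinine", "continuous", reference_value = 1,
                 low_mode = 1, high_mode = 4.5, missing_rate = 0.15,
                 severity_loading = 0.6),
    feature_spec("sodium", "continuous", reference_value = 140,
                 low_mode = 128, high_mode = 152, missing_rate = 0.1,
                 severity_loading = 0.4),
    feature_spec("wbc", "continuous", reference_value = 8,
                 low_mode = 2.5, high_mode = 24, missing_rate = 0.12,
                 severity_loading = 0.5),
    feature_spec("albumin", "continuous", reference_value = 4,
                 low_mode = 1.8, high_mode = 4, missing_rate = 0.4,
                 severity_loading = 0.6),
    feature_spec("ph", "continuous", reference_value = 7.4,
                 low_mode = 7.15, high_mode = 7.55, missing_rate = 0.3,
                 severity_loading = 0.5),
    feature_spec("fio2", "continuous", reference_value = 0.21,
                 low_mode = 0.21, high_mode = 0.9, missing_rate = 0.732,
                 severity_loading = 0.6),
    feature_spec("glucose", "continuous", reference_value = 100,
                 low_mode = 58, high_mode = 270, missing_rate = 0.1,
                 severity_loading = 0.5),
    feature_spec("hematocrit", "continuous", reference_value = 42,
                 low_mode = 25, high_mode = 52, missing_rate = 0.1,
                 severity_loading = 0.3),
    feature_spec("gcs_eyes", "continuous", reference_value = 4,
                 low_mode = 1, high_mode = 4, missing_rate = 0.05,
                 severity_loading = 0.55),
    feature_spec("gcs_motor", "continuous", reference_value = 6,
                 low_mode = 1, high_mode = 6, missing_rate = 0.05,
                 severity_loading = 0.6),
    feature_spec("gcs_verbal", "continuous", reference_value = 5,
                 low_mode = 1, high_mode = 5, missing_rate = 0.05,
                 severity_loading = 0.7),
    feature_spec("admissionheight", "continuous", reference_value = 170,
                 low_mode = 170, high_mode = 170, sd = 10,
                 missing_rate = 0.03, severity_loading = 0),
    feature_spec("admissionweight", "continuous", reference_value = 80,
                 low_mode = 80, high_mode = 80, sd = 16,
                 missing_rate = 0.03, severity_loading = 0),
    feature_spec("vent", "binary", base_rate = 0.22, severity_loading = 1.0),
    feature_spec("intubated", "binary", base_rate = 0.12,
                 severity_loading = 0.9),
    feature_spec("electivesurgery", "binary", base_rate = 0.2,
                 severity_loading = -0.8),
    feature_spec("chronic_condition", "binary", base_rate = 0.15,
                 severity_loading = 0.3),
    feature_spec("adx", "categorical",
                 categories = c("cardiovascular", "respiratory", "neuro",
                                "gastrointestinal", "sepsis", "trauma"),
                 severity_loading = 0.25),
    feature_spec("unit_admit_source", "categorical",
                 categories = c("emergency", "operating_room", "floor",
                                "other"),
                 severity_loading = 0.2),
    feature_spec("sex", "categorical", categories = c("F", "M"),
                 severity_loading = 0)
  )
}

schema_names <- function(schema, kind = NULL) {
  keep <- vapply(schema, function(s) is.null(kind) || s$kind %in% kind, TRUE)
  vapply(schema[keep], `[[`, "", "name")
}

schema_get <- function(schema, name) {
  for (s in schema) if (s$name == name) return(s)
  stopf("feature '%s' not found in schema", name)
}
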