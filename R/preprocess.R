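#' Patient selection criteria
#'
#' Encodes the standard inclusion filters for APACHE-style mortality
#' modelling: adults only, ICU stays of at least 24 hours (so the
#' worst-in-24h summaries are complete), a single unit stay per patient, and
#' non-missing key fields.
#'
#' @param min_age Minimum age in years (default 18).
#' @param min_icu_los_hours Minimum ICU length of stay in hours (default 24).
#' @param max_unit_stays Maximum number of unit stays (default 1).
#' @param required_fields Fields that must be non-missing. `NULL` (default)
#'   means: every categorical schema feature plus `age`, `outcome` and
#'   `reference_probability`.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_age = 18, min_icu_los_hours = 24,
                               max_unit_stays = 1, required_fields = NULL) {
  if (min_age <= 0 || min_icu_los_hours <= 0 || max_unit_stays <= 0) {
    stopf("selection thresholds must be positive")
  }
  structure(list(min_age = min_age,
                 min_icu_los_hours = min_icu_los_hours,
                 max_unit_stays = max_unit_stays,
                 required_fields = required_fields),
            class = "selection_criteria")
}

#' Apply patient-selection filters
#'
#' Removes patients with more than `max_unit_stays` unit stays, below the age
#' bound, with an ICU stay shorter than the bound, or with any required field
#' missing. Each excluded patient is logged with the first matching reason,
#' in that order (`"unit_stays"`, `"age"`, `"los"`, `"missing"`). Idempotent.
#'
#' @param cohort An `icu_cohort`.
#' @param criteria A [selection_criteria()].
#' @return A list with elements `cohort` (the retained patients) and
#'   `exclusions` (tibble of `patient_id`, `reason`).
#' @export
select_patients <- function(cohort, criteria = selection_criteria()) {
  dat <- cohort$data
  req <- criteria$required_fields
  if (is.null(req)) {
    req <- c(setdiff(schema_names(cohort$schema, "categorical"), "sex"),
             intersect(c("sex", "age", "outcome", "reference_probability"),
                       names(dat)))
  }
  reason <- rep(NA_character_, nrow(dat))
  hit <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  hit(dat$n_unit_stays > criteria$max_unit_stays, "unit_stays")
  hit(dat$age < criteria$min_age, "age")
  hit(dat$icu_los_hours < criteria$min_icu_los_hours, "los")
  any_missing <- Reduce(`|`, lapply(req, function(f) is.na(dat[[f]])),
                        rep(FALSE, nrow(dat)))
  hit(any_missing, "missing")

  keep <- is.na(reason)
  if (!any(keep)) {
    stopf("no patients remain after selection (all %d excluded)", nrow(dat))
  }
  list(
    cohort = new_cohort(dat[keep, , drop = FALSE], cohort$schema),
    exclusions = tibble::tibble(patient_id = dat$patient_id[!keep],
                                reason = reason[!keep])
  )
}

#' Impute artefactual heights and weights
#'
#' Heights outside (100, 250) cm and weights outside (30, 300) kg are assumed
#' to be recording artefacts and replaced by the mean of the patient's sex
#' computed over in-range values. A sex stratum with no in-range values falls
#' back to the overall in-range mean (logged via a message).
#'
#' @param cohort An `icu_cohort` with `admissionheight`, `admissionweight`
#'   and `sex` columns.
#' @param height_range,weight_range Open plausibility intervals.
#' @return A new `icu_cohort` with all retained values strictly in range
#'   (missing values are left missing).
#' @export
impute_anthropometrics <- function(cohort,
                                   height_range = c(100, 250),
                                   weight_range = c(30, 300)) {
  dat <- cohort$data
  fix <- function(x, rng) {
    in_range <- !is.na(x) & x > rng[1] & x < rng[2]
    bad <- !is.na(x) & !in_range
    if (!any(bad)) return(x)
    overall <- mean(x[in_range])
    for (s in unique(dat$sex[bad])) {
      sel <- dat$sex == s
      m <- mean(x[sel & in_range])
      if (is.nan(m)) {
        message(sprintf("no in-range values for sex '%s'; using overall mean", s))
        m <- overall
      }
      x[bad & sel] <- m
    }
    x
  }
  dat$admissionheight <- fix(dat$admissionheight, height_range)
  dat$admissionweight <- fix(dat$admissionweight, weight_range)
  new_cohort(dat, cohort$schema)
}

#' Fit a training-set mean imputer
#'
#' Records the training-partition mean of every continuous feature. Test-set
#' values never enter the state, so applying the imputer to any other
#' partition cannot leak information.
#'
#' @param train An `icu_cohort` (training partition only).
#' @return An object of class `icu_imputer` holding `feature_means`.
#' @export
fit_imputer <- function(train) {
  cont <- schema_names(train$schema, "continuous")
  means <- vapply(cont, function(f) mean(train$data[[f]], na.rm = TRUE), 0)
  empty <- cont[is.nan(means)]
  if (length(empty)) {
    stopf("feature(s) entirely missing in training partition: %s",
          paste(empty, collapse = ", "))
  }
  structure(list(feature_means = means), class = "icu_imputer")
}

#' Replace missing continuous values with training means
#'
#' @param state An `icu_imputer` from [fit_imputer()].
#' @param cohort Cohort to impute (training or test partition).
#' @return A new `icu_cohort` with no missing continuous values. Pure: the
#'   state is never modified.
#' @export
apply_imputer <- function(state, cohort) {
  dat <- cohort$data
  for (f in names(state$feature_means)) {
    miss <- is.na(dat[[f]])
    if (any(miss)) dat[[f]][miss] <- state$feature_means[[f]]
  }
  new_cohort(dat, cohort$schema)
}

#' Category levels observed in a training partition
#'
#' @param schema Feature schema.
#' @param data Training patient table.
#' @return Named list mapping each categorical feature to its observed
#'   levels, kept in schema declaration order.
#' @export
onehot_levels <- function(schema, data) {
  cats <- schema_names(schema, "categorical")
  out <- lapply(cats, function(f) {
    s <- schema_get(schema, f)
    s$categories[s$categories %in% unique(data[[f]])]
  })
  names(out) <- cats
  out
}

#' One-hot encode a patient table into a numeric design matrix
#'
#' Continuous features map to one numeric column, binary features to a single
#' 0/1 column, and each categorical feature to one indicator column per
#' training-seen category. A test-time category unseen in training yields an
#' all-zero indicator block (logged in the `"unseen"` attribute). The column
#' map records the parent feature of every design column, as needed when
#' merging attribution scores back to feature level.
#'
#' @param schema Feature schema.
#' @param data Patient table (imputed; continuous features must be complete).
#' @param levels Named list of training-seen category levels, from
#'   [onehot_levels()]. `NULL` derives them from `data` itself (training use).
#' @return A list with `matrix` (numeric design matrix), `column_map`
#'   (tibble of `column`, `parent`) and `levels`.
#' @export
encode_onehot <- function(schema, data, levels = NULL) {
  if (is.null(levels)) levels <- onehot_levels(schema, data)
  cols <- list()
  parents <- character(0)
  unseen <- character(0)
  for (s in schema) {
    if (s$kind == "continuous") {
      v <- data[[s$name]]
      if (anyNA(v)) stopf("continuous feature '%s' has missing values; impute first", s$name)
      cols[[s$name]] <- as.numeric(v)
      parents <- c(parents, s$name)
    } else if (s$kind == "binary") {
      v <- data[[s$name]]
      if (anyNA(v)) stopf("binary feature '%s' has missing values", s$name)
      cols[[s$name]] <- as.numeric(v)
      parents <- c(parents, s$name)
    } else {
      v <- as.character(data[[s$name]])
      if (anyNA(v)) stopf("categorical feature '%s' has missing values; exclude those patients", s$name)
      lv <- levels[[s$name]]
      nov <- setdiff(unique(v), lv)
      if (length(nov)) {
        unseen <- c(unseen, sprintf("%s=%s", s$name, nov))
      }
      for (cat in lv) {
        cn <- paste0(s$name, "=", cat)
        cols[[cn]] <- as.numeric(v == cat)
        parents <- c(parents, s$name)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- data$patient_id
  out <- list(matrix = X,
              column_map = tibble::tibble(column = colnames(X),
                                          parent = parents),
              levels = levels)
  if (length(unseen)) {
    message("unseen categories encoded as all-zero: ",
            paste(unseen, collapse = ", "))
    attr(out, "unseen") <- unseen
  }
  out
}

#' Worst value relative to a reference
#'
#' Returns the element of `values` furthest from `reference`; ties are broken
#' toward the larger value. An empty input returns `NA`.
#'
#' @param values Numeric vector of measurements (e.g. over the first 24 h).
#' @param reference Scalar reference value.
#' @return Scalar worst value.
#' @export
#' @examples
#' worst_value(c(60, 130), 75)  # 130
worst_value <- function(values, reference) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  d <- abs(values - reference)
  max(values[d == max(d)])
}
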