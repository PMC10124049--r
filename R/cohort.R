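#' Construct a cohort object
#'
#' A cohort bundles a patient table (one row per ICU stay) with the feature
#' schema that describes which columns are model features and how they were
#' generated. Auxiliary columns (`patient_id`, `outcome`,
#' `reference_probability`, `aps`, discharge offsets, `icu_los_hours`,
#' `n_unit_stays`, `true_subgroup`) travel alongside the features.
#'
#' @param data A data frame with one row per patient.
#' @param schema A list of [feature_spec()] objects; every feature column in
#'   `data` must be named in the schema.
#' @return An object of class `icu_cohort`.
#' @export
new_cohort <- function(data, schema) {
  data <- tibble::as_tibble(data)
  if (anyDuplicated(data$patient_id)) stopf("duplicate patient_id in cohort")
  feat <- schema_names(schema)
  missing_cols <- setdiff(feat, names(data))
  if (length(missing_cols)) {
    stopf("schema features absent from data: %s",
          paste(missing_cols, collapse = ", "))
  }
  structure(list(data = data, schema = schema), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("<icu_cohort> %d patients, %d features (%d continuous)\n",
              nrow(x$data), length(x$schema),
              length(schema_names(x$schema, "continuous"))))
  if ("outcome" %in% names(x$data)) {
    cat(sprintf("  dead fraction: %.3f\n", mean(x$data$outcome == "dead")))
  }
  invisible(x)
}

#' @export
dim.icu_cohort <- function(x) dim(x$data)

#' Extract the patient table of a cohort
#' @param cohort An `icu_cohort`.
#' @return A tibble.
#' @export
cohort_data <- function(cohort) cohort$data

#' Extract the feature schema of a cohort
#' @param cohort An `icu_cohort`.
#' @return A list of [feature_spec()] objects.
#' @export
cohort_schema <- function(cohort) cohort$schema

#' Configuration of the synthetic cohort generator
#'
#' The generator plants three latent subgroups: clearly-alive patients (low
#' severity), clearly-dead patients (high severity) and an ambiguous group
#' whose severity sits tightly at the population decision boundary. The
#' latent severity is Normal within each subgroup; a logistic link maps
#' severity to mortality risk and the link intercept is solved numerically so
#' the marginal death rate equals `prevalence`. The ambiguous subgroup's
#' event rate comes out slightly below the marginal prevalence, which anchors
#' the learners' Youden cuts on the Alive side of that cluster, while the
#' miscalibrated reference model (see `reference_miscalibration`) votes Dead
#' on it — the structural voter disagreement that makes those patients
#' genuinely unstable to classify. The methods vignette derives why this
#' two-anchor construction is needed.
#'
#' @param n_patients Number of patients to generate.
#' @param prevalence Marginal in-hospital death rate, default 0.105.
#' @param subgroup_mix Named fractions `(clear_alive, clear_dead, ambiguous)`
#'   summing to 1.
#' @param feature_specs Schema, default [default_feature_specs()].
#' @param reference_model_noise SD, on the log-odds scale, of the fixed
#'   reference probability around its (miscalibrated) risk estimate
#'   (APACHE-IV analogue).
#' @param reference_miscalibration Named vector `c(amplitude, width)` of a
#'   Gaussian over-prediction bump, on the log-odds scale, centred at the
#'   ambiguous subgroup's severity. Legacy severity scores transported to new
#'   cohorts characteristically over-predict mortality for
#'   intermediate-severity patients; the bump reproduces that, making the
#'   reference voter systematically more pessimistic than the learners
#'   exactly where the data are least informative. Set the amplitude to 0 for
#'   a perfectly calibrated reference.
#' @param informative_missingness Strength of the severity tilt on
#'   missingness; positive values give sicker patients fewer missing values.
#' @param severity_means,severity_sds Location and spread of the latent
#'   severity per subgroup, in the order clear_alive, clear_dead, ambiguous.
#' @param severity_slope Slope of the logistic outcome link on severity.
#' @param anthropometric_outlier_rate Fraction of records given artefactual
#'   heights/weights outside plausible human ranges.
#' @param seed Integer master seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             prevalence = 0.105,
                             subgroup_mix = c(clear_alive = 0.674,
                                              clear_dead = 0.106,
                                              ambiguous = 0.22),
                             feature_specs = default_feature_specs(),
                             reference_model_noise = 0.35,
                             reference_miscalibration = c(amplitude = 4.2,
                                                          width = 0.8),
                             informative_missingness = 0.6,
                             severity_means = c(clear_alive = -4,
                                                clear_dead = 3,
                                                ambiguous = 0),
                             severity_sds = c(clear_alive = 1,
                                              clear_dead = 1,
                                              ambiguous = 0.1),
                             severity_slope = 1.5,
                             anthropometric_outlier_rate = 0.004,
                             seed = 1L) {
  if (!is_scalar_number(n_patients) || n_patients < 1) {
    stopf("n_patients must be a positive integer")
  }
  if (!is_scalar_number(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stopf("prevalence must lie in (0, 1)")
  }
  if (length(subgroup_mix) != 3L || abs(sum(subgroup_mix) - 1) > 1e-9) {
    stopf("subgroup_mix must be 3 fractions summing to 1")
  }
  if (is.null(names(subgroup_mix))) {
    names(subgroup_mix) <- c("clear_alive", "clear_dead", "ambiguous")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), prevalence = prevalence,
      subgroup_mix = subgroup_mix, feature_specs = feature_specs,
      reference_model_noise = reference_model_noise,
      reference_miscalibration = reference_miscalibration,
      informative_missingness = informative_missingness,
      severity_means = severity_means, severity_sds = severity_sds,
      severity_slope = severity_slope,
      anthropometric_outlier_rate = anthropometric_outlier_rate,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Intercept of the logistic outcome link such that the marginal death rate
# over the subgroup mixture equals the configured prevalence.
solve_link_intercept <- function(config) {
  b <- config$severity_slope
  marginal <- function(a) {
    p <- 0
    for (k in seq_along(config$subgroup_mix)) {
      mu <- config$severity_means[[k]]
      s <- config$severity_sds[[k]]
      f <- stats::integrate(
        function(z) stats::plogis(a + b * z) * stats::dnorm(z, mu, s),
        lower = mu - 8 * s, upper = mu + 8 * s
      )$value
      p <- p + config$subgroup_mix[[k]] * f
    }
    p - config$prevalence
  }
  stats::uniroot(marginal, c(-30, 10), tol = 1e-10)$root
}

#' Draw worst-in-24h values from a severity-tilted two-mode mixture
#'
#' Models the "value furthest from a clinical reference" summary: draws come
#' from a two-component Gaussian mixture centred at `low_mode` and
#' `high_mode`. The weight on the mode further from the reference value is
#' `plogis(severity * severity_loading)`, so at zero loading the two peaks
#' are equally likely and sicker patients drift toward the extreme peak.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param spec A continuous [feature_spec()].
#' @param severity Numeric vector of latent severities (one draw each).
#' @return Numeric vector of draws, same length as `severity`.
#' @export
sample_worst_value <- function(spec, severity) {
  if (spec$kind != "continuous") {
    stopf("sample_worst_value requires a continuous feature, got '%s' (%s)",
          spec$name, spec$kind)
  }
  n <- length(severity)
  d_low <- abs(spec$low_mode - spec$reference_value)
  d_high <- abs(spec$high_mode - spec$reference_value)
  # the extreme mode is the one further from the reference; ties go high
  extreme <- if (d_high >= d_low) spec$high_mode else spec$low_mode
  other <- if (d_high >= d_low) spec$low_mode else spec$high_mode
  w_extreme <- stats::plogis(severity * spec$severity_loading)
  pick <- stats::rbinom(n, 1L, w_extreme) == 1L
  centre <- ifelse(pick, extreme, other)
  stats::rnorm(n, mean = centre, sd = spec$sd)
}

# severity-tilted categorical draw: log-weights increase linearly with the
# category index scaled by severity * loading
sample_categorical <- function(spec, severity) {
  k <- length(spec$categories)
  pos <- seq_len(k) - (k + 1) / 2      # centred category index
  out <- character(length(severity))
  logw <- outer(severity * spec$severity_loading, pos / max(pos, 1))
  p <- exp(logw)
  p <- p / rowSums(p)
  for (i in seq_along(severity)) {
    out[i] <- sample(spec$categories, 1L, prob = p[i, ])
  }
  out
}

#' Generate a synthetic ICU cohort
#'
#' Produces `n_patients` records with latent severity drawn per planted
#' subgroup, outcome drawn Bernoulli on the logistic risk, a fixed
#' reference-model probability (true risk plus noise, clipped to `[0, 1]`),
#' an acute physiology score increasing with severity, discharge offsets with
#' `hospital >= unit`, and the feature table described by the schema.
#' Severity-dependent informative missingness is applied last, so sicker
#' patients carry fewer missing values. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An `icu_cohort`. The generating config is attached as attribute
#'   `"config"`; the patient table keeps the latent `true_subgroup` label for
#'   recovery checks (synthetic data only).
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(500, seed = 42))
#' mean(cohort_data(coh)$outcome == "dead")
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    stopf("config must be a generator_config")
  }
  n <- config$n_patients
  with_seed(config$seed, {
    groups <- names(config$subgroup_mix)
    subgroup <- sample(groups, n, replace = TRUE, prob = config$subgroup_mix)
    sev <- stats::rnorm(n,
                        mean = config$severity_means[subgroup],
                        sd = config$severity_sds[subgroup])
    a <- solve_link_intercept(config)
    link <- a + config$severity_slope * sev
    risk <- stats::plogis(link)
    outcome <- ifelse(stats::rbinom(n, 1L, risk) == 1L, "dead", "alive")
    # reference model: true risk plus an intermediate-severity over-prediction
    # bump and patient-level noise, both on the log-odds scale
    mc <- config$reference_miscalibration
    bump <- mc[["amplitude"]] * exp(-(sev - config$severity_means[["ambiguous"]])^2 /
                                      (2 * mc[["width"]]^2))
    ref_prob <- stats::plogis(link + bump +
                                stats::rnorm(n, 0, config$reference_model_noise))

    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.46, 0.54))

    dat <- tibble::tibble(
      patient_id = sprintf("pt%06d", seq_len(n)),
      outcome = outcome,
      reference_probability = ref_prob,
      true_subgroup = subgroup
    )

    for (spec in config$feature_specs) {
      val <- switch(
        spec$name,
        age = round(pmin(95, pmax(16, stats::rnorm(
          n, spec$reference_value + spec$severity_loading * spec$sd * sev,
          spec$sd)))),
        sex = sex,
        admissionheight = {
          h <- stats::rnorm(n, ifelse(sex == "M", 177, 164), 8)
          out_h <- stats::runif(n) < config$anthropometric_outlier_rate
          h[out_h] <- sample(c(stats::runif(sum(out_h), 2, 95),
                               stats::runif(sum(out_h), 255, 400)),
                             sum(out_h))
          h
        },
        admissionweight = {
          w <- pmax(35, stats::rnorm(n, ifelse(sex == "M", 86, 73), 15))
          out_w <- stats::runif(n) < config$anthropometric_outlier_rate
          w[out_w] <- sample(c(stats::runif(sum(out_w), 2, 28),
                               stats::runif(sum(out_w), 305, 700)),
                             sum(out_w))
          w
        },
        switch(spec$kind,
               continuous = sample_worst_value(spec, sev),
               binary = stats::rbinom(
                 n, 1L,
                 stats::plogis(stats::qlogis(spec$base_rate) +
                                 spec$severity_loading * sev)),
               categorical = sample_categorical(spec, sev))
      )
      dat[[spec$name]] <- val
    }

    # physiology floors for clinical plausibility
    for (nm in c("heartrate", "respiratoryrate", "bun", "creatinine", "wbc",
                 "albumin", "glucose", "meanbp")) {
      if (nm %in% names(dat)) dat[[nm]] <- pmax(dat[[nm]], 0.1)
    }
    if ("fio2" %in% names(dat)) dat$fio2 <- pmin(1, pmax(0.21, dat$fio2))
    if ("gcs_eyes" %in% names(dat)) dat$gcs_eyes <- pmin(4, pmax(1, dat$gcs_eyes))
    if ("gcs_motor" %in% names(dat)) dat$gcs_motor <- pmin(6, pmax(1, dat$gcs_motor))
    if ("gcs_verbal" %in% names(dat)) dat$gcs_verbal <- pmin(5, pmax(1, dat$gcs_verbal))

    # log-linear severity map keeps APS positive and right-skewed (range
    # roughly 2-200, median near 20), like real acute physiology scores
    dat$aps <- exp(3 + 0.55 * sev + stats::rnorm(n, 0, 0.25))
    dat$icu_los_hours <- pmax(2, stats::rlnorm(n, log(48) + 0.15 * sev, 0.6))
    dat$unit_discharge_offset <- dat$icu_los_hours * 60
    same <- stats::runif(n) < stats::plogis(-1.9 + 0.9 * sev)
    extra <- ifelse(same, 0, stats::rexp(n, rate = 1 / 4000))
    dat$hospital_discharge_offset <- dat$unit_discharge_offset + extra
    dat$n_unit_stays <- 1L + stats::rbinom(n, 1L, 0.05)

    cohort <- new_cohort(dat, config$feature_specs)
    cohort <- inject_missingness(cohort, config$informative_missingness,
                                 severity = sev)
    attr(cohort, "config") <- config
    cohort
  })
}

#' Apply (informative) missingness to a cohort
#'
#' Sets each feature value to missing with its schema `missing_rate`, tilted
#' on the log-odds scale by `-informative_strength * severity` so that sicker
#' patients have fewer missing values (they get tested more). Returns a new
#' cohort; the input is untouched. Uses the current RNG state unless `seed`
#' is given.
#'
#' @param cohort An `icu_cohort` with fully observed features.
#' @param informative_strength Non-negative tilt strength; 0 gives
#'   missing-completely-at-random at the schema rates.
#' @param severity Optional latent severity vector; defaults to a scaled,
#'   centred APS so the function also works on cohorts without the latent.
#' @param seed Optional seed.
#' @return A new `icu_cohort` with `NA` cells.
#' @export
inject_missingness <- function(cohort, informative_strength = 0,
                               severity = NULL, seed = NULL) {
  run <- function() {
    dat <- cohort$data
    n <- nrow(dat)
    if (is.null(severity)) {
      severity <- as.numeric(scale(dat$aps %||% rep(0, n)))
      severity[is.na(severity)] <- 0
    }
    # centre the tilt so the marginal rate stays at the schema missing_rate
    severity <- severity - mean(severity)
    for (spec in cohort$schema) {
      r <- spec$missing_rate
      if (r <= 0) next
      p <- if (r >= 1) rep(1, n) else {
        stats::plogis(stats::qlogis(r) - informative_strength * severity)
      }
      drop <- stats::runif(n) < p
      dat[[spec$name]][drop] <- NA
    }
    new_cohort(dat, cohort$schema)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
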