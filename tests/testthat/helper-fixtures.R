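# Shared fixture builders. Everything is generated in code; no data files.

# Minimal hand-built cohort for preprocessing tests: one continuous, one
# categorical and one binary feature plus the auxiliary columns.
toy_schema <- function() {
  list(
    feature_spec("f1", "continuous", reference_value = 0,
                 low_mode = -1, high_mode = 1, missing_rate = 0.2),
    feature_spec("color", "categorical", categories = c("A", "B", "C")),
    feature_spec("flag", "binary", base_rate = 0.5)
  )
}

toy_cohort <- function(n = 8,
                       age = rep(50, n),
                       icu_los_hours = rep(48, n),
                       n_unit_stays = rep(1L, n),
                       f1 = seq_len(n),
                       color = rep("A", n),
                       flag = rep(0L, n),
                       sex = rep(c("F", "M"), length.out = n),
                       height = rep(165, n),
                       weight = rep(70, n),
                       outcome = rep(c("alive", "dead"), length.out = n)) {
  new_cohort(
    tibble::tibble(
      patient_id = sprintf("p%03d", seq_len(n)),
      outcome = outcome,
      reference_probability = ifelse(outcome == "dead", 0.8, 0.1),
      f1 = f1, color = color, flag = flag,
      age = age, sex = sex,
      admissionheight = height, admissionweight = weight,
      aps = ifelse(outcome == "dead", 80, 20),
      icu_los_hours = icu_los_hours,
      unit_discharge_offset = icu_los_hours * 60,
      hospital_discharge_offset = icu_los_hours * 60 + 100,
      n_unit_stays = n_unit_stays,
      true_subgroup = "ambiguous"
    ),
    toy_schema()
  )
}

# Tiny-grid model bank used by the fast end-to-end fixtures: one
# configuration per family, 3-fold CV, 40 boosting stumps.
fixture_model_specs <- function() {
  ms <- default_model_specs("tiny")
  for (s in names(ms)) ms[[s]]$cv_folds <- 3L
  ms$adaptive_boosting$grid$n_trees <- 40
  ms
}

# Selected, anthropometric-imputed synthetic cohort of about 5000 patients.
fixture_cohort <- function(seed = 1, n_raw = 8250) {
  coh <- generate_cohort(generator_config(n_raw, seed = seed))
  impute_anthropometrics(select_patients(coh)$cohort)
}

# Independent brute-force oracle for vote fusion, deliberately naive.
fuse_oracle <- function(va, vd, outcome, threshold) {
  n <- length(va)
  final <- character(n)
  group <- character(n)
  for (i in seq_len(n)) {
    x <- 100 * va[i] / (va[i] + vd[i])
    y <- 100 * vd[i] / (va[i] + vd[i])
    if (x >= threshold) {
      final[i] <- "Alive"
      group[i] <- if (outcome[i] == "alive") "TN" else "FN"
    } else if (y >= threshold) {
      final[i] <- "Dead"
      group[i] <- if (outcome[i] == "dead") "TP" else "FP"
    } else {
      final[i] <- "MIXED"
      group[i] <- "MIXED"
    }
  }
  list(final = final, group = group)
}

# O(n^2) pair-counting oracle for the AUROC (ties count one half).
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive-search oracle for the Youden threshold; kept in integer
# arithmetic (J scaled by n1*n0) so exact ties resolve unambiguously.
youden_oracle <- function(scores, labels) {
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(cand, function(t) {
    sum(scores[labels == 1] >= t) * n0 - sum(scores[labels == 0] >= t) * n1
  }, 0)
  cand[which(j == max(j))[1]]
}

# order-insensitive comparison helper for record tibbles
sort_records <- function(x) x[order(x$group, x$feature), ]
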