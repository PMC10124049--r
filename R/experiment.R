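#' Configuration of the repeated-resampling experiment
#'
#' @param n_rounds Number of split/train/predict rounds (default 100).
#' @param test_fraction Test share per round (default 0.25).
#' @param model_specs Named list of [model_spec()] voters; default: the three
#'   learner families plus the fixed reference. An empty list runs the split
#'   schedule only (appearance counting without votes).
#' @param base_seed Integer; round `r` uses seed `base_seed + r`, so rounds
#'   are mutually independent and the whole experiment is reproducible.
#' @param agreement_threshold Percent in `(50, 100]` a class must reach for a
#'   non-MIXED fused prediction (default 90).
#' @param threshold_source `"train"` (default) derives each model's Youden
#'   threshold from its training-partition predictions; `"test"` from the
#'   test partition (no leakage into fitting either way, but `"test"` lets
#'   the threshold see test labels).
#' @param keep_attributions Accumulate per-prediction feature attributions
#'   for the learner families (needed for importance tables).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_rounds = 100L,
                              test_fraction = 0.25,
                              model_specs = default_model_specs(),
                              base_seed = 1L,
                              agreement_threshold = 90,
                              threshold_source = c("train", "test"),
                              keep_attributions = TRUE) {
  if (n_rounds < 1) stopf("n_rounds must be at least 1")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie in (0, 1)")
  }
  if (agreement_threshold <= 50 || agreement_threshold > 100) {
    stopf("agreement_threshold must lie in (50, 100]")
  }
  structure(list(n_rounds = as.integer(n_rounds),
                 test_fraction = test_fraction,
                 model_specs = model_specs,
                 base_seed = as.integer(base_seed),
                 agreement_threshold = agreement_threshold,
                 threshold_source = match.arg(threshold_source),
                 keep_attributions = isTRUE(keep_attributions)),
            class = "experiment_config")
}

#' Run the repeated split / train / vote experiment
#'
#' For each round: stratified split (seed `base_seed + round`), mean imputer
#' fitted on the training partition only, one-hot encoding with
#' training-seen categories, grid-search fitting of every voter, Youden
#' thresholding, binarization of the test-set predictions, and accumulation
#' of the Alive/Dead votes into the per-patient ledger. Round-level AUROC,
#' AUPRC and Brier scores are recorded per voter. Rounds are independent: no
#' state flows between them except the vote tally.
#'
#' @param cohort An `icu_cohort` that already passed [select_patients()] and
#'   [impute_anthropometrics()].
#' @param config An [experiment_config()].
#' @return An object of class `icu_experiment`: a list with
#'   \describe{
#'     \item{rounds}{tibble of per-round, per-voter thresholds, chosen
#'       hyperparameters and test metrics}
#'     \item{ledger}{tibble of per-patient `n_appearances`, `votes_alive`,
#'       `votes_dead`, `outcome`}
#'     \item{attributions}{per-family list of normalized, category-merged
#'       attribution rows with their patient ids and rounds}
#'     \item{unassessed}{ids of patients never drawn into any test set}
#'   }
#' @export
run_experiment <- function(cohort, config = experiment_config()) {
  dat <- cohort$data
  n <- nrow(dat)
  pid <- dat$patient_id
  appearances <- integer(n)
  votes_alive <- integer(n)
  votes_dead <- integer(n)
  names(appearances) <- names(votes_alive) <- names(votes_dead) <- pid

  specs <- config$model_specs
  rounds <- list()
  attr_rows <- list()
  attr_pid <- list()
  attr_round <- list()
  for (fam in names(specs)) {
    attr_rows[[fam]] <- list()
    attr_pid[[fam]] <- list()
    attr_round[[fam]] <- list()
  }

  for (r in seq_len(config$n_rounds)) {
    seed_r <- config$base_seed + r
    sp <- stratified_split(cohort, config$test_fraction, seed = seed_r)
    te_ids <- sp$test$data$patient_id
    appearances[te_ids] <- appearances[te_ids] + 1L

    if (!length(specs)) next  # split-only schedule

    imp <- fit_imputer(sp$train)
    train <- apply_imputer(imp, sp$train)
    test <- apply_imputer(imp, sp$test)
    lv <- onehot_levels(cohort$schema, train$data)
    enc_tr <- encode_onehot(cohort$schema, train$data, levels = lv)
    enc_te <- encode_onehot(cohort$schema, test$data, levels = lv)
    y_tr <- as.integer(train$data$outcome == "dead")
    y_te <- as.integer(test$data$outcome == "dead")

    for (fam in names(specs)) {
      fitted <- tryCatch(
        fit_with_gridsearch(specs[[fam]], enc_tr$matrix, y_tr, seed = seed_r),
        error = function(e) stopf("round %d, model %s failed: %s",
                                  r, fam, conditionMessage(e)))
      s_tr <- predict_scores(fitted, enc_tr$matrix,
                             reference = train$data$reference_probability)
      s_te <- predict_scores(fitted, enc_te$matrix,
                             reference = test$data$reference_probability)
      thr <- if (config$threshold_source == "train") {
        youden_threshold(s_tr, y_tr)
      } else {
        youden_threshold(s_te, y_te)
      }
      vote <- binarize(s_te, thr)
      is_dead_vote <- vote == "Dead"
      votes_dead[te_ids[is_dead_vote]] <- votes_dead[te_ids[is_dead_vote]] + 1L
      votes_alive[te_ids[!is_dead_vote]] <- votes_alive[te_ids[!is_dead_vote]] + 1L

      rounds[[length(rounds) + 1L]] <- tibble::tibble(
        round = r, family = fam,
        params = list(fitted$params),
        threshold = thr,
        auroc = auroc(s_te, y_te),
        auprc = auprc(s_te, y_te),
        brier = brier(s_te, y_te)
      )

      if (config$keep_attributions && fam != "reference") {
        A <- attribute(fitted, enc_te$matrix)
        A_norm <- normalize_per_prediction(A$contributions)
        A_par <- merge_onehot(A_norm, enc_te$column_map)
        k <- length(attr_rows[[fam]]) + 1L
        attr_rows[[fam]][[k]] <- A_par
        attr_pid[[fam]][[k]] <- te_ids
        attr_round[[fam]][[k]] <- rep(r, length(te_ids))
      }
    }
  }

  attributions <- NULL
  if (config$keep_attributions && length(specs)) {
    attributions <- list()
    for (fam in setdiff(names(specs), "reference")) {
      if (!length(attr_rows[[fam]])) next
      attributions[[fam]] <- list(
        matrix = do.call(rbind, attr_rows[[fam]]),
        patient_id = unlist(attr_pid[[fam]], use.names = FALSE),
        round = unlist(attr_round[[fam]], use.names = FALSE)
      )
    }
  }

  structure(list(
    rounds = if (length(rounds)) do.call(rbind, rounds) else tibble::tibble(),
    ledger = tibble::tibble(
      patient_id = pid,
      n_appearances = unname(appearances),
      votes_alive = unname(votes_alive),
      votes_dead = unname(votes_dead),
      outcome = dat$outcome
    ),
    attributions = attributions,
    unassessed = pid[appearances == 0L],
    config = config
  ), class = "icu_experiment")
}

#' @export
print.icu_experiment <- function(x, ...) {
  cat(sprintf("<icu_experiment> %d rounds, %d voters, %d patients (%d unassessed)\n",
              x$config$n_rounds, length(x$config$model_specs),
              nrow(x$ledger), length(x$unassessed)))
  invisible(x)
}
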