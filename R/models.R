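#' Specify a model family and its hyperparameter grid
#'
#' Four voter families are supported: ridge-penalized logistic regression
#' (`glmnet`), gradient-boosted trees (`xgboost`), adaptive boosting of
#' decision stumps (in-package SAMME), and the fixed `reference` probability
#' column, which is consumed as-is (an APACHE-IV analogue) and has no
#' hyperparameters.
#'
#' @param family One of `"logistic_regression"`, `"gradient_boosted_trees"`,
#'   `"adaptive_boosting"`, `"reference"`.
#' @param grid Named list of candidate hyperparameter values; the grid is the
#'   cross product. Must be empty for the reference family.
#' @param cv_folds Stratified cross-validation folds for grid search.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("logistic_regression",
                                  "gradient_boosted_trees",
                                  "adaptive_boosting", "reference"),
                       grid = list(), cv_folds = 5L) {
  family <- match.arg(family)
  if (family == "reference" && length(grid)) {
    stopf("the reference family takes no hyperparameter grid")
  }
  if (cv_folds < 2) stopf("cv_folds must be at least 2")
  structure(list(family = family, grid = grid,
                 cv_folds = as.integer(cv_folds)),
            class = "model_spec")
}

#' Default model bank
#'
#' The three learner families plus the fixed reference model. `"default"`
#' grids are small exhaustive grids (tree depth, learning rate, L2 strength);
#' `"tiny"` grids hold a single configuration per family, for fast fixtures.
#'
#' @param grid `"default"` or `"tiny"`.
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function(grid = c("default", "tiny")) {
  grid <- match.arg(grid)
  if (grid == "default") {
    list(
      logistic_regression = model_spec("logistic_regression",
                                       grid = list(lambda = c(0.01, 0.1, 1))),
      gradient_boosted_trees = model_spec(
        "gradient_boosted_trees",
        grid = list(max_depth = c(2, 3, 4), eta = c(0.1, 0.3), nrounds = 60)),
      adaptive_boosting = model_spec("adaptive_boosting",
                                     grid = list(n_trees = c(40, 80))),
      reference = model_spec("reference")
    )
  } else {
    list(
      logistic_regression = model_spec("logistic_regression",
                                       grid = list(lambda = 0.1)),
      gradient_boosted_trees = model_spec(
        "gradient_boosted_trees",
        grid = list(max_depth = 3, eta = 0.3, nrounds = 40)),
      adaptive_boosting = model_spec("adaptive_boosting",
                                     grid = list(n_trees = 50)),
      reference = model_spec("reference")
    )
  }
}

#' Stratified train/test split
#'
#' Partitions a cohort into disjoint, exhaustive train and test sets, drawing
#' the test fraction within each outcome class separately so both partitions
#' match the cohort's death rate to within one patient. Deterministic given
#' `seed`.
#'
#' @param cohort An `icu_cohort` with both outcomes present.
#' @param test_fraction Fraction assigned to the test set (default 0.25).
#' @param seed Integer seed.
#' @return List with `train` and `test` cohorts.
#' @export
stratified_split <- function(cohort, test_fraction = 0.25, seed = 1L) {
  dat <- cohort$data
  classes <- split(seq_len(nrow(dat)), dat$outcome)
  if (length(classes) < 2 || any(lengths(classes) < 2)) {
    stopf("each outcome class needs at least 2 patients to split")
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(classes, function(idx) {
      sample(idx, round(length(idx) * test_fraction))
    }), use.names = FALSE)
  })
  list(
    train = new_cohort(dat[-test_idx, , drop = FALSE], cohort$schema),
    test = new_cohort(dat[test_idx, , drop = FALSE], cohort$schema)
  )
}

# ---- family backends --------------------------------------------------------

fit_family <- function(family, params, X, y, seed) {
  switch(
    family,
    logistic_regression = {
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = params$lambda)
      list(fit = fit, train_means = colMeans(X))
    },
    gradient_boosted_trees = {
      set.seed(seed)
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = dm, nrounds = params$nrounds, verbose = 0)
    },
    adaptive_boosting = fit_adaboost(X, y, n_trees = params$n_trees),
    stopf("unknown family '%s'", family)
  )
}

predict_family <- function(family, model, X) {
  switch(
    family,
    logistic_regression =
      as.numeric(stats::predict(model$fit, X, type = "response")),
    gradient_boosted_trees = as.numeric(stats::predict(model, X)),
    adaptive_boosting = predict_adaboost(model, X),
    stopf("unknown family '%s'", family)
  )
}

# SAMME adaptive boosting of depth-1 rpart stumps. The score is the
# alpha-weighted fraction of stumps voting "dead", which lies in [0, 1].
# Each stump depends on at most one feature, so additive attributions are
# exact (see attribute()).
fit_adaboost <- function(X, y, n_trees) {
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  yf <- factor(y, levels = c(0, 1))
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- vector("list", n_trees)
  alphas <- numeric(n_trees)
  train_mean_h <- numeric(n_trees)
  used <- 0L
  for (t in seq_len(n_trees)) {
    fit <- rpart::rpart(
      yf ~ ., data = df, weights = w * n, method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 20,
                                     xval = 0, maxcompete = 0,
                                     maxsurrogate = 0))
    h <- as.integer(stats::predict(fit, df, type = "class") == "1")
    err <- sum(w * (h != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break  # weak-learner condition violated; stop growing
    alpha <- log((1 - err) / err)
    used <- used + 1L
    trees[[used]] <- fit
    alphas[used] <- alpha
    train_mean_h[used] <- mean(h)
    w <- w * exp(alpha * (h != y))
    w <- w / sum(w)
  }
  if (used == 0L) {
    # degenerate: fall back to the base rate as a constant score
    return(structure(list(trees = list(), alphas = numeric(0),
                          train_mean_h = numeric(0), base_rate = mean(y),
                          feature_names = colnames(X)),
                     class = "ada_boost"))
  }
  structure(list(trees = trees[seq_len(used)],
                 alphas = alphas[seq_len(used)],
                 train_mean_h = train_mean_h[seq_len(used)],
                 base_rate = mean(y),
                 feature_names = colnames(X)),
            class = "ada_boost")
}

# per-stump 0/1 votes for new data, one column per stump
adaboost_votes <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- make.names(model$feature_names)
  vapply(model$trees,
         function(tr) as.integer(stats::predict(tr, df, type = "class") == "1"),
         integer(nrow(X)))
}

predict_adaboost <- function(model, X) {
  if (!length(model$trees)) return(rep(model$base_rate, nrow(X)))
  votes <- adaboost_votes(model, X)
  wts <- model$alphas / sum(model$alphas)
  as.numeric(votes %*% wts)
}

# the feature each stump splits on (NA for constant stumps)
adaboost_stump_features <- function(model) {
  safe <- make.names(model$feature_names)
  vapply(model$trees, function(tr) {
    v <- as.character(tr$frame$var[1])
    if (v == "<leaf>") NA_character_ else model$feature_names[match(v, safe)]
  }, "")
}

# ---- grid search ------------------------------------------------------------

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Fit one model family with exhaustive grid search
#'
#' Every grid configuration is scored by stratified cross-validated AUROC on
#' the training partition; the best mean-AUROC configuration is refitted on
#' the full partition. Ties resolve to the earliest grid entry in declaration
#' order. The reference family returns a pass-through of the stored
#' probability column and skips fitting entirely.
#'
#' @param spec A [model_spec()].
#' @param X Numeric design matrix of the training partition.
#' @param y 0/1 training labels (1 = dead); both classes required.
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return An object of class `icu_model` with the chosen hyperparameters,
#'   the fitted backend and the grid's CV AUROC table.
#' @export
fit_with_gridsearch <- function(spec, X, y, seed = 1L) {
  if (spec$family == "reference") {
    return(structure(list(family = "reference", params = list(),
                          model = NULL, cv = NULL),
                     class = "icu_model"))
  }
  y <- check_labels(rep(0, length(y)), y, need_both = TRUE)
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (!nrow(grid)) stopf("empty hyperparameter grid for %s", spec$family)
  fold <- stratified_folds(y, spec$cv_folds, seed)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold != f
      m <- fit_family(spec$family, params, X[tr, , drop = FALSE], y[tr],
                      seed = seed + f)
      auroc(predict_family(spec$family, m, X[!tr, , drop = FALSE]), y[!tr])
    }, 0)
    cv_auc[g] <- mean(aucs)
  }
  best <- which.max(cv_auc)  # first maximum = declaration order
  params <- as.list(grid[best, , drop = FALSE])
  model <- fit_family(spec$family, params, X, y, seed = seed)
  structure(list(family = spec$family, params = params, model = model,
                 cv = cbind(grid, cv_auroc = cv_auc)),
            class = "icu_model")
}

#' Predict mortality probabilities from a fitted voter
#'
#' @param fitted An `icu_model` from [fit_with_gridsearch()].
#' @param X Design matrix with the training columns.
#' @param reference Stored reference probabilities, required for (and only
#'   used by) the reference family.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_scores <- function(fitted, X, reference = NULL) {
  if (fitted$family == "reference") {
    if (is.null(reference)) {
      stopf("the reference family needs the stored probability column")
    }
    return(as.numeric(reference))
  }
  predict_family(fitted$family, fitted$model, X)
}

#' @export
print.icu_model <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<icu_model> %s (%s)\n", x$family, ps))
  invisible(x)
}
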