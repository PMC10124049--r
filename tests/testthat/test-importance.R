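test_that("per-prediction normalization uses absolute values and sums to 1", {
  m <- rbind(c(2, -2), c(1, 0))
  out <- normalize_per_prediction(cbind(m, 0)[, 1:2])
  expect_equal(out[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(out[2, ], c(1, 0), ignore_attr = TRUE)
  withr::with_seed(1, {
    r <- matrix(rnorm(60), 10, 6)
    expect_equal(rowSums(normalize_per_prediction(r)), rep(1, 10))
  })
})

test_that("all-zero rows normalize to the uniform split and are flagged", {
  m <- rbind(c(0, 0, 0), c(3, 1, 0))
  out <- normalize_per_prediction(m)
  expect_equal(out[1, ], rep(1 / 3, 3), ignore_attr = TRUE)
  expect_equal(attr(out, "flagged"), 1)
})

test_that("aggregation is patient-first, never a pooled row mean", {
  m <- rbind(c(1, 0), c(0, 1), c(1, 0))
  colnames(m) <- c("f1", "f2")
  rec <- aggregate_importance(m, c("A", "A", "B"), model_family = "lr")
  all_rec <- rec[rec$group == "ALL", ]
  # patient A mean (0.5, 0.5); patient B (1, 0); two-stage mean (0.75, 0.25)
  expect_equal(all_rec$mean_normalized_importance[all_rec$feature == "f1"],
               0.75)
  expect_equal(all_rec$mean_normalized_importance[all_rec$feature == "f2"],
               0.25)
})

test_that("aggregation is invariant to row order and emits per-group records", {
  withr::with_seed(2, {
    m <- matrix(runif(40), 10, 4)
    m <- m / rowSums(m)
    colnames(m) <- paste0("f", 1:4)
    pid <- sample(c("a", "b", "c"), 10, replace = TRUE)
    grouping <- c(a = "TN", b = "TP", c = "TN")
    r1 <- aggregate_importance(m, pid, grouping, "xgb")
    perm <- sample(10)
    r2 <- aggregate_importance(m[perm, ], pid[perm], grouping, "xgb")
    expect_equal(sort_records(r1), sort_records(r2))
    sums <- tapply(r1$mean_normalized_importance,
                   paste(r1$model_family, r1$group), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  })
})

test_that("one-hot importances merge into parents and conserve totals", {
  m <- rbind(c(0.02, 0.01, 0.01, 0.96), c(0.1, 0.2, 0.3, 0.4))
  colnames(m) <- c("adx=a", "adx=b", "adx=c", "age")
  cmap <- tibble::tibble(column = colnames(m),
                         parent = c("adx", "adx", "adx", "age"))
  out <- merge_onehot(m, cmap)
  expect_equal(out[1, "adx"], 0.04, ignore_attr = TRUE)
  expect_equal(rowSums(out), rowSums(m))
  # no categoricals: identity up to column order
  m2 <- m[, "age", drop = FALSE]
  out2 <- merge_onehot(m2, cmap[4, ])
  expect_equal(out2, m2)
  expect_error(merge_onehot(m, cmap[1:3, ]), "parent")
})

test_that("rank table orders by importance with alphabetical tie-break", {
  rec <- tibble::tibble(model_family = "lr", group = "ALL",
                        feature = c("a", "b", "c"),
                        mean_normalized_importance = c(0.5, 0.3, 0.2))
  rt <- rank_table(rec, top_k = 2)
  expect_equal(rt$feature, c("a", "b"))
  expect_equal(rt$cumulative[2], 0.8)
  tied <- tibble::tibble(model_family = "lr", group = "ALL",
                         feature = c("zeta", "alpha", "mid"),
                         mean_normalized_importance = rep(1 / 3, 3))
  expect_equal(rank_table(tied)$feature, c("alpha", "mid", "zeta"))
  expect_equal(max(rank_table(tied)$cumulative), 1)
  # top_k beyond the feature count returns the full table
  expect_equal(nrow(rank_table(rec, top_k = 99)), 3)
})

test_that("linear attributions are exact and additive on the link scale", {
  pd <- withr::with_seed(3, {
    X <- cbind(x1 = rnorm(300), x2 = rnorm(300))
    y <- rbinom(300, 1, plogis(1.5 * X[, 1] - X[, 2]))
    y[1:2] <- c(0, 1)
    list(X = X, y = y)
  })
  fit <- fit_with_gridsearch(
    model_spec("logistic_regression", grid = list(lambda = 0.01),
               cv_folds = 3), pd$X, pd$y, seed = 1)
  at <- attribute(fit, pd$X)
  # additivity: base + row sum reproduces the model's log-odds output
  link <- qlogis(predict_scores(fit, pd$X))
  expect_equal(at$base + rowSums(at$contributions), link, tolerance = 1e-6)
  # closed form: contribution_j / (x_j - mean_j) is the coefficient
  beta <- as.numeric(coef(fit$model$fit))[-1]
  ratio <- at$contributions[, 1] / (pd$X[, 1] - mean(pd$X[, 1]))
  expect_equal(unname(ratio), rep(beta[1], 300), tolerance = 1e-8)
})

test_that("a constant model attributes nothing", {
  pd <- withr::with_seed(4, {
    X <- cbind(x1 = rnorm(100), x2 = rnorm(100))
    list(X = X, y = c(0, 1, rbinom(98, 1, 0.3)))
  })
  # an essentially infinite ridge penalty shrinks every coefficient to zero
  fit <- fit_with_gridsearch(
    model_spec("logistic_regression", grid = list(lambda = 1e9),
               cv_folds = 3), pd$X, pd$y, seed = 1)
  at <- attribute(fit, pd$X)
  expect_true(all(abs(at$contributions) < 1e-6))
})

test_that("tree and boosting attributions satisfy the additivity contract", {
  pd <- withr::with_seed(5, {
    X <- cbind(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
    y <- rbinom(300, 1, plogis(-1 + 2 * X[, 1]))
    y[1:2] <- c(0, 1)
    list(X = X, y = y)
  })
  xgb <- fit_with_gridsearch(
    model_spec("gradient_boosted_trees",
               grid = list(max_depth = 3, eta = 0.3, nrounds = 20),
               cv_folds = 3), pd$X, pd$y, seed = 2)
  at <- attribute(xgb, pd$X)
  expect_equal(plogis(at$base + rowSums(at$contributions)),
               predict_scores(xgb, pd$X), tolerance = 1e-5)

  ada <- fit_with_gridsearch(
    model_spec("adaptive_boosting", grid = list(n_trees = 15), cv_folds = 3),
    pd$X, pd$y, seed = 3)
  at2 <- attribute(ada, pd$X)
  expect_equal(at2$base + rowSums(at2$contributions),
               predict_scores(ada, pd$X), tolerance = 1e-10)
  # stumps split on the planted feature, so attributions concentrate there
  share <- colSums(abs(at2$contributions))
  expect_equal(names(which.max(share)), "x1")
})

test_that("the reference voter cannot be attributed", {
  fit <- fit_with_gridsearch(model_spec("reference"), matrix(0, 3, 1),
                             c(0, 1, 0))
  expect_error(attribute(fit, matrix(0, 3, 1)), "reference")
})
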