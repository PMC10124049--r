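#' Per-prediction additive feature attributions
#'
#' Computes Shapley-style additive contributions for each prediction: the
#' base value plus the row sum of contributions reproduces the model output
#' for that row (on the family's native output scale). Backends:
#' \describe{
#'   \item{gradient_boosted_trees}{xgboost's exact tree-path attributions
#'     (TreeSHAP), on the log-odds margin scale.}
#'   \item{logistic_regression}{closed-form linear attribution
#'     `beta_j * (x_j - mean_j)` on the link scale, with the training means
#'     recorded at fit time.}
#'   \item{adaptive_boosting}{each depth-1 stump depends on one feature, so
#'     its weighted vote minus its training mean vote is an exact additive
#'     contribution to that feature, on the probability scale.}
#' }
#' The reference voter has no features and cannot be attributed.
#'
#' @param fitted An `icu_model` from [fit_with_gridsearch()].
#' @param X Design matrix with the training columns.
#' @return List with `contributions` (rows = predictions, columns = design
#'   columns) and `base` (scalar expected output).
#' @export
attribute <- function(fitted, X) {
  fam <- fitted$family
  if (fam == "reference") {
    stopf("the reference voter has no features to attribute")
  }
  if (fam == "logistic_regression") {
    beta <- as.numeric(stats::coef(fitted$model$fit))
    intercept <- beta[1]
    beta <- beta[-1]
    if (length(beta) != ncol(X)) stopf("design matrix columns do not match the fitted model")
    mu <- fitted$model$train_means
    contrib <- sweep(X, 2, mu) * rep(beta, each = nrow(X))
    colnames(contrib) <- colnames(X)
    return(list(contributions = contrib,
                base = intercept + sum(beta * mu)))
  }
  if (fam == "gradient_boosted_trees") {
    ct <- stats::predict(fitted$model, X, predcontrib = TRUE)
    bias_col <- ncol(ct)  # xgboost appends the bias as the last column
    base <- ct[1, bias_col]
    contrib <- ct[, -bias_col, drop = FALSE]
    colnames(contrib) <- colnames(X)
    return(list(contributions = contrib, base = base))
  }
  if (fam == "adaptive_boosting") {
    m <- fitted$model
    contrib <- matrix(0, nrow(X), ncol(X),
                      dimnames = list(rownames(X), colnames(X)))
    if (length(m$trees)) {
      votes <- adaboost_votes(m, X)
      wts <- m$alphas / sum(m$alphas)
      feats <- adaboost_stump_features(m)
      for (t in seq_along(m$trees)) {
        if (is.na(feats[t])) next  # constant stump: pure base contribution
        j <- match(feats[t], colnames(X))
        contrib[, j] <- contrib[, j] + wts[t] * (votes[, t] - m$train_mean_h[t])
      }
      base <- sum(wts * m$train_mean_h)
    } else {
      base <- m$base_rate
    }
    return(list(contributions = contrib, base = base))
  }
  stopf("unknown family '%s'", fam)
}

#' Normalize attributions within each prediction
#'
#' Each row becomes `|contribution| / sum(|contributions|)`, so every
#' prediction contributes one unit of importance regardless of its output
#' magnitude; sign (direction of effect) is discarded. All-zero rows are
#' assigned the uniform `1/k` split and counted in the `"flagged"` attribute.
#'
#' @param contributions Attribution matrix (rows = predictions).
#' @return Matrix of per-row fractions, each row summing to 1.
#' @export
normalize_per_prediction <- function(contributions) {
  a <- abs(contributions)
  s <- rowSums(a)
  zero <- s == 0
  if (any(zero)) {
    a[zero, ] <- 1
    s[zero] <- ncol(a)
  }
  out <- a / s
  if (any(zero)) attr(out, "flagged") <- sum(zero)
  out
}

#' Merge one-hot indicator importances into their parent features
#'
#' Sums the importance of every indicator column of a categorical feature
#' into a single parent-feature column; totals are conserved.
#'
#' @param normalized Normalized attribution matrix (columns = design
#'   columns).
#' @param column_map Tibble of `column`, `parent` from [encode_onehot()].
#' @return Matrix with one column per parent feature.
#' @export
merge_onehot <- function(normalized, column_map) {
  orphan <- setdiff(colnames(normalized), column_map$column)
  if (length(orphan)) {
    stopf("columns without a parent feature: %s", paste(orphan, collapse = ", "))
  }
  parent <- column_map$parent[match(colnames(normalized), column_map$column)]
  parents <- unique(column_map$parent)
  out <- matrix(0, nrow(normalized), length(parents),
                dimnames = list(rownames(normalized), parents))
  for (p in parents) {
    out[, p] <- rowSums(normalized[, parent == p, drop = FALSE])
  }
  out
}

#' Two-stage (patient-first) importance aggregation
#'
#' Averages attribution rows within each patient first, then averages the
#' patient means within each group — never a pooled row mean, so patients
#' appearing in many test sets do not dominate. Emitted for `ALL` plus every
#' requested group with at least one patient.
#'
#' @param normalized Normalized (and typically category-merged) attribution
#'   matrix.
#' @param patient_index Patient id per row.
#' @param grouping Named character vector mapping patient id to group.
#'   Patients missing from `grouping` only contribute to `ALL`.
#' @param model_family Family label stamped on the records.
#' @return Tibble of `model_family`, `group`, `feature`,
#'   `mean_normalized_importance`; importances sum to 1 within each
#'   (family, group).
#' @export
aggregate_importance <- function(normalized, patient_index, grouping = NULL,
                                 model_family = "model") {
  if (nrow(normalized) != length(patient_index)) {
    stopf("one patient id is required per attribution row")
  }
  # stage 1: mean over each patient's rows
  pm <- rowsum(normalized, group = patient_index, reorder = TRUE)
  pm <- pm / as.vector(table(patient_index)[rownames(pm)])
  groups <- list(ALL = rownames(pm))
  if (!is.null(grouping)) {
    for (g in unique(grouping)) {
      ids <- intersect(names(grouping)[grouping == g], rownames(pm))
      if (length(ids)) groups[[g]] <- ids
    }
  }
  rows <- lapply(names(groups), function(g) {
    v <- colMeans(pm[groups[[g]], , drop = FALSE])
    tibble::tibble(model_family = model_family, group = g,
                   feature = names(v), mean_normalized_importance = unname(v))
  })
  do.call(rbind, rows)
}

#' Importance records for a whole experiment
#'
#' Runs the normalize-merge-aggregate chain already accumulated by
#' [run_experiment()] through the patient-first average, for `ALL`, the two
#' outcomes, and each consensus group.
#'
#' @param experiment An `icu_experiment` run with `keep_attributions = TRUE`.
#' @param assignments Consensus assignments from [fuse_ledger()].
#' @return Tibble of importance records across model families and groups.
#' @export
compute_importance <- function(experiment, assignments) {
  if (is.null(experiment$attributions)) {
    stopf("experiment was run with keep_attributions = FALSE")
  }
  grouping <- c(
    stats::setNames(assignments$group, assignments$patient_id)
  )
  outcome_grouping <- stats::setNames(assignments$outcome,
                                      assignments$patient_id)
  rows <- lapply(names(experiment$attributions), function(fam) {
    acc <- experiment$attributions[[fam]]
    rbind(
      aggregate_importance(acc$matrix, acc$patient_id, grouping, fam),
      # outcome-level groups (alive/dead), skipping the duplicate ALL
      subset(aggregate_importance(acc$matrix, acc$patient_id,
                                  outcome_grouping, fam), group != "ALL")
    )
  })
  do.call(rbind, rows)
}

#' Ranked importance table with cumulative shares
#'
#' Sorts one (family, group)'s features by decreasing importance, ties broken
#' alphabetically, and reports the running cumulative share (conventionally
#' read at ranks 5, 10 and 15).
#'
#' @param records Importance records for a single family and group.
#' @param top_k Rows to keep; values beyond the feature count return the full
#'   table.
#' @return Tibble of `rank`, `feature`, `importance`, `cumulative`.
#' @export
rank_table <- function(records, top_k = 15L) {
  if (length(unique(records$model_family)) > 1 ||
      length(unique(records$group)) > 1) {
    stopf("rank_table expects records for a single (family, group)")
  }
  ord <- order(-records$mean_normalized_importance, records$feature)
  records <- records[ord, ]
  k <- min(top_k, nrow(records))
  tibble::tibble(
    rank = seq_len(k),
    feature = records$feature[seq_len(k)],
    importance = records$mean_normalized_importance[seq_len(k)],
    cumulative = cumsum(records$mean_normalized_importance)[seq_len(k)]
  )
}
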