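#' Raw feature values split by consensus group
#'
#' Pulls a feature's actual (non-imputed) values from the cohort and splits
#' them by each patient's consensus group. Missing cells stay missing, so
#' downstream density estimates reflect observed values only.
#'
#' @param cohort The (unimputed) `icu_cohort`.
#' @param assignments Consensus assignments from [fuse_ledger()].
#' @param feature Feature or auxiliary column name.
#' @return Named list of value vectors, one per group.
#' @export
group_feature_values <- function(cohort, assignments, feature) {
  dat <- cohort$data
  idx <- match(assignments$patient_id, dat$patient_id)
  split(dat[[feature]][idx], assignments$group)
}

#' Kernel density estimates per consensus group
#'
#' Gaussian-kernel densities on a common grid: 512 points spanning the pooled
#' data range extended by three times the largest per-group bandwidth.
#' Bandwidths follow Silverman-type rules (`stats::bw.nrd0` by default).
#' Values beyond `cutoff` are excluded from estimation but counted, matching
#' the convention of reporting "patients not shown" for long-tailed features
#' such as discharge offsets. Groups with fewer than `min_n` usable values
#' are omitted with a message.
#'
#' @param values_by_group Named list of numeric vectors (missing values
#'   allowed; they are dropped from `n_used`).
#' @param feature Feature label stamped on the results.
#' @param bandwidth_rule `"nrd0"` (Silverman) or `"nrd"` (Scott).
#' @param cutoff Upper display cutoff in feature units (default `Inf`).
#' @param min_n Minimum usable values per group (default 2).
#' @return List of `kde_result` objects with fields `feature`, `group`,
#'   `grid`, `density`, `bandwidth`, `n_used`, `n_beyond_cutoff`.
#' @export
kde_by_group <- function(values_by_group, feature = "",
                         bandwidth_rule = c("nrd0", "nrd"),
                         cutoff = Inf, min_n = 2L) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  bw_fun <- switch(bandwidth_rule, nrd0 = stats::bw.nrd0, nrd = stats::bw.nrd)
  clean <- lapply(values_by_group, function(v) v[!is.na(v)])
  beyond <- vapply(clean, function(v) sum(v > cutoff), 0L)
  clean <- lapply(clean, function(v) v[v <= cutoff])
  usable <- vapply(clean, length, 0L) >= min_n
  if (any(!usable)) {
    message("groups omitted (fewer than ", min_n, " values): ",
            paste(names(clean)[!usable], collapse = ", "))
  }
  clean <- clean[usable]
  if (!length(clean)) return(list())
  bws <- vapply(clean, function(v) {
    b <- bw_fun(v)
    if (!is.finite(b) || b <= 0) b <- max(stats::sd(v), 1e-3)  # degenerate sample
    b
  }, 0)
  pooled <- unlist(clean, use.names = FALSE)
  lo <- min(pooled) - 3 * max(bws)
  hi <- max(pooled) + 3 * max(bws)
  out <- lapply(names(clean), function(g) {
    d <- stats::density(clean[[g]], bw = bws[[g]], kernel = "gaussian",
                        from = lo, to = hi, n = 512)
    structure(list(feature = feature, group = g,
                   grid = d$x, density = d$y, bandwidth = bws[[g]],
                   n_used = length(clean[[g]]),
                   n_beyond_cutoff = unname(beyond[[g]])),
              class = "kde_result")
  })
  names(out) <- names(clean)
  out
}

#' @export
print.kde_result <- function(x, ...) {
  cat(sprintf("<kde_result> %s / %s: n=%d (%d beyond cutoff), bw=%.3g\n",
              x$feature, x$group, x$n_used, x$n_beyond_cutoff, x$bandwidth))
  invisible(x)
}

#' Tidy a list of KDE results
#'
#' @param kdes List from [kde_by_group()].
#' @return Tibble of `feature`, `group`, `grid`, `density`.
#' @export
kde_tidy <- function(kdes) {
  do.call(rbind, lapply(kdes, function(k) {
    tibble::tibble(feature = k$feature, group = k$group,
                   grid = k$grid, density = k$density)
  }))
}

#' Per-group categorical occurrence shares
#'
#' Percentage of each category among non-missing values, per consensus group.
#' Shares within a group sum to 100; a group with no non-missing values
#' yields `NA` shares.
#'
#' @param cohort The (unimputed) `icu_cohort`.
#' @param assignments Consensus assignments from [fuse_ledger()].
#' @param feature A binary or categorical feature name.
#' @return Tibble of `feature`, `group`, `category`, `share` (percent).
#' @export
categorical_shares <- function(cohort, assignments, feature) {
  spec <- schema_get(cohort$schema, feature)
  if (spec$kind == "continuous") {
    stopf("categorical_shares requires a binary or categorical feature")
  }
  cats <- if (spec$kind == "binary") c("0", "1") else spec$categories
  vals <- group_feature_values(cohort, assignments, feature)
  rows <- lapply(names(vals), function(g) {
    v <- as.character(vals[[g]])
    v <- v[!is.na(v)]
    share <- if (length(v)) {
      100 * as.numeric(table(factor(v, levels = cats))) / length(v)
    } else {
      rep(NA_real_, length(cats))
    }
    tibble::tibble(feature = feature, group = g, category = cats,
                   share = share)
  })
  do.call(rbind, rows)
}

#' Auxiliary per-group summaries
#'
#' Applies the same density machinery to four quantities that are not model
#' inputs but separate the consensus groups: the acute physiology score, the
#' unit and hospital discharge offsets (in minutes, with a display cutoff for
#' long stays), and the per-patient count of missing feature values. Also
#' reports, per group, the share of patients whose unit and hospital
#' discharge offsets coincide (patients who leave the hospital, or die,
#' straight from the ICU).
#'
#' @param cohort The (unimputed) `icu_cohort`.
#' @param assignments Consensus assignments from [fuse_ledger()].
#' @param offset_cutoff Display cutoff for both offsets, minutes (default
#'   20000, about two weeks).
#' @return List with `kde` (named list of KDE-result lists for `aps`,
#'   `unit_discharge_offset`, `hospital_discharge_offset`,
#'   `missing_count`), `missing_count_by_group` (tibble of group means), and
#'   `identical_offset` (tibble of per-group percent with identical offsets).
#' @export
auxiliary_summary <- function(cohort, assignments, offset_cutoff = 20000) {
  dat <- cohort$data
  idx <- match(assignments$patient_id, dat$patient_id)
  feats <- schema_names(cohort$schema)
  miss_count <- rowSums(is.na(dat[, feats, drop = FALSE]))

  by_group <- function(v) split(v[idx], assignments$group)
  kde <- list(
    aps = kde_by_group(by_group(dat$aps), "aps"),
    unit_discharge_offset = kde_by_group(by_group(dat$unit_discharge_offset),
                                         "unit_discharge_offset",
                                         cutoff = offset_cutoff),
    hospital_discharge_offset = kde_by_group(
      by_group(dat$hospital_discharge_offset), "hospital_discharge_offset",
      cutoff = offset_cutoff),
    missing_count = kde_by_group(by_group(miss_count), "missing_count")
  )

  mc <- by_group(miss_count)
  ident <- by_group(dat$unit_discharge_offset == dat$hospital_discharge_offset)
  list(
    kde = kde,
    missing_count_by_group = tibble::tibble(
      group = names(mc),
      mean_missing = vapply(mc, mean, 0)
    ),
    identical_offset = tibble::tibble(
      group = names(ident),
      percent_identical = vapply(ident, function(z) 100 * mean(z), 0)
    )
  )
}
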