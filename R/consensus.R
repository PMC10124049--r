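#' Fuse accumulated votes into a final prediction and consensus group
#'
#' For each patient, `X% = 100 * votes_alive / (votes_alive + votes_dead)`.
#' If `X%` reaches the agreement threshold the fused prediction is `Alive`;
#' if the dead share `Y% = 100 - X%` reaches it, `Dead`; otherwise `MIXED`.
#' Crossing the fused prediction with the hospital-discharge outcome assigns
#' the consensus group: (Alive, alive) = TN, (Alive, dead) = FN,
#' (Dead, dead) = TP, (Dead, alive) = FP, MIXED stays MIXED. Because the
#' threshold exceeds 50, at most one class can reach it, so the fused
#' decision is single-valued.
#'
#' @param votes_alive,votes_dead Non-negative vote counts.
#' @param outcome `"alive"`/`"dead"` at hospital discharge.
#' @param agreement_threshold Percent in `(50, 100]`.
#' @param strict Compare shares with `>` instead of the default `>=`. The
#'   default keeps the 100% threshold meaningful ("all votes agree").
#' @return Tibble with `fraction_alive`, `fraction_dead`, `final_prediction`,
#'   `group`.
#' @export
#' @examples
#' fuse(92, 8, "dead", 90)  # final prediction Alive, group FN
fuse <- function(votes_alive, votes_dead, outcome,
                 agreement_threshold = 90, strict = FALSE) {
  if (agreement_threshold <= 50 || agreement_threshold > 100) {
    stopf("agreement_threshold must lie in (50, 100]")
  }
  total <- votes_alive + votes_dead
  if (any(total < 1)) {
    stopf("patient with zero test-set appearances cannot be fused; report as unassessed")
  }
  x <- 100 * votes_alive / total
  y <- 100 - x
  meets <- if (strict) function(v) v > agreement_threshold else function(v) v >= agreement_threshold
  final <- ifelse(meets(x), "Alive", ifelse(meets(y), "Dead", "MIXED"))
  group <- ifelse(
    final == "MIXED", "MIXED",
    ifelse(final == "Alive",
           ifelse(outcome == "alive", "TN", "FN"),
           ifelse(outcome == "dead", "TP", "FP")))
  tibble::tibble(fraction_alive = x, fraction_dead = y,
                 final_prediction = final, group = group)
}

#' Fuse a whole prediction ledger
#'
#' Applies [fuse()] to every assessed patient in a ledger; patients with zero
#' appearances are returned separately as unassessed, never silently grouped.
#'
#' @param ledger Ledger tibble from [run_experiment()] (columns `patient_id`,
#'   `votes_alive`, `votes_dead`, `outcome`, `n_appearances`).
#' @param agreement_threshold Percent in `(50, 100]` (default 90).
#' @param strict See [fuse()].
#' @return Tibble of consensus assignments (`patient_id`, `fraction_alive`,
#'   `fraction_dead`, `final_prediction`, `group`, `outcome`), with the ids
#'   of unassessed patients in attribute `"unassessed"`.
#' @export
fuse_ledger <- function(ledger, agreement_threshold = 90, strict = FALSE) {
  assessed <- ledger$n_appearances > 0
  fl <- fuse(ledger$votes_alive[assessed], ledger$votes_dead[assessed],
             ledger$outcome[assessed], agreement_threshold, strict)
  out <- tibble::tibble(patient_id = ledger$patient_id[assessed],
                        fl,
                        outcome = ledger$outcome[assessed])
  attr(out, "unassessed") <- ledger$patient_id[!assessed]
  out
}

#' Group shares across a sweep of agreement thresholds
#'
#' Fuses the ledger at each threshold and reports the percentage of assessed
#' patients per consensus group. Shares sum to 100 at every threshold; the
#' MIXED share is non-decreasing and each of TN/TP/FN/FP non-increasing as
#' the threshold rises.
#'
#' @param ledger Ledger tibble from [run_experiment()].
#' @param thresholds Percents in `(50, 100]`.
#' @param strict See [fuse()].
#' @return Tibble with columns `threshold`, `tn`, `tp`, `fn`, `fp`, `mixed`
#'   (percent of assessed patients).
#' @export
sweep_thresholds <- function(ledger, thresholds = seq(55, 100, by = 5),
                             strict = FALSE) {
  rows <- lapply(thresholds, function(th) {
    g <- fuse_ledger(ledger, th, strict)$group
    shares <- 100 * table(factor(g, levels = c("TN", "TP", "FN", "FP",
                                               "MIXED"))) / length(g)
    tibble::tibble(threshold = th,
                   tn = shares[["TN"]], tp = shares[["TP"]],
                   fn = shares[["FN"]], fp = shares[["FP"]],
                   mixed = shares[["MIXED"]])
  })
  do.call(rbind, rows)
}

#' Test-set occurrence statistics
#'
#' Minimum, mean and maximum number of rounds each patient spent in the test
#' set. With 100 rounds at a 25% test fraction the per-patient count is
#' Binomial(100, 0.25), i.e. a mean of 25 appearances.
#'
#' @param ledger Ledger tibble from [run_experiment()].
#' @return Named list `min`, `mean`, `max`.
#' @export
occurrence_stats <- function(ledger) {
  if (!nrow(ledger)) stopf("empty ledger")
  list(min = min(ledger$n_appearances),
       mean = mean(ledger$n_appearances),
       max = max(ledger$n_appearances))
}
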