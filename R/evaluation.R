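#' Confusion matrix against a gold standard
#'
#' Counts reported match pairs against the true entity partition over all
#' `choose(n, 2)` record pairs.
#'
#' @param reported a [pair_set] of pairs reported as matches
#' @param gold a `gold_standard` (see [derive_gold_standard()])
#' @param n number of records in the dataset
#' @return list of class `confusion_matrix` with integers `TP`, `FP`, `FN`,
#'   `TN`
#' @export
confusion <- function(reported, gold, n) {
  stopifnot(inherits(reported, "pair_set"), inherits(gold, "gold_standard"),
            n >= 1)
  truth <- gold$true_match_pairs
  tp <- n_pairs(pair_intersect(reported, truth))
  fp <- n_pairs(reported) - tp
  fn <- n_pairs(truth) - tp
  total <- choose(n, 2)
  structure(list(TP = tp, FP = fp, FN = fn, TN = total - tp - fp - fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%s\n",
              x$TP, x$FP, x$FN, format(x$TN, scientific = FALSE)))
  invisible(x)
}

#' Indexing quality and complexity metrics
#'
#' The standard complexity/quality summary of a de-duplication run:
#' * pairs quality (precision analogue) `PQ = match_count / candidate_count`
#' * pairs completeness (recall analogue)
#'   `PC = match_count / total_true_pairs`
#' * reduction ratio `RR = 1 - candidate_count / choose(n, 2)`
#' * `F = 2 * PC * RR / (PC + RR)`, the harmonic mean of completeness and
#'   reduction (0 when both are 0).
#'
#' @param candidate_count candidate pairs generated by the indexing step
#' @param match_count matching pairs found among them
#' @param total_true_pairs true matching pairs in the dataset (from the gold
#'   standard, or [expected_matching_pairs()] when no gold standard exists)
#' @param n number of records
#' @return list of class `metrics_report` with `pq`, `pc`, `rr`, `f_score`
#'   and the input counts (plus `total_pairs = choose(n, 2)`)
#' @export
linkage_metrics <- function(candidate_count, match_count, total_true_pairs,
                            n) {
  total_pairs <- choose(n, 2)
  stopifnot(candidate_count >= 0, candidate_count <= total_pairs,
            match_count >= 0, match_count <= candidate_count,
            total_true_pairs >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  pq <- safe_div(match_count, candidate_count, "pairs quality")
  pc <- safe_div(match_count, total_true_pairs, "pairs completeness")
  rr <- 1 - candidate_count / total_pairs
  f <- if (pc + rr > 0) 2 * pc * rr / (pc + rr) else 0
  structure(list(pq = pq, pc = pc, rr = rr, f_score = f,
                 candidate_count = candidate_count,
                 match_count = match_count,
                 total_true_pairs = total_true_pairs,
                 total_pairs = total_pairs, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: PQ=%.6f PC=%.3f RR=%.3f F=%.3f (%s candidates, %s matches, %s true pairs, n=%d)\n",
    x$pq, x$pc, x$rr, x$f_score,
    format(x$candidate_count, scientific = FALSE),
    format(x$match_count, scientific = FALSE),
    format(x$total_true_pairs, scientific = FALSE), x$n))
  invisible(x)
}

#' Expected number of true matching pairs in a dirty dataset
#'
#' For a dataset of `n` records with duplicate ratio `DR` (duplicates / n)
#' and `d` duplicates per original on average, the expected true-match count
#' is `DR * (n/d) * [d + d*(d-1)/2]`: each of the `DR*n/d` duplicated
#' entities contributes `d` original-duplicate pairs plus `C(d, 2)`
#' duplicate-duplicate pairs.
#'
#' @param n dataset size
#' @param dr duplicate ratio in `[0, 1]`
#' @param d duplicates per original record (>= 1)
#' @return expected number of matching pairs (real)
#' @examples
#' expected_matching_pairs(1000, 0.5, 1)  # 500
#' @export
expected_matching_pairs <- function(n, dr, d) {
  stopifnot(n >= 1, dr >= 0, dr <= 1, d >= 1)
  dr * (n / d) * (d + d * (d - 1) / 2)
}

#' Full evaluation of a reported match set
#'
#' Convenience wrapper combining [confusion()] and [linkage_metrics()] for a
#' finished run: the candidate count is taken from the run, the match count
#' is the number of pairs classified as Match, and the true-pair total comes
#' from the gold standard.
#'
#' @param matches [pair_set] of pairs classified as Match
#' @param candidate_count number of candidate pairs the indexing generated
#' @param gold a `gold_standard`
#' @param n number of records
#' @return list with `confusion` and `metrics`
#' @export
evaluate_run <- function(matches, candidate_count, gold, n) {
  cm <- confusion(matches, gold, n)
  list(confusion = cm,
       metrics = linkage_metrics(candidate_count, n_pairs(matches),
                                 n_pairs(gold$true_match_pairs), n))
}
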