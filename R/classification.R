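#' Two-threshold match classification bounds
#'
#' Lower and upper bounds on the aggregate score F. A pair with
#' `F >= t_upper` is a Match, `F < t_lower` a Non-Match, anything between a
#' Possible Match (clerical-review zone). `thresholds(1, 1)` gives the
#' deterministic rule: only exact agreement on every linkage field matches.
#'
#' @param t_lower,t_upper reals with `0 <= t_lower <= t_upper <= 1`
#' @return a `thresholds` object
#' @export
thresholds <- function(t_lower = 0.5, t_upper = 0.75) {
  stopifnot(is.numeric(t_lower), is.numeric(t_upper),
            t_lower >= 0, t_lower <= t_upper, t_upper <= 1)
  structure(list(t_lower = t_lower, t_upper = t_upper), class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("thresholds: non-match < %g <= possible < %g <= match\n",
              x$t_lower, x$t_upper))
  invisible(x)
}

#' Classify aggregate scores against the thresholds
#'
#' Boundaries are as stated by the rule: `F >= t_upper` -> `"match"`,
#' `F < t_lower` -> `"non_match"`, otherwise `"possible"`.
#'
#' @param f numeric vector of aggregate scores in `[0, 1]`
#' @param th a [thresholds] object
#' @return character vector of labels
#' @export
classify_score <- function(f, th) {
  stopifnot(inherits(th, "thresholds"))
  ifelse(f >= th$t_upper, "match",
         ifelse(f < th$t_lower, "non_match", "possible"))
}

#' Compare and classify a candidate pair set
#'
#' Runs [compare_pairs()] on every candidate and partitions the pairs into
#' Match / Possible Match / Non-Match by [classify_score()].
#'
#' @param cands a [pair_set] of candidates
#' @param ds the `dedup_dataset` the ids refer to
#' @param rules list of [field_rule] objects; default [default_rules()]
#' @param th a [thresholds] object; default `thresholds()`
#' @param missing_ignore passed to [compare_pairs()]
#' @return a `classification_result`: list with `matches`,
#'   `possible_matches`, `non_matches` (three disjoint [pair_set]s that
#'   partition the candidates) and `scores` (the [compare_pairs()] frame
#'   plus a `class` column)
#' @export
classify_pairs <- function(cands, ds, rules = default_rules(),
                           th = thresholds(), missing_ignore = FALSE) {
  scores <- compare_pairs(cands, ds, rules, missing_ignore = missing_ignore)
  scores$class <- if (nrow(scores)) classify_score(scores$F, th)
                  else character()
  pick <- function(lbl) {
    sel <- scores$class == lbl
    pair_set(scores$id_a[sel], scores$id_b[sel])
  }
  structure(list(matches = pick("match"),
                 possible_matches = pick("possible"),
                 non_matches = pick("non_match"),
                 scores = scores),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result:",
      n_pairs(x$matches), "matches,",
      n_pairs(x$possible_matches), "possible,",
      n_pairs(x$non_matches), "non-matches\n")
  invisible(x)
}
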