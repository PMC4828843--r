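#' Normalised edit-distance similarity
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`, using the base
#' Levenshtein implementation ([utils::adist()]). Equal non-empty strings
#' score 1; if either value is missing (empty) the score is 0
#' (disagreement), unless callers opt to drop missing fields from the
#' aggregate (see [compare_pairs()]).
#'
#' @param a,b character vectors (recycled to common length)
#' @return numeric vector of similarities in `[0, 1]`
#' @examples
#' edit_distance_sim("peter", "pedro")  # distance 3 over length 5 -> 0.4
#' @export
edit_distance_sim <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- numeric(n)
  ok <- nzchar(a) & nzchar(b)
  if (any(ok)) {
    d <- mapply(function(x, y) utils::adist(x, y)[1L, 1L], a[ok], b[ok],
                USE.NAMES = FALSE)
    out[ok] <- 1 - d / pmax(nchar(a[ok]), nchar(b[ok]))
  }
  out
}

qgrams <- function(x, q) {
  n <- nchar(x)
  if (n < q) return(character())
  substring(x, 1:(n - q + 1L), q:n)
}

#' q-gram similarity
#'
#' Counts the q-grams (length-q substrings, no padding) common to both
#' values as multisets and divides by the average q-gram count:
#' `|common| / ((c_a + c_b)/2)`. Scores 0 when either side has no q-grams
#' (shorter than `q`, or missing).
#'
#' @param a,b character vectors (recycled to common length)
#' @param q q-gram length (default 2, i.e. bigrams)
#' @return numeric vector of similarities in `[0, 1]`
#' @examples
#' qgram_sim("peter", "pedro")  # one shared bigram of four -> 0.25
#' @export
qgram_sim <- function(a, b, q = 2L) {
  stopifnot(q >= 1)
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  mapply(function(x, y) {
    ga <- qgrams(x, q)
    gb <- qgrams(y, q)
    if (length(ga) == 0L || length(gb) == 0L) return(0)
    ta <- table(ga)
    tb <- table(gb)
    shared <- intersect(names(ta), names(tb))
    common <- sum(pmin(ta[shared], tb[shared]))
    common / ((length(ga) + length(gb)) / 2)
  }, a, b, USE.NAMES = FALSE)
}

#' Exact-agreement similarities on encoded values
#'
#' `soundex_exact_sim` scores 1 when both values are non-empty and share a
#' soundex code, else 0. `substring_exact_sim` does the same on the first
#' `k` characters.
#'
#' @param a,b character vectors (recycled to common length)
#' @return numeric vector of 0/1 similarities
#' @export
soundex_exact_sim <- function(a, b) {
  as.numeric(nzchar(a) & nzchar(b) & soundex(a) == soundex(b))
}

#' @rdname soundex_exact_sim
#' @param k prefix length
#' @export
substring_exact_sim <- function(a, b, k = 4L) {
  as.numeric(nzchar(a) & nzchar(b) &
               substring_prefix(a, k) == substring_prefix(b, k))
}

#' Per-field comparison rule
#'
#' One entry of the linking-key specification: which field to compare, with
#' which comparator, and its weight in the aggregate score.
#'
#' @param field schema field name
#' @param comparator one of `"edit_distance"`, `"qgram"`, `"soundex_exact"`,
#'   `"substring_exact"`
#' @param q q-gram length (qgram comparator only)
#' @param prefix_len prefix length (substring_exact comparator only)
#' @param weight non-negative weight in the aggregate score (default 1)
#' @return a `field_rule` object
#' @export
field_rule <- function(field,
                       comparator = c("edit_distance", "qgram",
                                      "soundex_exact", "substring_exact"),
                       q = 2L, prefix_len = 4L, weight = 1) {
  comparator <- match.arg(comparator)
  stopifnot(is.character(field), length(field) == 1L, nzchar(field),
            q >= 1, prefix_len >= 1, weight >= 0)
  structure(list(field = field, comparator = comparator, q = as.integer(q),
                 prefix_len = as.integer(prefix_len), weight = weight),
            class = "field_rule")
}

#' Default linking-key rules
#'
#' The five-field linking key used throughout: postcode and soc_sec_id by
#' edit distance, address_1 by q-gram, and the two name fields by exact
#' agreement of their encoded form. The name-field comparator follows the
#' run's indexing encoding (`"soundex"` or `"substring"`); `"both"` applies
#' soundex and substring rules to each name field.
#'
#' @param encoding `"soundex"`, `"substring"` or `"both"` for the name fields
#' @param prefix_len substring prefix length (default 4)
#' @return list of [field_rule] objects
#' @export
default_rules <- function(encoding = c("soundex", "substring", "both"),
                          prefix_len = 4L) {
  encoding <- match.arg(encoding)
  name_rules <- function(f) switch(
    encoding,
    soundex = list(field_rule(f, "soundex_exact")),
    substring = list(field_rule(f, "substring_exact",
                                prefix_len = prefix_len)),
    both = list(field_rule(f, "soundex_exact"),
                field_rule(f, "substring_exact", prefix_len = prefix_len)))
  c(list(field_rule("postcode", "edit_distance"),
         field_rule("address_1", "qgram"),
         field_rule("soc_sec_id", "edit_distance")),
    name_rules("given_name"),
    name_rules("surname"))
}

apply_rule <- function(rule, a, b) {
  switch(rule$comparator,
         edit_distance = edit_distance_sim(a, b),
         qgram = qgram_sim(a, b, rule$q),
         soundex_exact = soundex_exact_sim(a, b),
         substring_exact = substring_exact_sim(a, b, rule$prefix_len))
}

#' Compare candidate record pairs field by field
#'
#' Builds the weight (comparison) vector for every candidate pair: one
#' similarity in `[0, 1]` per rule, plus the aggregate score
#' `F = sum(weight * sim) / sum(weight)`. By default a missing value on
#' either side scores 0 for that field (disagreement); with
#' `missing_ignore = TRUE` a field missing on either side is dropped from
#' the weighted mean instead (pairs missing every rule field get `F = 0`).
#'
#' @param pairs a [pair_set]
#' @param ds the `dedup_dataset` the ids refer to
#' @param rules list of [field_rule] objects (non-empty);
#'   default [default_rules()]
#' @param missing_ignore drop missing fields from the mean instead of
#'   scoring them 0
#' @return data frame with columns `id_a`, `id_b`, one `sim_<field>` column
#'   per rule, and `F`
#' @export
compare_pairs <- function(pairs, ds, rules = default_rules(),
                          missing_ignore = FALSE) {
  stopifnot(inherits(pairs, "pair_set"), inherits(ds, "dedup_dataset"),
            is.list(rules))
  if (length(rules) == 0L) stop("spec error: empty rule list")
  if (!all(vapply(rules, inherits, TRUE, "field_rule")))
    stop("spec error: rules must be field_rule objects")
  unknown <- setdiff(vapply(rules, `[[`, "", "field"), attr(ds, "schema"))
  if (length(unknown) > 0L)
    stop("spec error: unknown rule field(s): ",
         paste(unknown, collapse = ", "))
  df <- as.data.frame(pairs)
  missing_ids <- setdiff(c(df$id_a, df$id_b), ds$rec_id)
  if (length(missing_ids) > 0L)
    stop("integrity error: pair id(s) not in dataset: ", missing_ids[1L])
  out <- df
  sim_names <- make.unique(paste0("sim_", vapply(rules, rule_label, "")))
  if (nrow(df) == 0L) {
    for (nm in sim_names) out[[nm]] <- numeric()
    out$F <- numeric()
    return(out)
  }
  ia <- match(df$id_a, ds$rec_id)
  ib <- match(df$id_b, ds$rec_id)
  w <- vapply(rules, `[[`, 0, "weight")
  sims <- matrix(0, nrow(df), length(rules))
  present <- matrix(TRUE, nrow(df), length(rules))
  for (k in seq_along(rules)) {
    a <- ds[[rules[[k]]$field]][ia]
    b <- ds[[rules[[k]]$field]][ib]
    sims[, k] <- apply_rule(rules[[k]], a, b)
    present[, k] <- nzchar(a) & nzchar(b)
    out[[sim_names[k]]] <- sims[, k]
  }
  if (missing_ignore) {
    wm <- present * rep(w, each = nrow(df))
    tot <- rowSums(wm)
    out$F <- ifelse(tot > 0, rowSums(sims * wm) / tot, 0)
  } else {
    out$F <- as.numeric(sims %*% w / sum(w))
  }
  out
}

rule_label <- function(rule) rule$field

#' @export
print.field_rule <- function(x, ...) {
  cat("field_rule:", x$field, "via", x$comparator,
      if (x$weight != 1) paste0("(weight ", x$weight, ")") else "", "\n")
  invisible(x)
}
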