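#' Build an inverted index over encoded key values
#'
#' Groups records by their encoded key value. Each record lands in at most
#' one bucket; records whose key value is empty (all key fields missing) are
#' excluded from the index by default, so they generate no candidate pairs
#' in that pass. Set `empty_key_bucket = TRUE` to pool them into a single
#' shared bucket instead.
#'
#' @param ds a `dedup_dataset`
#' @param spec a [key_spec]
#' @param empty_key_bucket pool empty-key records into one bucket keyed `""`
#'   (sorted before every other key) instead of dropping them
#' @return an `inverted_index`: list with `buckets` (named list key value ->
#'   character vector of rec_ids), `keys` (bucket keys in ascending
#'   lexicographic order) and `b` (bucket count)
#' @export
build_index <- function(ds, spec, empty_key_bucket = FALSE) {
  keys <- build_keys(ds, spec)
  if (!empty_key_bucket) keys <- keys[nzchar(keys)]
  buckets <- split(names(keys), keys)
  # C-locale byte order: deterministic across platforms
  ord <- order(names(buckets), method = "radix")
  buckets <- buckets[ord]
  structure(list(buckets = buckets, keys = names(buckets),
                 b = length(buckets)),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  sizes <- lengths(x$buckets)
  cat("inverted_index:", x$b, "buckets,", sum(sizes), "records",
      sprintf("(bucket size %d-%d)\n",
              if (x$b) min(sizes) else 0L, if (x$b) max(sizes) else 0L))
  invisible(x)
}

#' Candidate pairs by blocking
#'
#' Standard blocking: only records sharing a bucket (i.e. an encoded key
#' value) are paired.
#'
#' @param ix an `inverted_index`
#' @return a [pair_set] — the union over buckets of all within-bucket
#'   unordered pairs
#' @export
block_pairs <- function(ix) {
  stopifnot(inherits(ix, "inverted_index"))
  big <- ix$buckets[lengths(ix$buckets) >= 2L]
  if (length(big) == 0L) return(pair_set())
  do.call(pair_union, lapply(big, all_pairs))
}

#' Candidate pairs by sorted-neighbourhood windowing
#'
#' Buckets are ordered by ascending key value and a fixed window of `w`
#' consecutive buckets is slid over them one bucket at a time; all records
#' in a common window are paired. Whole buckets enter a window, so ties
#' within a bucket need no tie-break. With `w = 1` this degenerates to
#' [block_pairs()]; when there are at most `w` buckets a single window
#' covers everything.
#'
#' @param ix an `inverted_index`
#' @param w window size in buckets (positive integer)
#' @return a [pair_set] — the deduplicated union of all within-window pairs
#' @export
window_pairs <- function(ix, w) {
  stopifnot(inherits(ix, "inverted_index"),
            is.numeric(w), length(w) == 1L, w >= 1)
  w <- as.integer(w)
  b <- ix$b
  if (b == 0L) return(pair_set())
  # two buckets share a window iff their positions differ by < w (all
  # positions share one when b <= w), so the union decomposes into
  # within-bucket pairs plus cross pairs at position gaps 1..w-1
  gap_max <- if (b <= w) b - 1L else w - 1L
  sets <- lapply(ix$buckets[lengths(ix$buckets) >= 2L], all_pairs)
  if (gap_max >= 1L && b >= 2L) {
    for (p in seq_len(b - 1L)) {
      for (q in (p + 1L):min(b, p + gap_max)) {
        a_ids <- ix$buckets[[p]]
        b_ids <- ix$buckets[[q]]
        grid <- expand.grid(a = a_ids, b = b_ids, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        sets[[length(sets) + 1L]] <- pair_set(grid$a, grid$b)
      }
    }
  }
  if (length(sets) == 0L) return(pair_set())
  do.call(pair_union, sets)
}

#' Union of candidate pair sets from multiple passes
#'
#' Multipass blocking/windowing runs the indexing step once per key and
#' keeps the union of the candidate sets, so duplicates missed by one key
#' get another chance under the next.
#'
#' @param pair_sets list of [pair_set] objects (at least one)
#' @return a [pair_set]
#' @export
multipass_union <- function(pair_sets) {
  stopifnot(is.list(pair_sets), length(pair_sets) >= 1L)
  do.call(pair_union, pair_sets)
}

# ---- closed-form comparison-count estimators -------------------------------
# All estimators assume b uniform buckets of n/b records and return reals
# (expectations), not integers.

#' Expected record comparisons under blocking
#'
#' For `n` records spread uniformly over `b` blocks, blocking compares
#' `b * [(n/b)((n/b)-1)]/2` record pairs.
#'
#' @param n dataset size
#' @param b number of blocks (`b <= n`)
#' @return expected number of record comparisons (real)
#' @export
est_block_comparisons <- function(n, b) {
  stopifnot(n >= 1, b >= 1, b <= n)
  m <- n / b
  b * m * (m - 1) / 2
}

#' Expected comparisons for single-key blocking
#'
#' Single-key blocking on a key with `i` distinct values forms `i` blocks of
#' average size `n/i`.
#'
#' @param n dataset size
#' @param i distinct values of the (first) key
#' @return expected number of record comparisons (real)
#' @export
est_skb_comparisons <- function(n, i) est_block_comparisons(n, i)

#' Expected comparisons for composite-key blocking
#'
#' Blocking on the concatenation of two keys with `i` and `j` distinct
#' values (`i >= j`) forms on average `i*j/2` blocks of size `2n/(i*j)`, so
#' composite-key blocking never exceeds the single-key count for `j >= 2`.
#'
#' @param n dataset size
#' @param i,j distinct values of the two keys, `i >= j`
#' @return expected number of record comparisons (real)
#' @export
est_ckb_comparisons <- function(n, i, j) {
  stopifnot(i >= j, j >= 1)
  nb <- i * j / 2
  m <- n / nb
  nb * m * (m - 1) / 2
}

#' Expected comparisons for two-pass multipass blocking
#'
#' One single-key pass per key, candidate sets unioned; the expectation adds
#' the per-pass counts (overlap between passes is ignored by the model).
#'
#' @param n dataset size
#' @param i,j distinct values of the two pass keys
#' @return expected number of record comparisons (real)
#' @export
est_mpb_comparisons <- function(n, i, j) {
  est_skb_comparisons(n, i) + est_skb_comparisons(n, j)
}

#' Expected comparisons for sorted-neighbourhood windowing
#'
#' For `b` uniform buckets of `n/b` records and window size `w`: the first
#' window holds `wn/b` records and contributes `(wn/b)((wn/b)-1)/2` pairs;
#' each of the remaining `b - w` window positions introduces one new bucket,
#' adding its internal pairs plus its cross pairs with the `w - 1` buckets
#' already in the window. At `w = 1` this reduces to
#' [est_block_comparisons()]; at `w = b` it is the full `C(n,2)`.
#'
#' @param n dataset size
#' @param b number of buckets
#' @param w window size, `1 <= w <= b`
#' @return expected number of record comparisons (real)
#' @export
est_window_comparisons <- function(n, b, w) {
  stopifnot(w >= 1, w <= b, b <= n)
  m <- n / b
  wn <- w * m
  wn * (wn - 1) / 2 + (b - w) * (m * (m - 1) / 2 + (w - 1) * m^2)
}
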