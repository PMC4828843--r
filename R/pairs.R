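#' Candidate pair sets
#'
#' A `pair_set` is the canonical container for unordered record-id pairs
#' produced by blocking or windowing and consumed by comparison,
#' classification and evaluation. Pairs are stored as a two-column character
#' matrix with `id_a < id_b` (lexicographic), no self-pairs and no
#' duplicates, in sorted order so that identical sets are identical objects.
#'
#' @param id_a,id_b character vectors of equal length; element `i` of each
#'   forms one unordered pair. Self-pairs are dropped.
#' @return an object of class `pair_set`.
#' @examples
#' ps <- pair_set(c("r2", "r1"), c("r1", "r2"))
#' n_pairs(ps)  # 1: the two entries canonicalise to the same pair
#' @export
pair_set <- function(id_a = character(), id_b = character()) {
  id_a <- as.character(id_a)
  id_b <- as.character(id_b)
  stopifnot(length(id_a) == length(id_b))
  keep <- id_a != id_b
  id_a <- id_a[keep]
  id_b <- id_b[keep]
  swap <- id_a > id_b
  if (any(swap)) {
    tmp <- id_a[swap]
    id_a[swap] <- id_b[swap]
    id_b[swap] <- tmp
  }
  key <- paste(id_a, id_b, sep = "\x1f")
  ord <- order(key)
  dup <- duplicated(key[ord])
  m <- cbind(id_a = id_a[ord][!dup], id_b = id_b[ord][!dup])
  structure(m, class = c("pair_set", class(m)))
}

#' @rdname pair_set
#' @param ps a `pair_set`
#' @export
n_pairs <- function(ps) {
  stopifnot(inherits(ps, "pair_set"))
  nrow(ps)
}

pair_keys <- function(ps) {
  if (nrow(ps) == 0L) return(character())
  paste(ps[, 1L], ps[, 2L], sep = "\x1f")
}

keys_to_pair_set <- function(keys) {
  if (length(keys) == 0L) return(pair_set())
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  pair_set(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Set algebra on candidate pair sets
#'
#' `pair_union()` deduplicates the union of any number of pair sets (the
#' multipass combination step); `pair_intersect()` and `pair_diff()` give the
#' usual intersection and asymmetric difference.
#'
#' @param ... `pair_set` objects (for `pair_union`)
#' @return a `pair_set`
#' @export
pair_union <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "pair_set")))
  keys <- unique(unlist(lapply(sets, pair_keys), use.names = FALSE))
  keys_to_pair_set(keys)
}

#' @rdname pair_union
#' @param x,y `pair_set` objects
#' @export
pair_intersect <- function(x, y) {
  keys_to_pair_set(intersect(pair_keys(x), pair_keys(y)))
}

#' @rdname pair_union
#' @export
pair_diff <- function(x, y) {
  keys_to_pair_set(setdiff(pair_keys(x), pair_keys(y)))
}

#' @export
print.pair_set <- function(x, ...) {
  cat("pair_set with", nrow(x), "unordered pairs\n")
  if (nrow(x) > 0L) {
    show <- utils::head(cbind(x[, 1L], x[, 2L]), 6L)
    apply(show, 1L, function(r) cat(" ", r[1L], "--", r[2L], "\n"))
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pair_set <- function(x, ...) {
  data.frame(id_a = as.character(x[, 1L]), id_b = as.character(x[, 2L]),
             stringsAsFactors = FALSE)
}

#' All unordered pairs among a set of ids
#'
#' Used internally by blocking and windowing; exported because it is also the
#' brute-force reference for small inputs.
#'
#' @param ids character vector of record ids (duplicates ignored)
#' @return a `pair_set` with `choose(length(unique(ids)), 2)` pairs
#' @export
all_pairs <- function(ids) {
  ids <- unique(as.character(ids))
  m <- length(ids)
  if (m < 2L) return(pair_set())
  idx <- utils::combn(m, 2L)
  pair_set(ids[idx[1L, ]], ids[idx[2L, ]])
}
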