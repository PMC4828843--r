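# small in-code fixtures and brute-force references shared across tests

# a dedup_dataset with the full schema; `...` are field = character-vector
# pairs, everything else is filled with ""
tiny_dataset <- function(rec_id, ...) {
  fields <- list(...)
  n <- length(rec_id)
  df <- data.frame(rec_id = rec_id, stringsAsFactors = FALSE)
  for (f in febrl_schema())
    df[[f]] <- if (f %in% names(fields)) as.character(fields[[f]])
               else rep("", n)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  read_dataset(tmp)
}

# inverted index built directly from a named key vector (names = rec ids),
# bypassing the encoders; empty keys excluded as in build_index()
index_from_keys <- function(keys) {
  keys <- keys[nzchar(keys)]
  buckets <- split(names(keys), keys)
  buckets <- buckets[order(names(buckets), method = "radix")]
  structure(list(buckets = buckets, keys = names(buckets),
                 b = length(buckets)),
            class = "inverted_index")
}

# brute-force blocking: test key equality over all C(n,2) pairs
bf_block_pairs <- function(keys) {
  ids <- names(keys)
  a <- character(); b <- character()
  n <- length(ids)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (nzchar(keys[i]) && keys[i] == keys[j]) {
        a <- c(a, ids[i]); b <- c(b, ids[j])
      }
    }
  }
  pair_set(a, b)
}

# brute-force windowing: literally slide windows of w buckets over the
# sorted distinct keys and take all pairs inside each window
bf_window_pairs <- function(keys, w) {
  keys <- keys[nzchar(keys)]
  if (length(keys) == 0L) return(pair_set())
  sorted <- sort(unique(keys), method = "radix")
  b <- length(sorted)
  starts <- seq_len(max(b - w + 1L, 1L))
  sets <- lapply(starts, function(s) {
    win_keys <- sorted[s:min(s + w - 1L, b)]
    all_pairs(names(keys)[keys %in% win_keys])
  })
  do.call(pair_union, sets)
}

# uniform synthetic index: b buckets of exactly m records
uniform_index <- function(b, m) {
  ids <- sprintf("r%03d", seq_len(b * m))
  keys <- rep(sprintf("k%03d", seq_len(b)), each = m)
  names(keys) <- ids
  index_from_keys(keys)
}
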