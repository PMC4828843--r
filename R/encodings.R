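#' American soundex phonetic code
#'
#' Encodes a word as its initial letter plus three digits describing the
#' consonant skeleton, so that similar-sounding names (smith/smyth) share a
#' code. Vowels (a, e, i, o, u, y) separate adjacent consonants of equal
#' code; h and w are transparent and do not separate them. Non-alphabetic
#' characters are stripped before encoding; an input with no letters encodes
#' to the empty string.
#'
#' @param x character vector
#' @return character vector of 4-character codes (letter + 3 digits,
#'   zero-padded), `""` where the input has no letters
#' @examples
#' soundex(c("ullman", "jeffrey", "smith", "smyth"))
#' @export
soundex <- function(x) {
  x <- toupper(gsub("[^A-Za-z]", "", as.character(x)))
  vapply(x, soundex1, "", USE.NAMES = FALSE)
}

# digit codes; "0" marks vowel separators, "" marks transparent h/w
soundex_codes <- local({
  codes <- c(A = "0", E = "0", I = "0", O = "0", U = "0", Y = "0",
             H = "", W = "",
             B = "1", F = "1", P = "1", V = "1",
             C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2",
             X = "2", Z = "2",
             D = "3", T = "3",
             L = "4", M = "5", N = "5", R = "6")
  codes[order(names(codes))]
})

soundex1 <- function(word) {
  if (!nzchar(word)) return("")
  letters_vec <- strsplit(word, "", fixed = TRUE)[[1L]]
  digits <- unname(soundex_codes[letters_vec])
  # drop transparent h/w, then collapse adjacent equal codes (this makes
  # h/w non-separating and vowels separating, per American soundex)
  keep <- digits != ""
  d <- digits[keep]
  if (length(d) > 1L) d <- d[c(TRUE, d[-1L] != d[-length(d)])]
  # the first retained code belongs to the initial letter group unless the
  # initial letter is h/w (then nothing is dropped for it)
  if (digits[1L] != "") d <- d[-1L]
  d <- d[d != "0"]
  code <- paste0(letters_vec[1L], paste(d, collapse = ""))
  substr(paste0(code, "000"), 1L, 4L)
}

#' Substring-prefix encoding
#'
#' Returns the first `k` characters of the value (fewer when the value is
#' shorter). The least restrictive of the key encodings: two values share a
#' code whenever they agree on their first `k` characters. Operates on the
#' normalised value as-is, so digits in fields such as postcode are kept.
#'
#' @param x character vector
#' @param k positive integer prefix length
#' @return character vector of prefixes
#' @export
substring_prefix <- function(x, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  substr(as.character(x), 1L, as.integer(k))
}

#' Indexing-key specification
#'
#' Describes how the blocking/sorting key value of a record is built: one
#' field gives a single key, two or more give a composite key. Each field
#' value is encoded separately and the encodings are concatenated in field
#' order (a separator can be supplied to avoid rare cross-field collisions
#' with variable-length substring codes).
#'
#' @param fields character vector of schema field names, in key order
#' @param encoder `"soundex"` or `"substring"`
#' @param prefix_len prefix length for the substring encoder (default 4)
#' @param separator string placed between per-field encodings (default `""`)
#' @return a `key_spec` object
#' @export
key_spec <- function(fields, encoder = c("substring", "soundex"),
                     prefix_len = 4L, separator = "") {
  encoder <- match.arg(encoder)
  stopifnot(is.character(fields), length(fields) >= 1L,
            all(nzchar(fields)), prefix_len >= 1L)
  structure(list(fields = fields, encoder = encoder,
                 prefix_len = as.integer(prefix_len), separator = separator),
            class = "key_spec")
}

#' @export
print.key_spec <- function(x, ...) {
  enc <- if (x$encoder == "substring")
    paste0("substring-", x$prefix_len) else "soundex"
  cat("key_spec:", paste(x$fields, collapse = " + "), "via", enc, "\n")
  invisible(x)
}

encode_field <- function(values, spec) {
  switch(spec$encoder,
         soundex = soundex(values),
         substring = substring_prefix(values, spec$prefix_len))
}

#' Build indexing-key values for every record
#'
#' Applies the key specification to a dataset: each constituent field is
#' encoded and the encodings concatenated in order. A record whose key
#' fields are all missing gets an empty key and takes no part in that
#' indexing pass (see [build_index()]).
#'
#' @param ds a `dedup_dataset`
#' @param spec a [key_spec]
#' @return character vector of key values, one per record, named by `rec_id`
#' @export
build_keys <- function(ds, spec) {
  stopifnot(inherits(ds, "dedup_dataset"), inherits(spec, "key_spec"))
  unknown <- setdiff(spec$fields, attr(ds, "schema"))
  if (length(unknown) > 0L)
    stop("spec error: unknown key field(s): ", paste(unknown, collapse = ", "))
  parts <- lapply(spec$fields, function(f) encode_field(ds[[f]], spec))
  all_missing <- Reduce(`&`, lapply(spec$fields,
                                    function(f) !nzchar(ds[[f]])))
  keys <- do.call(paste, c(parts, sep = spec$separator))
  keys[all_missing] <- ""
  names(keys) <- ds$rec_id
  keys
}
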