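#' The default person-record schema
#'
#' Twelve string fields commonly used in synthetic person datasets for
#' de-duplication benchmarks. Every dataset additionally carries a unique
#' `rec_id` column, which is not part of the schema itself.
#'
#' @return character vector of the 12 field names
#' @export
febrl_schema <- function() {
  c("given_name", "surname", "street_number", "address_1", "address_2",
    "suburb", "postcode", "state", "date_of_birth", "age", "phone_number",
    "soc_sec_id")
}

normalise_values <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  x[is.na(x)] <- ""
  x
}

new_dataset <- function(df, schema) {
  stopifnot(is.data.frame(df), "rec_id" %in% names(df))
  df <- df[, c("rec_id", schema), drop = FALSE]
  df$rec_id <- as.character(df$rec_id)
  rownames(df) <- NULL
  structure(df, schema = schema, class = c("dedup_dataset", "data.frame"))
}

#' Read a person-record CSV dataset
#'
#' Reads a comma-separated file with a header row containing `rec_id` plus
#' the schema fields (RFC 4180 quoting handled by the base reader). All
#' values are normalised on load: lower-cased, outer whitespace stripped,
#' internal whitespace runs collapsed to a single space; missing cells become
#' empty strings.
#'
#' @param path path to a CSV file
#' @param schema character vector of field names expected in the header
#'   (default [febrl_schema()])
#' @return a `dedup_dataset`: a data frame with columns `rec_id` and the
#'   schema fields (all character), with a `schema` attribute
#' @export
read_dataset <- function(path, schema = febrl_schema()) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  if (!"rec_id" %in% names(df))
    stop("format error: no 'rec_id' column in ", path)
  missing_fields <- setdiff(schema, names(df))
  if (length(missing_fields) > 0L)
    stop("format error: schema fields absent from header: ",
         paste(missing_fields, collapse = ", "))
  df$rec_id <- trimws(df$rec_id)
  if (anyDuplicated(df$rec_id))
    stop("integrity error: duplicate rec_id values, e.g. ",
         df$rec_id[duplicated(df$rec_id)][1L])
  for (f in schema) df[[f]] <- normalise_values(df[[f]])
  new_dataset(df, schema)
}

#' Write a dataset back to CSV
#'
#' @param ds a `dedup_dataset`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "dedup_dataset"))
  utils::write.csv(as.data.frame(unclass(ds), stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.dedup_dataset <- function(x, ...) {
  cat("dedup_dataset:", nrow(x), "records,",
      length(attr(x, "schema")), "fields + rec_id\n")
  print(utils::head(as.data.frame(unclass(x)), 4L))
  invisible(x)
}

#' Derive the gold standard from record-id naming conventions
#'
#' Synthetic de-duplication benchmarks name records `rec-<entity>-org` for
#' originals and `rec-<entity>-dup-<k>` for the k-th duplicate of that
#' entity. Two records are a true match iff they share `<entity>`. When a
#' dataset does not follow this convention an explicit mapping can be given
#' via [gold_from_mapping()].
#'
#' @param ds a `dedup_dataset` whose `rec_id`s all match
#'   `rec-<entity>-org` / `rec-<entity>-dup-<k>`
#' @return a `gold_standard`: list with `entity_of` (named character vector,
#'   rec_id -> entity id) and `true_match_pairs` (a [pair_set] of all
#'   within-entity unordered pairs)
#' @export
derive_gold_standard <- function(ds) {
  stopifnot(inherits(ds, "dedup_dataset"))
  ids <- ds$rec_id
  pat <- "^rec-(.+)-(org|dup-[0-9]+)$"
  bad <- !grepl(pat, ids)
  if (any(bad))
    stop("convention error: rec_id does not match rec-<entity>-org/",
         "rec-<entity>-dup-<k>: ", ids[bad][1L],
         " (supply a mapping via gold_from_mapping() instead)")
  entity <- sub(pat, "\\1", ids)
  names(entity) <- ids
  gold_from_mapping(data.frame(rec_id = ids, entity_id = entity,
                               stringsAsFactors = FALSE))
}

#' Build a gold standard from an explicit rec_id -> entity mapping
#'
#' @param mapping data frame with columns `rec_id` and `entity_id`
#' @return a `gold_standard` (see [derive_gold_standard()])
#' @export
gold_from_mapping <- function(mapping) {
  stopifnot(is.data.frame(mapping),
            all(c("rec_id", "entity_id") %in% names(mapping)))
  entity <- as.character(mapping$entity_id)
  names(entity) <- as.character(mapping$rec_id)
  if (anyDuplicated(names(entity)))
    stop("integrity error: duplicate rec_id in mapping")
  groups <- split(names(entity), entity)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) > 0L) {
    sets <- lapply(groups, all_pairs)
    tmp <- do.call(pair_union, sets)
  } else {
    tmp <- pair_set()
  }
  structure(list(entity_of = entity, true_match_pairs = tmp),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard:", length(x$entity_of), "records,",
      length(unique(x$entity_of)), "entities,",
      n_pairs(x$true_match_pairs), "true matching pairs\n")
  invisible(x)
}

#' Read or write a gold standard as a two-column CSV
#'
#' @param gold a `gold_standard`
#' @param path CSV path with columns `rec_id,entity_id`
#' @return `write_gold_standard` returns `path` invisibly;
#'   `read_gold_standard` returns a `gold_standard`
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  utils::write.csv(data.frame(rec_id = names(gold$entity_of),
                              entity_id = unname(gold$entity_of)),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_gold_standard
#' @export
read_gold_standard <- function(path) {
  gold_from_mapping(utils::read.csv(path, colClasses = "character"))
}

#' Write candidate pairs (optionally with scores and classes) to CSV
#'
#' @param pairs a [pair_set], or a data frame with columns
#'   `id_a,id_b[,score,class]` as produced by [classify_pairs()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_pairs <- function(pairs, path) {
  df <- if (inherits(pairs, "pair_set")) as.data.frame(pairs) else pairs
  stopifnot(is.data.frame(df), all(c("id_a", "id_b") %in% names(df)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
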