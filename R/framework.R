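#' Framework configuration
#'
#' Settings for the three-phase de-duplication pipeline: composite-key
#' blocking (CKB), two-pass multipass blocking (MPB), then two-pass
#' multipass windowing (MPW) with a small window. The phases share one
#' compared-pair cache so no pair is scored twice, and records resolved as
#' duplicates by the blocking phases can be removed before windowing.
#'
#' @param encoder `"substring"` (default, the least restrictive choice) or
#'   `"soundex"`
#' @param prefix_len substring prefix length (default 4)
#' @param ckb_fields fields of the composite blocking key
#'   (default `given_name + surname`)
#' @param mpb_pass_fields list of field vectors, one per blocking pass
#'   (default one pass on `given_name`, one on `surname`)
#' @param mpw_pass_fields list of field vectors, one per windowing pass
#'   (default as MPB)
#' @param window_size sliding-window size in buckets (default 3; small
#'   windows suffice once the blocking phases have cleaned the data)
#' @param th a [thresholds] object
#' @param rules list of [field_rule]; `NULL` means [default_rules()] keyed to
#'   `encoder`
#' @param cross_phase_cache skip pairs already compared in an earlier phase
#'   (default `TRUE`)
#' @param remove_matched_records before windowing, drop every record that is
#'   a non-representative member of a resolved duplicate cluster
#'   (default `TRUE`)
#' @param empty_key_bucket pool empty-key records (see [build_index()])
#' @return a `framework_config` object
#' @export
framework_config <- function(encoder = c("substring", "soundex"),
                             prefix_len = 4L,
                             ckb_fields = c("given_name", "surname"),
                             mpb_pass_fields = list("given_name", "surname"),
                             mpw_pass_fields = list("given_name", "surname"),
                             window_size = 3L,
                             th = thresholds(),
                             rules = NULL,
                             cross_phase_cache = TRUE,
                             remove_matched_records = TRUE,
                             empty_key_bucket = FALSE) {
  encoder <- match.arg(encoder)
  stopifnot(window_size >= 1, length(ckb_fields) >= 1,
            is.list(mpb_pass_fields), is.list(mpw_pass_fields),
            inherits(th, "thresholds"))
  if (is.null(rules))
    rules <- default_rules(encoding = encoder, prefix_len = prefix_len)
  structure(list(encoder = encoder, prefix_len = as.integer(prefix_len),
                 ckb_fields = ckb_fields,
                 mpb_pass_fields = mpb_pass_fields,
                 mpw_pass_fields = mpw_pass_fields,
                 window_size = as.integer(window_size),
                 th = th, rules = rules,
                 cross_phase_cache = isTRUE(cross_phase_cache),
                 remove_matched_records = isTRUE(remove_matched_records),
                 empty_key_bucket = isTRUE(empty_key_bucket)),
            class = "framework_config")
}

#' Read a framework configuration from a YAML file
#'
#' Recognised keys mirror [framework_config()] arguments; `t_lower` /
#' `t_upper` set the thresholds. Unknown keys raise an error.
#'
#' @param path YAML file path
#' @return a `framework_config`
#' @export
read_framework_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("encoder", "prefix_len", "ckb_fields", "mpb_pass_fields",
             "mpw_pass_fields", "window_size", "t_lower", "t_upper",
             "cross_phase_cache", "remove_matched_records",
             "empty_key_bucket")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("spec error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), c("encoder", "prefix_len", "ckb_fields",
                                      "window_size", "cross_phase_cache",
                                      "remove_matched_records",
                                      "empty_key_bucket"))]
  if (!is.null(raw$mpb_pass_fields))
    args$mpb_pass_fields <- as.list(raw$mpb_pass_fields)
  if (!is.null(raw$mpw_pass_fields))
    args$mpw_pass_fields <- as.list(raw$mpw_pass_fields)
  if (!is.null(raw$t_lower) || !is.null(raw$t_upper))
    args$th <- thresholds(raw$t_lower %||% 0.5, raw$t_upper %||% 0.75)
  do.call(framework_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transitive closure of a match set into duplicate clusters
#'
#' Connected components of the match graph: every record mentioned in a
#' match pair belongs to exactly one cluster.
#'
#' @param matches a [pair_set] of matched pairs
#' @return list of character vectors (each sorted), one per cluster of
#'   size >= 2
#' @export
transitive_clusters <- function(matches) {
  stopifnot(inherits(matches, "pair_set"))
  if (n_pairs(matches) == 0L) return(list())
  g <- igraph::graph_from_edgelist(unclass(matches)[, 1:2, drop = FALSE],
                                   directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  unname(lapply(members, function(v) sort(v)))
}

phase_row <- function(name, generated, new_compared, matches_found) {
  data.frame(phase = name, pairs_generated = generated,
             new_pairs_compared = new_compared,
             matches_found = matches_found, stringsAsFactors = FALSE)
}

#' Run the full blocking-then-windowing de-duplication framework
#'
#' Executes the three phases in succession on one dataset:
#'
#' 1. **CKB** — one inverted index on the composite key, within-block pairs
#'    compared and classified.
#' 2. **MPB** — one single-key blocking pass per `mpb_pass_fields` entry,
#'    candidate union taken; with the cross-phase cache on, pairs already
#'    compared in phase 1 are not compared again.
#' 3. **MPW** — optionally drop every non-representative member of the
#'    duplicate clusters resolved so far (representative = lexicographically
#'    smallest rec_id in the cluster's transitive closure), then one
#'    sorted-neighbourhood windowing pass per `mpw_pass_fields` entry with
#'    window `window_size`, union, uncached pairs compared and classified.
#'
#' The final match set is the union of the per-phase match sets.
#'
#' @param ds a `dedup_dataset`
#' @param cfg a [framework_config]
#' @param gold optional `gold_standard`; when given, evaluation metrics are
#'   computed for the whole run
#' @return list of class `framework_result` with `classification`
#'   (final [pair_set]s `matches` / `possible_matches`), `phase_reports`
#'   (data frame, one row per phase plus a total row), `compared`
#'   ([pair_set] of every pair scored), `scores` (combined score frame) and,
#'   when `gold` is given, `evaluation` (see [evaluate_run()])
#' @export
run_framework <- function(ds, cfg = framework_config(), gold = NULL) {
  stopifnot(inherits(ds, "dedup_dataset"), inherits(cfg, "framework_config"))
  key_for <- function(fields) key_spec(fields, encoder = cfg$encoder,
                                       prefix_len = cfg$prefix_len)
  compared <- pair_set()     # global compared-pair cache
  matches <- pair_set()
  possibles <- pair_set()
  score_frames <- list()
  reports <- list()

  run_phase <- function(name, cands, data) {
    new <- if (cfg$cross_phase_cache) pair_diff(cands, compared) else cands
    cl <- classify_pairs(new, data, cfg$rules, cfg$th)
    compared <<- pair_union(compared, new)
    matches <<- pair_union(matches, cl$matches)
    possibles <<- pair_union(possibles, cl$possible_matches)
    score_frames[[length(score_frames) + 1L]] <<- cl$scores
    reports[[length(reports) + 1L]] <<-
      phase_row(name, n_pairs(cands), n_pairs(new), n_pairs(cl$matches))
  }

  # phase 1: composite-key blocking
  ix <- build_index(ds, key_for(cfg$ckb_fields), cfg$empty_key_bucket)
  run_phase("CKB", block_pairs(ix), ds)

  # phase 2: multipass blocking
  mpb_sets <- lapply(cfg$mpb_pass_fields, function(fields)
    block_pairs(build_index(ds, key_for(fields), cfg$empty_key_bucket)))
  run_phase("MPB", multipass_union(mpb_sets), ds)

  # phase 3: multipass windowing on the (optionally reduced) dataset
  ds_w <- ds
  if (cfg$remove_matched_records && n_pairs(matches) > 0L) {
    drop_ids <- unlist(lapply(transitive_clusters(matches),
                              function(cl) cl[-1L]))
    ds_w <- new_dataset(ds[!(ds$rec_id %in% drop_ids), , drop = FALSE],
                        attr(ds, "schema"))
  }
  mpw_sets <- lapply(cfg$mpw_pass_fields, function(fields)
    window_pairs(build_index(ds_w, key_for(fields), cfg$empty_key_bucket),
                 cfg$window_size))
  run_phase("MPW", multipass_union(mpw_sets), ds_w)

  phase_reports <- do.call(rbind, reports)
  phase_reports <- rbind(phase_reports,
                         phase_row("Total",
                                   sum(phase_reports$pairs_generated),
                                   sum(phase_reports$new_pairs_compared),
                                   sum(phase_reports$matches_found)))
  possibles <- pair_diff(possibles, matches)
  res <- list(classification = list(matches = matches,
                                    possible_matches = possibles),
              phase_reports = phase_reports,
              compared = compared,
              scores = do.call(rbind, score_frames))
  if (!is.null(gold)) {
    stopifnot(inherits(gold, "gold_standard"))
    res$evaluation <- evaluate_run(matches, n_pairs(compared), gold,
                                   nrow(ds))
  }
  structure(res, class = "framework_result")
}

#' @export
print.framework_result <- function(x, ...) {
  cat("framework_result\n")
  print(x$phase_reports, row.names = FALSE)
  cat("final:", n_pairs(x$classification$matches), "matches,",
      n_pairs(x$classification$possible_matches), "possible matches\n")
  if (!is.null(x$evaluation)) print(x$evaluation$metrics)
  invisible(x)
}

#' Write per-phase reports and final pairs for a framework run
#'
#' @param result a `framework_result`
#' @param dir output directory (created if needed); writes
#'   `phase_report.csv`, `matches.csv` and `possible_matches.csv`
#' @return `dir`, invisibly
#' @export
write_framework_report <- function(result, dir) {
  stopifnot(inherits(result, "framework_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$phase_reports,
                   file.path(dir, "phase_report.csv"), row.names = FALSE)
  sc <- result$scores
  keep <- sc$class != "non_match"
  out <- sc[keep, c("id_a", "id_b", "F", "class")]
  names(out)[3L] <- "score"
  write_pairs(out[out$class == "match", ], file.path(dir, "matches.csv"))
  write_pairs(out[out$class == "possible", ],
              file.path(dir, "possible_matches.csv"))
  invisible(dir)
}
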