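test_that("transitive closure of the match graph gives duplicate clusters", {
  expect_equal(transitive_clusters(pair_set(c("a", "b"), c("b", "c"))),
               list(c("a", "b", "c")))
  expect_equal(transitive_clusters(pair_set()), list())
  two <- transitive_clusters(pair_set(c("a", "c"), c("b", "d")))
  expect_equal(lengths(two), c(2L, 2L))
})

test_that("a clean dataset yields no comparisons and no matches", {
  ds <- tiny_dataset(sprintf("rec-%d-org", 1:6),
                     given_name = c("anna", "bert", "carl", "dora", "evan",
                                    "fred"),
                     surname = c("reid", "shaw", "tate", "ulm", "vane",
                                 "webb"))
  res <- run_framework(ds, framework_config(encoder = "substring"))
  expect_equal(res$phase_reports$new_pairs_compared[
    res$phase_reports$phase == "CKB"], 0)
  expect_equal(n_pairs(res$classification$matches), 0L)
})

test_that("cross-phase cache means no pair is compared twice", {
  out <- generate_dataset(generator_config(60, 45, 3, 3, 2, seed = 8))
  res <- run_framework(out$dataset, framework_config(encoder = "substring"))
  rep <- res$phase_reports
  phases <- rep[rep$phase != "Total", ]
  expect_true(all(phases$new_pairs_compared <= phases$pairs_generated))
  # sum of new pairs over phases = size of the global compared cache
  expect_equal(sum(phases$new_pairs_compared), n_pairs(res$compared))
  # the score log holds each unordered pair at most once
  keys <- paste(res$scores$id_a, res$scores$id_b)
  expect_equal(anyDuplicated(keys), 0L)
  # total row is the sum of the phases
  expect_equal(rep$pairs_generated[rep$phase == "Total"],
               sum(phases$pairs_generated))
})

test_that("the framework finds at least what composite blocking finds alone", {
  out <- generate_dataset(generator_config(60, 45, 3, 3, 2, seed = 8))
  cfg <- framework_config(encoder = "substring")
  res <- run_framework(out$dataset, cfg, out$gold)
  ckb <- classify_pairs(
    block_pairs(build_index(out$dataset,
                            key_spec(cfg$ckb_fields, "substring", 4))),
    out$dataset, cfg$rules, cfg$th)
  expect_gte(n_pairs(res$classification$matches), n_pairs(ckb$matches))
  expect_equal(n_pairs(pair_diff(ckb$matches, res$classification$matches)),
               0L)
})

test_that("disabling cache and removal reproduces standalone phase counts", {
  out <- generate_dataset(generator_config(50, 35, 2, 2, 1, seed = 15))
  ds <- out$dataset
  cfg <- framework_config(encoder = "soundex", cross_phase_cache = FALSE,
                          remove_matched_records = FALSE)
  res <- run_framework(ds, cfg)
  rep <- res$phase_reports
  ks <- function(f) key_spec(f, "soundex")
  ckb <- block_pairs(build_index(ds, ks(c("given_name", "surname"))))
  mpb <- multipass_union(list(block_pairs(build_index(ds, ks("given_name"))),
                              block_pairs(build_index(ds, ks("surname")))))
  mpw <- multipass_union(list(
    window_pairs(build_index(ds, ks("given_name")), 3),
    window_pairs(build_index(ds, ks("surname")), 3)))
  expect_equal(rep$new_pairs_compared[rep$phase == "CKB"], n_pairs(ckb))
  expect_equal(rep$new_pairs_compared[rep$phase == "MPB"], n_pairs(mpb))
  expect_equal(rep$new_pairs_compared[rep$phase == "MPW"], n_pairs(mpw))
})

test_that("framework results round-trip through the report writer", {
  out <- generate_dataset(generator_config(40, 25, 2, 2, 1, seed = 2))
  res <- run_framework(out$dataset, framework_config(), out$gold)
  dir <- withr::local_tempdir()
  write_framework_report(res, dir)
  rep <- utils::read.csv(file.path(dir, "phase_report.csv"))
  expect_equal(nrow(rep), 4L)
  matches <- utils::read.csv(file.path(dir, "matches.csv"))
  expect_equal(nrow(matches), n_pairs(res$classification$matches))
})

test_that("a YAML config maps onto the framework configuration", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("encoder: soundex", "window_size: 6", "t_lower: 0.4",
               "t_upper: 0.9", "remove_matched_records: false",
               "mpb_pass_fields: [given_name, postcode]"), tmp)
  cfg <- read_framework_config(tmp)
  expect_equal(cfg$encoder, "soundex")
  expect_equal(cfg$window_size, 6L)
  expect_equal(cfg$th$t_upper, 0.9)
  expect_false(cfg$remove_matched_records)
  expect_equal(cfg$mpb_pass_fields, list("given_name", "postcode"))
  writeLines("banana: 1", tmp)
  expect_error(read_framework_config(tmp), "unknown config key")
})
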