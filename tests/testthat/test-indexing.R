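test_that("inverted index buckets records by key and drops empty keys", {
  ds <- tiny_dataset(c("r1", "r2", "r3"), given_name = c("ann", "ann", "bob"))
  ix <- build_index(ds, key_spec("given_name", "substring", 4))
  expect_equal(ix$b, 2L)
  expect_equal(sort(unname(lengths(ix$buckets))), c(1L, 2L))
  expect_equal(ix$keys, sort(ix$keys, method = "radix"))

  ds2 <- tiny_dataset(c("r1", "r2", "r3"), given_name = c("ann", "", "ann"))
  ix2 <- build_index(ds2, key_spec("given_name", "substring", 4))
  expect_equal(ix2$b, 1L)
  expect_equal(unname(lengths(ix2$buckets)), 2L)
  ix2p <- build_index(ds2, key_spec("given_name", "substring", 4),
                      empty_key_bucket = TRUE)
  expect_equal(ix2p$b, 2L)

  # all keys distinct -> n singleton buckets
  ds3 <- tiny_dataset(paste0("r", 1:4),
                      given_name = c("ann", "bob", "cat", "dan"))
  ix3 <- build_index(ds3, key_spec("given_name", "substring", 4))
  expect_equal(ix3$b, 4L)
  expect_equal(n_pairs(block_pairs(ix3)), 0L)
})

test_that("blocking pairs are the within-bucket pairs", {
  ix <- index_from_keys(c(r1 = "a", r2 = "a", r3 = "b"))
  expect_equal(as.data.frame(block_pairs(ix)),
               data.frame(id_a = "r1", id_b = "r2"))
  # one bucket of size 5 -> C(5,2) = 10 pairs
  expect_equal(n_pairs(block_pairs(uniform_index(1L, 5L))), 10L)
})

test_that("windowing pairs cover runs of w adjacent buckets", {
  keys <- c(r1 = "a", r2 = "a", r3 = "b", r4 = "c")
  ix <- index_from_keys(keys)
  got <- window_pairs(ix, 2)
  expect_equal(n_pairs(got), 4L)
  expect_equal(as.data.frame(got),
               data.frame(id_a = c("r1", "r1", "r2", "r3"),
                          id_b = c("r2", "r3", "r3", "r4")))
  # w = 1 degenerates to blocking
  expect_equal(window_pairs(ix, 1), block_pairs(ix))
  # window wider than the bucket count -> one window over everything
  wide <- index_from_keys(c(r1 = "a", r2 = "a", r3 = "b"))
  expect_equal(n_pairs(window_pairs(wide, 5)), choose(3, 2))
})

test_that("window pairs grow monotonically with window size", {
  set.seed(9)
  keys <- sample(paste0("k", 1:8), 30, replace = TRUE)
  names(keys) <- paste0("r", 1:30)
  ix <- index_from_keys(keys)
  prev <- window_pairs(ix, 1)
  for (w in 2:8) {
    cur <- window_pairs(ix, w)
    expect_equal(n_pairs(pair_diff(prev, cur)), 0L)
    prev <- cur
  }
})

test_that("multipass union deduplicates across passes", {
  p12 <- pair_set("r1", "r2")
  p23 <- pair_set("r2", "r3")
  expect_equal(n_pairs(multipass_union(list(p12, p23))), 2L)
  expect_equal(n_pairs(multipass_union(list(p12, p12))), 1L)
})

test_that("composite-key blocking never generates more pairs than either key", {
  out <- generate_dataset(generator_config(80, 60, 3, 3, 2, seed = 21))
  ds <- out$dataset
  comp <- block_pairs(build_index(ds, key_spec(c("given_name", "surname"),
                                               "soundex")))
  single1 <- block_pairs(build_index(ds, key_spec("given_name", "soundex")))
  single2 <- block_pairs(build_index(ds, key_spec("surname", "soundex")))
  expect_equal(n_pairs(pair_diff(comp, single1)), 0L)
  expect_equal(n_pairs(pair_diff(comp, single2)), 0L)
})

test_that("comparison-count estimators reproduce the worked values", {
  expect_equal(est_block_comparisons(1000, 1), 499500)
  expect_equal(est_block_comparisons(100, 10), 450)
  expect_equal(est_block_comparisons(50, 50), 0)
  expect_equal(est_skb_comparisons(1000, 10), 49500)
  expect_equal(est_ckb_comparisons(1000, 10, 4), 24500)
  expect_equal(est_mpb_comparisons(1000, 10, 10), 99000)
  expect_equal(est_window_comparisons(100, 10, 2), 1350)
  expect_equal(est_window_comparisons(100, 10, 10), choose(100, 2))
  for (b in c(1, 5, 20)) {
    expect_equal(est_window_comparisons(100, b, 1),
                 est_block_comparisons(100, b))
  }
})
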