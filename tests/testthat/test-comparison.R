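test_that("edit-distance similarity is normalised Levenshtein", {
  expect_equal(edit_distance_sim("abc", "abc"), 1)
  expect_equal(edit_distance_sim("peter", "pedro"), 0.4)  # distance 3 / 5
  expect_equal(edit_distance_sim("abc", ""), 0)
  expect_equal(edit_distance_sim("", ""), 0)
  expect_equal(edit_distance_sim(c("abc", "ab"), c("abd", "ab")), c(2/3, 1))
})

test_that("q-gram similarity counts shared grams over the average count", {
  expect_equal(qgram_sim("peter", "peter"), 1)
  expect_equal(qgram_sim("peter", "pedro"), 0.25)  # {pe} of 4 average
  expect_equal(qgram_sim("ab", "cd"), 0)
  expect_equal(qgram_sim("a", "abc"), 0)   # no bigrams on one side
  # repeated grams are counted as multisets
  expect_equal(qgram_sim("aaa", "aaaa"), 2 / 2.5)
})

test_that("encoded exact-agreement comparators give 0/1", {
  expect_equal(soundex_exact_sim("smith", "smyth"), 1)
  expect_equal(soundex_exact_sim("smith", "jones"), 0)
  expect_equal(soundex_exact_sim("", "smith"), 0)
  expect_equal(substring_exact_sim("peters", "peterson", 4), 1)
  expect_equal(substring_exact_sim("peters", "pedros", 4), 0)
  expect_equal(substring_exact_sim("", "", 4), 0)
})

test_that("comparators and the aggregate are symmetric and in [0, 1]", {
  set.seed(4)
  vals <- replicate(40, paste(sample(letters[1:6], sample(0:7, 1),
                                     replace = TRUE), collapse = ""))
  a <- sample(vals, 30, replace = TRUE)
  b <- sample(vals, 30, replace = TRUE)
  for (f in list(edit_distance_sim, qgram_sim, soundex_exact_sim,
                 function(x, y) substring_exact_sim(x, y, 3))) {
    sab <- f(a, b)
    expect_equal(sab, f(b, a))
    expect_true(all(sab >= 0 & sab <= 1))
  }
})

test_that("compare_pairs builds the weight vector and aggregate F", {
  fields <- c("given_name", "surname", "suburb", "state", "postcode")
  rules <- lapply(fields, field_rule, comparator = "edit_distance")
  # values chosen so per-field sims are 1, 1, 0.5, 0, 1
  ds <- tiny_dataset(c("r1", "r2"),
                     given_name = c("anna", "anna"),
                     surname = c("reid", "reid"),
                     suburb = c("ab", "aa"),
                     state = c("xx", "yy"),
                     postcode = c("2000", "2000"))
  wv <- compare_pairs(pair_set("r1", "r2"), ds, rules)
  expect_equal(unname(unlist(wv[1, paste0("sim_", fields)])),
               c(1, 1, 0.5, 0, 1))
  expect_equal(wv$F, 0.7)

  # identical records -> F = 1; fully disjoint -> F = 0
  ds_eq <- tiny_dataset(c("r1", "r2"),
                        given_name = c("anna", "anna"),
                        surname = c("reid", "reid"),
                        suburb = c("ab", "ab"),
                        state = c("xx", "xx"),
                        postcode = c("2000", "2000"))
  expect_equal(compare_pairs(pair_set("r1", "r2"), ds_eq, rules)$F, 1)
  ds_ne <- tiny_dataset(c("r1", "r2"),
                        given_name = c("aa", "bb"), surname = c("cc", "dd"),
                        suburb = c("ee", "ff"), state = c("gg", "hh"),
                        postcode = c("11", "22"))
  expect_equal(compare_pairs(pair_set("r1", "r2"), ds_ne, rules)$F, 0)
})

test_that("weights and the missing-value rule shape the aggregate", {
  rules <- list(field_rule("given_name", "edit_distance", weight = 3),
                field_rule("surname", "edit_distance", weight = 1))
  ds <- tiny_dataset(c("r1", "r2"),
                     given_name = c("anna", "anna"), surname = c("x", ""))
  wv <- compare_pairs(pair_set("r1", "r2"), ds, rules)
  expect_equal(wv$F, 3 / 4)  # missing surname scores 0 but keeps its weight
  wv2 <- compare_pairs(pair_set("r1", "r2"), ds, rules,
                       missing_ignore = TRUE)
  expect_equal(wv2$F, 1)     # missing field dropped from the mean

  expect_error(compare_pairs(pair_set("r1", "r2"), ds, list()),
               "spec error")
  expect_error(compare_pairs(pair_set("r1", "zz"), ds, rules),
               "integrity error")
})

test_that("default rules follow the encoding choice for name fields", {
  sdx <- default_rules("soundex")
  expect_length(sdx, 5L)
  expect_setequal(vapply(sdx, `[[`, "", "field"),
                  c("postcode", "address_1", "soc_sec_id",
                    "given_name", "surname"))
  name_cmp <- vapply(sdx[4:5], `[[`, "", "comparator")
  expect_true(all(name_cmp == "soundex_exact"))
  sub <- default_rules("substring", prefix_len = 3)
  expect_true(all(vapply(sub[4:5], `[[`, "", "comparator") ==
                    "substring_exact"))
  both <- default_rules("both")
  expect_length(both, 7L)
})
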