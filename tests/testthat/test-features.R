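test_that("the registry fixes order, dimension and naming", {
  reg <- feature_registry(phrases = 1:21)
  expect_equal(nrow(reg), 56 * 21)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(reg$phrase_id, rep(1:21, each = 56))
  reg3 <- feature_registry(phrases = c(2, 5, 9))
  expect_equal(nrow(reg3), 56 * 3)
  expect_match(reg3$name[1], "__phrase02$")
})

test_that("feature extraction is deterministic and registry-shaped", {
  reg <- feature_registry(phrases = c(1, 2))
  recs <- list(quick_voice(seed = 1, duration = 0.4),
               quick_voice(seed = 2, duration = 0.4))
  recs[[1]]$phrase_id <- 1L
  recs[[2]]$phrase_id <- 2L
  v1 <- extract_feature_vector(recs, reg)
  v2 <- extract_feature_vector(recs, reg)
  expect_identical(v1, v2)
  expect_equal(names(v1), reg$name)
  expect_equal(length(v1), nrow(reg))
})

test_that("an absent phrase leaves exactly its block missing", {
  reg <- feature_registry(phrases = c(1, 2, 3))
  rec <- quick_voice(seed = 1, duration = 0.4)
  rec$phrase_id <- 2L
  v <- extract_feature_vector(list(rec), reg)
  expect_true(all(is.na(v[reg$phrase_id != 2])))
  expect_true(mean(is.na(v[reg$phrase_id == 2])) < 0.2)
})

test_that("unknown and duplicate phrase ids are rejected", {
  reg <- feature_registry(phrases = c(1, 2))
  rec <- quick_voice(seed = 1, duration = 0.4)
  rec$phrase_id <- 9L
  expect_error(extract_feature_vector(list(rec), reg), "unknown phrase")
  r1 <- quick_voice(seed = 1, duration = 0.4)
  r1$phrase_id <- 1L
  expect_error(extract_feature_vector(list(r1, r1), reg), "duplicate")
})

test_that("a feature table has one registry-ordered row per subject", {
  cfg <- cohort_config(n_per_group = 2, phrases = c(1, 18),
                       duration_s = 0.4, acoustic_effect = 1)
  ds <- generate_cohort_dataset(cfg, seed = 4)
  ft <- extract_feature_table(ds)
  reg <- feature_registry(c(1, 18))
  expect_equal(nrow(ft), 4)
  expect_equal(names(ft), c("subject_id", reg$name))
  num <- as.matrix(ft[, -1])
  expect_true(mean(is.finite(num)) > 0.8)
})
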