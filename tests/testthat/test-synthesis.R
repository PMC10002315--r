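test_that("synthesized recording honours length and normalization contract", {
  rec <- quick_voice(duration = 1.0, seed = 1)
  expect_length(rec$samples, 11025)
  expect_true(all(is.finite(rec$samples)))
  expect_true(max(abs(rec$samples)) <= 1)
})

test_that("synthesis is a pure function of its arguments", {
  a <- quick_voice(seed = 7, jitter = 2, shimmer = 2, snr = 15)
  b <- quick_voice(seed = 7, jitter = 2, shimmer = 2, snr = 15)
  expect_identical(a$samples, b$samples)
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(a$samples, a$rate, p1)
  write_wav(b$samples, b$rate, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a noiseless, jitterless voice is periodic at its F0", {
  # 105 Hz at 11025 Hz gives an exact 105-sample period
  rec <- quick_voice(f0 = 105, seed = 2)
  x <- rec$samples
  l <- 105
  r <- cor(x[1:(length(x) - l)], x[(l + 1):length(x)])
  expect_gt(r, 0.99)
})

test_that("invalid synthesis parameters are rejected", {
  expect_error(glottal_params(open_quotient = 1.2), "open_quotient")
  expect_error(glottal_params(f0_mean = -5), "f0_mean")
  expect_error(glottal_params(jitter_pct = -1), "non-negative")
  expect_error(formant_spec(c(500, 400, 900, 1000, 2000), rep(100, 5)),
               "increasing")
  expect_error(formant_spec(700, -10), "positive")
  expect_error(quick_voice(duration = 0), "duration")
  expect_error(
    synthesize_voice(glottal_params(), formant_spec(c(500, 6000), c(80, 80)),
                     rate = 11025),
    "Nyquist"
  )
})

test_that("generated HAM-D records always satisfy the scale invariants", {
  rng <- hamd_item_ranges()
  for (seed in 1:3) {
    ch <- generate_hamd_cohort(15, seed = seed)
    for (r in ch$records) {
      expect_equal(r$total, sum(r$items))
      expect_true(all(r$items >= rng[, "min"] & r$items <= rng[, "max"]))
    }
    expect_setequal(names(ch$true_group),
                    vapply(ch$records, `[[`, "", "subject_id"))
  }
})

test_that("identical profiles give no systematic group differences", {
  pr <- default_symptom_profiles(0)
  ch <- generate_hamd_cohort(200, profiles = list(pr[[1]], pr[[1]]), seed = 5)
  df <- hamd_to_df(ch$records)
  g <- ch$true_group[df$subject_id]
  n_out2 <- 0L
  for (i in 1:17) {
    v <- df[[paste0("item_", i)]]
    se <- sqrt(var(v[g == 1]) / sum(g == 1) + var(v[g == 2]) / sum(g == 2))
    d <- abs(mean(v[g == 1]) - mean(v[g == 2]))
    expect_lt(d, 3 * se + 1e-9)
    if (d >= 2 * se) n_out2 <- n_out2 + 1L
  }
  # at the 2-SE level a few of 17 null items may stray by chance
  expect_lte(n_out2, 2L)
})

test_that("item 1 / item 7 correlation hits the calibrated target", {
  ch <- generate_hamd_cohort(250, item_corr_target = 0.7, seed = 11)
  df <- hamd_to_df(ch$records)
  expect_lt(abs(cor(df$item_1, df$item_7) - 0.7), 0.1)
})

test_that("cohort dataset counts, linkage and determinism hold", {
  cfg <- cohort_config(n_per_group = 20, phrases = 1:21, duration_s = 0.25)
  ds <- generate_cohort_dataset(cfg, seed = 3)
  expect_length(ds$recordings, 40 * 21)
  expect_length(ds$hamd, 40)
  recs <- subject_recordings(ds, names(ds$true_group)[1])
  expect_length(recs, 21)
  expect_equal(unname(vapply(recs, `[[`, 0L, "phrase_id")), 1:21)

  ds2 <- generate_cohort_dataset(cfg, seed = 3)
  k <- names(ds$recordings)[c(1, 100, 840)]
  for (key in k) {
    expect_identical(ds$recordings[[key]]$samples, ds2$recordings[[key]]$samples)
  }
  expect_identical(hamd_to_df(ds$hamd), hamd_to_df(ds2$hamd))
})

test_that("unknown cohort config keys are an error", {
  expect_error(cohort_config(n_subject = 10), "unknown config keys")
})
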