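test_that("IAIF recovers the glottal flow derivative of a known source", {
  rec <- quick_voice(f0 = 120, seed = 2)
  tru <- synthesis_truth(rec)
  gf <- iaif(rec)
  td <- diff(tru$flow)
  ed <- gf$flow_derivative
  n <- min(length(td), length(ed))
  rng <- 1000:(n - 1100)
  cc <- max(vapply(seq(-110, 110, 2), function(L) {
    cor(td[rng], ed[rng + L])
  }, 0))
  expect_gt(cc, 0.8)
})

test_that("detected glottal cycle rate matches the synthesis F0 within 5%", {
  for (seed in 2:3) {
    rec <- quick_voice(f0 = 120, seed = seed)
    gf <- iaif(rec)
    rate_est <- 1 / mean(diff(gf$cycle_boundaries) / gf$rate)
    expect_lt(abs(rate_est - 120) / 120, 0.05)
  }
})

test_that("fully unvoiced input takes the unvoiced path with no cycles", {
  expect_warning(gf <- iaif(noise_recording(seed = 2)), "voiced")
  expect_false(gf$voiced)
  expect_length(gf$cycle_boundaries, 0)
  expect_error(glottal_quotients(gf), "cycle")
})

test_that("QOQ is within (0, 1] by construction and NAQ positive", {
  rec <- quick_voice(f0 = 120, seed = 3, jitter = 1, shimmer = 1, snr = 20)
  gq <- glottal_quotients(iaif(rec))
  expect_true(all(gq$qoq > 0 & gq$qoq <= 1))
  expect_true(all(gq$naq > 0))
})

test_that("quotients of the ideal pulse match dense numerical evaluation", {
  for (oq in c(0.5, 0.6, 0.7)) {
    oracle <- rosenberg_quotients_oracle(oq)
    gq <- glottal_quotients(ideal_pulse_flow(f0 = 120, oq = oq))
    expect_lt(abs(mean(gq$naq) - oracle$naq) / oracle$naq, 0.05)
    expect_lt(abs(mean(gq$qoq) - oracle$qoq) / oracle$qoq, 0.05)
  }
})

test_that("quotients are invariant to waveform amplitude scaling", {
  a <- glottal_quotients(ideal_pulse_flow(amp = 1))
  b <- glottal_quotients(ideal_pulse_flow(amp = 2))
  expect_equal(a$naq, b$naq, tolerance = 1e-12)
  expect_equal(a$qoq, b$qoq, tolerance = 1e-12)
})

test_that("degenerate cycles are skipped and counted", {
  flow <- rep(0.5, 200)                      # flat flow: no usable cycles
  gf <- glottal_flow(flow, c(1, 100, 199), 11025)
  gq <- glottal_quotients(gf)
  expect_equal(nrow(gq), 0)
  expect_equal(attr(gq, "n_skipped"), 2)
})
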