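# shared fixtures, all generated in code

quick_voice <- function(f0 = 120, seed = 1, duration = 1, jitter = 0,
                        shimmer = 0, snr = Inf, oq = 0.6,
                        tract = formant_spec(), rate = 11025) {
  synthesize_voice(
    glottal_params(f0_mean = f0, jitter_pct = jitter, shimmer_pct = shimmer,
                   noise_snr_db = snr, open_quotient = oq),
    tract, duration = duration, rate = rate, seed = seed
  )
}

sine_recording <- function(freq, duration = 0.5, rate = 11025, amp = 0.5) {
  t <- seq(0, duration, by = 1 / rate)[-1]
  audio_recording(amp * sin(2 * pi * freq * t), rate)
}

noise_recording <- function(duration = 0.5, rate = 11025, seed = 1) {
  withr::with_seed(seed, audio_recording(rnorm(duration * rate, 0, 0.3), rate))
}

# dense numerical evaluation of the closed-form Rosenberg pulse: NAQ and QOQ
# straight from their definitions, independent of the cycle-extraction code
rosenberg_quotients_oracle <- function(open_quotient, rise_fraction = 2 / 3,
                                       n_grid = 200000) {
  ph <- seq(0, 1, length.out = n_grid + 1)[-(n_grid + 1)]
  f <- rosenberg_pulse(ph, open_quotient, rise_fraction)
  d <- diff(f) * n_grid                  # derivative per unit cycle
  app <- max(f) - min(f)
  naq <- app / (abs(min(d)) * 1)         # cycle duration = 1 in phase units
  thr <- min(f) + 0.5 * app
  qoq <- mean(f >= thr)
  list(naq = naq, qoq = qoq)
}

# ideal Rosenberg pulse train as a glottal_flow (no tract, no noise)
ideal_pulse_flow <- function(f0 = 120, oq = 0.6, rate = 11025,
                             duration = 1, amp = 1) {
  t <- (0:(round(duration * rate) - 1)) / rate
  flow <- amp * rosenberg_pulse(t * f0, oq)
  onsets <- seq(0, duration - 1.5 / f0, by = 1 / f0)
  glottal_flow(flow, onsets * rate + 1, rate)
}

# exhaustive best 2-partition under the within-cluster correlation distance
# (distance of each member to its cluster's mean profile)
brute_force_partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (m in 1:(2^(n - 1) - 1)) {
    g <- as.integer(intToBits(m))[1:n] + 1L
    if (length(unique(g)) < 2) next
    cen <- rbind(colMeans(x[g == 1, , drop = FALSE]),
                 colMeans(x[g == 2, , drop = FALSE]))
    d <- 0
    for (i in 1:n) {
      ci <- cen[g[i], ]
      d <- d + (if (sd(x[i, ]) == 0 || sd(ci) == 0) 1 else 1 - cor(x[i, ], ci))
    }
    if (is.null(best) || d < best$objective) best <- list(g = g, objective = d)
  }
  best
}

# gaussian feature table for classifier tests: k informative columns shifted
# by `delta` between groups, rest pure noise
toy_feature_table <- function(n_per_group = 30, n_feat = 20, k = 3,
                              delta = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    x <- matrix(rnorm(n * n_feat), n, n_feat)
    grp <- rep(1:2, each = n_per_group)
    if (k > 0) x[grp == 1, seq_len(k)] <- x[grp == 1, seq_len(k)] + delta
    colnames(x) <- sprintf("feat_%02d__mean__phrase01", seq_len(n_feat))
    ids <- sprintf("S%03d", seq_len(n))
    list(features = cbind(data.frame(subject_id = ids), as.data.frame(x)),
         labels = stats::setNames(grp, ids))
  })
}

# the end-to-end synthetic benchmark: synthesize a cohort, extract features,
# cluster the HAM-D records, cross-validate the classifier on the clustered
# labels; returns the pooled CV accuracy
signal_benchmark <- function(effect, seed, n_per_group = 40,
                             phrases = c(1, 7, 18), duration = 0.6) {
  cfg <- cohort_config(n_per_group = n_per_group, phrases = phrases,
                       duration_s = duration, acoustic_effect = effect,
                       hamd_separation = 2)
  ds <- generate_cohort_dataset(cfg, seed = seed)
  ft <- extract_feature_table(ds)
  cl <- cluster_cohort(ds$hamd, seed = seed)
  keep <- !is.na(cl$assignment)
  cv <- crossvalidate(ft[ft$subject_id %in% names(cl$assignment)[keep], ,
                         drop = FALSE],
                      cl$assignment[keep], seed = seed)
  cv$accuracy
}

adjusted_rand <- function(a, b) {
  # chance-corrected partition agreement from the pair-count contingency
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
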