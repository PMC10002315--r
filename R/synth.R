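#' Glottal source parameters
#'
#' Parameter set for the Rosenberg-pulse voice source: mean and slow-drift
#' standard deviation of the fundamental frequency, open quotient of the
#' glottal cycle, cycle-to-cycle period (jitter) and amplitude (shimmer)
#' perturbations, aspiration-noise level and overall gain.
#'
#' @param f0_mean mean fundamental frequency in Hz (> 0)
#' @param f0_sd standard deviation of the slow F0 drift in Hz (>= 0)
#' @param open_quotient fraction of the cycle the glottis is open, in (0, 1)
#' @param jitter_pct cycle-to-cycle period perturbation, percent (>= 0)
#' @param shimmer_pct cycle-to-cycle amplitude perturbation, percent (>= 0)
#' @param noise_snr_db ratio of periodic source power to aspiration-noise
#'   power in dB; `Inf` disables the noise
#' @param amplitude linear source gain
#' @return a `glottal_params` list
#' @export
glottal_params <- function(f0_mean = 120, f0_sd = 0, open_quotient = 0.6,
                           jitter_pct = 0, shimmer_pct = 0,
                           noise_snr_db = Inf, amplitude = 1) {
  if (!(f0_mean > 0)) stop("f0_mean must be positive")
  if (!(open_quotient > 0 && open_quotient < 1)) {
    stop("open_quotient must lie in (0, 1)")
  }
  if (jitter_pct < 0 || shimmer_pct < 0 || f0_sd < 0) {
    stop("jitter_pct, shimmer_pct and f0_sd must be non-negative")
  }
  structure(list(f0_mean = f0_mean, f0_sd = f0_sd,
                 open_quotient = open_quotient, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, noise_snr_db = noise_snr_db,
                 amplitude = amplitude),
            class = "glottal_params")
}

#' Vocal-tract formant specification
#'
#' Five resonance centre frequencies (strictly increasing) and their
#' bandwidths, realised at synthesis time as a cascade of second-order
#' all-pole resonators.
#'
#' @param centers formant centre frequencies in Hz, strictly increasing
#' @param bandwidths formant bandwidths in Hz, all positive
#' @return a `formant_spec` list
#' @export
formant_spec <- function(centers = c(660, 1200, 2500, 3500, 4800),
                         bandwidths = c(80, 110, 160, 220, 280)) {
  stopifnot(length(centers) == length(bandwidths))
  if (any(diff(centers) <= 0)) stop("formant centers must be strictly increasing")
  if (any(bandwidths <= 0)) stop("formant bandwidths must be positive")
  if (any(centers <= 0)) stop("formant centers must be positive")
  structure(list(centers = as.numeric(centers),
                 bandwidths = as.numeric(bandwidths)),
            class = "formant_spec")
}

#' Rosenberg glottal flow pulse
#'
#' Closed-form Rosenberg (type C) glottal flow evaluated at normalized phase
#' `t` within one cycle: a raised-cosine opening ramp over the first
#' `rise_fraction` of the open phase, a quarter-cosine closing ramp over the
#' remainder, zero during the closed phase. Peak flow is 1.
#'
#' @param t normalized phase in [0, 1) (values outside are wrapped)
#' @param open_quotient open fraction of the cycle, in (0, 1)
#' @param rise_fraction fraction of the open phase spent opening (default 2/3)
#' @return flow values in [0, 1]
#' @export
rosenberg_pulse <- function(t, open_quotient = 0.6, rise_fraction = 2 / 3) {
  stopifnot(open_quotient > 0, open_quotient < 1,
            rise_fraction > 0, rise_fraction < 1)
  ph <- t %% 1
  tp <- open_quotient * rise_fraction
  tn <- open_quotient - tp
  out <- numeric(length(ph))
  rise <- ph < tp
  fall <- !rise & ph < open_quotient
  out[rise] <- 0.5 * (1 - cos(pi * ph[rise] / tp))
  out[fall] <- cos(pi * (ph[fall] - tp) / (2 * tn))
  out
}

# second-order resonator filtering: cascade of all-pole sections
apply_formant_filter <- function(x, tract, rate) {
  if (any(tract$centers >= rate / 2)) {
    stop("formant center at or above Nyquist frequency")
  }
  y <- x
  for (i in seq_along(tract$centers)) {
    r <- exp(-pi * tract$bandwidths[i] / rate)
    theta <- 2 * pi * tract$centers[i] / rate
    a <- c(1, -2 * r * cos(theta), r^2)
    y <- as.numeric(signal::filter(1, a, y))
  }
  y
}

#' Synthesize a voiced phrase
#'
#' Source-filter synthesis: a Rosenberg glottal pulse train with per-cycle
#' period jitter, amplitude shimmer, slow F0 drift and additive Gaussian
#' aspiration noise, filtered by a cascade of second-order formant resonators
#' followed by a first-difference radiation characteristic, then
#' peak-normalized below clipping. The realised per-cycle onsets, periods,
#' amplitudes and the noise-free flow are attached as ground truth
#' (see [synthesis_truth()]).
#'
#' @param glottal a [glottal_params()] object
#' @param tract a [formant_spec()] object
#' @param duration duration in seconds (> 0)
#' @param rate sample rate in Hz (>= 8000)
#' @param seed integer seed; the output is a pure function of the arguments
#' @param phrase_id,subject_id optional identity attached to the recording
#' @return an `audio_recording`
#' @export
synthesize_voice <- function(glottal, tract = formant_spec(), duration = 1,
                             rate = 11025, seed = 1,
                             phrase_id = NA_integer_,
                             subject_id = NA_character_) {
  stopifnot(inherits(glottal, "glottal_params"), inherits(tract, "formant_spec"))
  if (duration <= 0) stop("duration must be positive")
  if (rate < 8000) stop("rate must be at least 8000 Hz")
  if (any(tract$centers >= rate / 2)) {
    stop("formant center at or above Nyquist frequency")
  }

  n <- round(duration * rate)
  with_seed(seed, {
    # per-cycle parameter track: slow AR(1) drift plus white jitter
    n_cyc_max <- ceiling(duration * (glottal$f0_mean * 1.5) + 4)
    drift <- numeric(n_cyc_max)
    if (glottal$f0_sd > 0) {
      phi <- 0.95
      innov <- rnorm(n_cyc_max, 0, glottal$f0_sd * sqrt(1 - phi^2))
      for (k in 2:n_cyc_max) drift[k] <- phi * drift[k - 1] + innov[k]
    }
    jit <- pmax(-3, pmin(3, rnorm(n_cyc_max)))
    shim <- pmax(-3, pmin(3, rnorm(n_cyc_max)))

    f0_cyc <- pmax(20, glottal$f0_mean + drift)
    periods <- (1 / f0_cyc) * (1 + glottal$jitter_pct / 100 * jit)
    amps <- glottal$amplitude *
      pmax(0, 1 + glottal$shimmer_pct / 100 * shim)
    # the period sequence accumulates on glottal-closure instants (the
    # landmarks any cycle detector measures); each open phase is rendered
    # backward from its closure
    closures <- cumsum(periods) - (1 - glottal$open_quotient) * periods[1]
    keep <- closures <= duration + periods[1]
    closures <- closures[keep]
    periods <- periods[keep]
    amps <- amps[keep]
    onsets <- closures - glottal$open_quotient * periods

    flow <- numeric(n)
    tt <- (seq_len(n) - 1) / rate
    for (k in seq_along(onsets)) {
      i0 <- max(1L, ceiling(onsets[k] * rate) + 1L)
      i1 <- min(n, floor(closures[k] * rate) + 1L)
      if (i0 > i1) next
      ph <- (tt[i0:i1] - onsets[k]) / periods[k]
      flow[i0:i1] <- flow[i0:i1] +
        amps[k] * rosenberg_pulse(pmin(pmax(ph, 0), 1 - 1e-12),
                                  glottal$open_quotient)
    }

    y <- apply_formant_filter(flow, tract, rate)
    y <- c(0, diff(y))                      # radiation characteristic
    if (is.finite(glottal$noise_snr_db)) {
      # aspiration noise enters at the glottis and is shaped by the same
      # tract + radiation path; its gain is set so the stated SNR holds in
      # the radiated signal, where downstream features measure it
      yn <- c(0, diff(apply_formant_filter(rnorm(n), tract, rate)))
      gain <- sqrt(stats::var(y) / stats::var(yn) /
                     10^(glottal$noise_snr_db / 10))
      y <- y + gain * yn
    }
    peak <- max(abs(y))
    if (peak > 0) y <- y / peak * 0.95

    rec <- audio_recording(y, rate, phrase_id = phrase_id,
                           subject_id = subject_id)
    attr(rec, "truth") <- list(onsets = onsets, closures = closures,
                               periods = periods, amplitudes = amps,
                               flow = flow, params = glottal, tract = tract)
    rec
  })
}
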