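leaky_integrate <- function(x, leak = 0.99) {
  as.numeric(signal::filter(1, c(1, -leak), x))
}

#' Glottal flow estimate container
#'
#' @param flow estimated glottal volume-velocity waveform (arbitrary units)
#' @param cycle_boundaries glottal-closure sample positions (may be
#'   fractional), strictly increasing
#' @param rate sample rate in Hz
#' @param voiced logical: whether any voiced content was found
#' @return a `glottal_flow` with `flow_derivative = diff(flow)`
#' @export
glottal_flow <- function(flow, cycle_boundaries = numeric(0), rate,
                         voiced = length(flow) > 0) {
  if (length(cycle_boundaries) > 1 && any(diff(cycle_boundaries) <= 0)) {
    stop("cycle boundaries must be strictly increasing")
  }
  structure(list(flow = as.numeric(flow),
                 flow_derivative = diff(as.numeric(flow)),
                 cycle_boundaries = as.numeric(cycle_boundaries),
                 rate = rate, voiced = voiced),
            class = "glottal_flow")
}

#' @export
print.glottal_flow <- function(x, ...) {
  cat(sprintf("<glottal_flow> %d samples, %d cycles%s\n", length(x$flow),
              max(0, length(x$cycle_boundaries) - 1),
              if (x$voiced) "" else " (unvoiced input)"))
  invisible(x)
}

#' Iterative adaptive inverse filtering (IAIF)
#'
#' Estimates the glottal volume-velocity waveform from speech by two rounds
#' of alternating glottal / vocal-tract linear prediction: high-pass
#' preprocessing, a first-order glottal pre-model and inverse filter, a
#' vocal-tract LP model and inverse filter with integration, a refined
#' fourth-order glottal model, and a final vocal-tract model whose inverse
#' filter output is integrated into the flow estimate (leaky integrators
#' absorb the radiation characteristic and low-frequency drift). The model
#' is fitted once per contiguous voiced segment, and the integrated flow is
#' smoothed with a zero-phase low-pass at `flow_smooth_hz` to strip residual
#' formant ripple, which lies well above the glottal band. Glottal-closure
#' instants are detected as the tracked negative peaks of the flow
#' derivative.
#'
#' @param rec an `audio_recording` with voiced content
#' @param vt_order vocal-tract LP order, default `rate/1000 - 1`
#' @param glottal_order refined glottal LP order (default 4)
#' @param flow_smooth_hz cutoff of the flow smoother in Hz (NULL disables)
#' @param f0 optional precomputed [estimate_f0()] result
#' @return a [glottal_flow()]; if the input is fully unvoiced, an empty flow
#'   with a warning
#' @export
iaif <- function(rec, vt_order = NULL, glottal_order = 4,
                 flow_smooth_hz = 600, f0 = NULL) {
  stopifnot(inherits(rec, "audio_recording"))
  fs <- rec$rate
  if (is.null(vt_order)) vt_order <- max(8L, default_lpc_order(fs) - 3L)
  if (is.null(f0)) f0 <- estimate_f0(rec)
  if (!any(f0$voiced_mask)) {
    warning("no voiced content; returning empty glottal flow")
    return(glottal_flow(numeric(0), numeric(0), fs, voiced = FALSE))
  }

  hp <- signal::butter(2, 2 * 40 / fs, type = "high")
  med_f0 <- median(f0$values[f0$voiced_mask])
  f0_fun <- stats::approxfun(f0$frame_times[f0$voiced_mask],
                             f0$values[f0$voiced_mask], rule = 2)

  flow_full <- numeric(length(rec$samples))
  boundaries <- numeric(0)

  for (seg in voiced_segments(f0, fs, length(rec$samples), med_f0)) {
    x <- rec$samples[seg$i0:seg$i1]
    if (length(x) < 4 * vt_order) next
    x <- as.numeric(signal::filtfilt(hp, x))
    w <- signal::hamming(length(x))

    hg1 <- lpc_coeffs(x * w, 1)
    y1 <- as.numeric(signal::filter(hg1, 1, x))
    hvt1 <- lpc_coeffs(y1 * w, vt_order)
    g1 <- leaky_integrate(as.numeric(signal::filter(hvt1, 1, x)))
    hg2 <- lpc_coeffs(g1 * w, glottal_order)
    y2 <- leaky_integrate(as.numeric(signal::filter(hg2, 1, x)))
    hvt2 <- lpc_coeffs(y2 * w, vt_order)
    dg <- as.numeric(signal::filter(hvt2, 1, x))
    flow <- leaky_integrate(dg)
    if (!is.null(flow_smooth_hz)) {
      # residual formant ripple sits well above the glottal band; zero-phase
      # smoothing leaves the flow (and its derivative) shape intact
      lpf <- signal::butter(4, 2 * flow_smooth_hz / fs)
      flow <- as.numeric(signal::filtfilt(lpf, flow))
    }
    peak <- max(abs(flow))
    if (peak > 0) flow <- flow / peak

    flow_full[seg$i0:seg$i1] <- flow
    pk <- track_negative_peaks(c(0, diff(flow)), fs,
                               function(t) fs / f0_fun(t + (seg$i0 - 1) / fs))
    boundaries <- c(boundaries, pk + seg$i0 - 1)
  }
  if (length(boundaries) > 1) {
    boundaries <- boundaries[c(TRUE, diff(boundaries) > 0)]
  }
  glottal_flow(flow_full, boundaries, fs, voiced = TRUE)
}

# contiguous voiced frame runs as sample ranges (>= 3 frames)
voiced_segments <- function(f0, fs, n, med_f0) {
  r <- rle(f0$voiced_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values & r$lengths >= 3)) {
    t0 <- max(0, f0$frame_times[starts[k]] - 0.5 / med_f0)
    t1 <- min(n / fs, f0$frame_times[ends[k]] + 0.5 / med_f0)
    segs[[length(segs) + 1L]] <- list(i0 = max(1L, floor(t0 * fs) + 1L),
                                      i1 = min(n, ceiling(t1 * fs)))
  }
  segs
}

#' Per-cycle glottal quotients NAQ and QOQ
#'
#' For each detected glottal cycle: NAQ is the peak-to-peak flow amplitude
#' divided by (magnitude of the most negative flow derivative times the
#' cycle duration); QOQ is the fraction of the cycle during which the flow
#' exceeds the cycle minimum plus half the peak-to-peak amplitude.
#' Degenerate cycles (zero duration, flat flow, or non-negative derivative
#' minimum) are skipped and counted in attribute `"n_skipped"`.
#'
#' @param gf a [glottal_flow()] with at least one complete cycle
#' @return a data frame with columns `time` (cycle onset, s), `naq`, `qoq`
#' @export
glottal_quotients <- function(gf) {
  stopifnot(inherits(gf, "glottal_flow"))
  nb <- length(gf$cycle_boundaries)
  if (nb < 2) stop("need at least one complete glottal cycle")
  fs <- gf$rate
  out <- data.frame(time = numeric(0), naq = numeric(0), qoq = numeric(0))
  skipped <- 0L
  for (k in seq_len(nb - 1L)) {
    b0 <- gf$cycle_boundaries[k]
    b1 <- gf$cycle_boundaries[k + 1L]
    t_cyc <- (b1 - b0) / fs
    i0 <- max(1L, round(b0))
    i1 <- min(length(gf$flow), round(b1))
    if (t_cyc <= 0 || i1 - i0 < 3) { skipped <- skipped + 1L; next }
    f <- gf$flow[i0:i1]
    d <- diff(f) * fs
    app <- max(f) - min(f)
    dmin <- min(d)
    if (app <= 0 || dmin >= 0) { skipped <- skipped + 1L; next }
    naq <- app / (abs(dmin) * t_cyc)
    thr <- min(f) + 0.5 * app
    qoq <- sum(f >= thr) / length(f)
    out <- rbind(out, data.frame(time = (i0 - 1) / fs, naq = naq, qoq = qoq))
  }
  attr(out, "n_skipped") <- skipped
  out
}
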