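# Track one sharp negative peak per glottal cycle through a signal.
# `period_at(t)` returns the expected period (in samples) at time t seconds.
# Returns fractional sample positions (parabolic-refined).
track_negative_peaks <- function(y, fs, period_at, t_start = 0,
                                 t_end = length(y) / fs) {
  i_start <- max(1L, floor(t_start * fs) + 1L)
  i_end <- min(length(y), floor(t_end * fs))
  if (i_end - i_start < 3) return(numeric(0))
  p0 <- period_at((i_start - 1) / fs)
  if (!is.finite(p0) || p0 <= 2) return(numeric(0))

  w_hi <- min(i_end, i_start + ceiling(1.5 * p0))
  seg <- y[i_start:w_hi]
  first <- i_start + which.min(seg) - 1L
  peaks <- refine_min(y, first)
  repeat {
    prev <- peaks[length(peaks)]
    per <- period_at(prev / fs)
    if (!is.finite(per) || per <= 2) break
    lo <- floor(prev + 0.82 * per)
    hi <- ceiling(prev + 1.18 * per)
    if (hi > i_end) break
    k <- lo + which.min(y[lo:hi]) - 1L
    if (k <= lo || k >= hi) {
      # minimum on the window edge: accept but do not refine past the edge
      peaks <- c(peaks, k)
    } else {
      peaks <- c(peaks, refine_min(y, k))
    }
  }
  peaks
}

refine_min <- function(y, k) {
  if (k <= 1L || k >= length(y)) return(as.numeric(k))
  pp <- parabolic_peak(y[k - 1L], y[k], y[k + 1L])
  k + pp$offset
}

#' Detect glottal cycles in a voiced recording
#'
#' Locates one glottal-closure instant per cycle as the sharp negative peak
#' of the waveform, tracked cycle by cycle under the F0 contour (the search
#' window for each closure is 0.72-1.30 local periods after the previous
#' one), with sub-sample parabolic refinement. Per-cycle amplitudes are
#' measured as the cycle RMS between consecutive closures (proportional to
#' the peak amplitude for a fixed cycle shape, and robust to sampling-phase
#' quantization of the sharp closure peak).
#'
#' @param rec an `audio_recording`
#' @param f0 optional precomputed [estimate_f0()] result
#' @return a list with `times` (closure instants, s), `periods` (s),
#'   `amplitudes` (cycle RMS per cycle); empty vectors when fewer than
#'   two closures are found
#' @export
detect_cycles <- function(rec, f0 = NULL) {
  if (is.null(f0)) f0 <- estimate_f0(rec)
  pa <- attr(f0, "analysis")
  if (!any(f0$voiced_mask)) {
    return(list(times = numeric(0), periods = numeric(0),
                amplitudes = numeric(0)))
  }
  fs <- rec$rate
  med_f0 <- median(f0$values[f0$voiced_mask])
  f0_fun <- stats::approxfun(f0$frame_times[f0$voiced_mask],
                             f0$values[f0$voiced_mask], rule = 2)
  period_at <- function(t) fs / f0_fun(t)

  # longest contiguous voiced run
  r <- rle(f0$voiced_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vi <- which(r$values)
  best <- vi[which.max(r$lengths[vi])]
  t0 <- f0$frame_times[starts[best]] - 0.5 / med_f0
  t1 <- f0$frame_times[ends[best]] + 0.5 / med_f0

  pk <- track_negative_peaks(rec$samples, fs, period_at,
                             max(0, t0), min(duration(rec), t1))
  if (length(pk) < 2) {
    return(list(times = numeric(0), periods = numeric(0),
                amplitudes = numeric(0)))
  }
  periods <- diff(pk) / fs
  y <- rec$samples
  # cycle amplitude as the cycle RMS: proportional to the peak amplitude for
  # a fixed cycle shape, and free of the sampling-phase quantization that a
  # raw peak-picked amplitude suffers at ~11 kHz
  amps <- vapply(seq_len(length(pk) - 1L), function(k) {
    i0 <- max(1L, ceiling(pk[k]))
    i1 <- min(length(y), floor(pk[k + 1L]))
    sqrt(mean(y[i0:i1]^2))
  }, 0)
  list(times = pk / fs, periods = periods, amplitudes = amps)
}

#' Local jitter
#'
#' Mean absolute difference of consecutive cycle periods divided by the mean
#' period.
#'
#' @param periods per-cycle durations (any consistent unit)
#' @return jitter as a ratio (multiply by 100 for percent)
#' @export
jitter_local <- function(periods) {
  if (length(periods) < 2) stop("jitter requires at least 2 cycle periods")
  mean(abs(diff(periods))) / mean(periods)
}

#' Local shimmer
#'
#' Mean absolute difference of consecutive cycle peak amplitudes divided by
#' the mean amplitude.
#'
#' @param amplitudes per-cycle peak amplitudes
#' @return shimmer as a ratio
#' @export
shimmer_local <- function(amplitudes) {
  if (length(amplitudes) < 2) stop("shimmer requires at least 2 cycle amplitudes")
  mean(abs(diff(amplitudes))) / mean(amplitudes)
}
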