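# Shared autocorrelation pitch analysis.
#
# Per rectangular frame: normalized cross-correlation
#   r(L) = sum x_t x_{t+L} / sqrt(sum_{1..N-L} x^2 * sum_{L+1..N} x^2)
# over the lag band [fs/fmax, fs/fmin]. Among local maxima within 0.01 of
# the global band maximum the shortest lag wins (guards against octave-down
# errors on strongly periodic frames); the winning lag and peak value are
# refined by parabolic interpolation. A frame is voiced when the refined
# peak exceeds the voicing threshold and the frame is not near-silent.
pitch_analysis <- function(rec, fmin = 60, fmax = 400, frame_len = 0.040,
                           hop = 0.010, voicing_threshold = 0.45) {
  stopifnot(inherits(rec, "audio_recording"))
  fs <- rec$rate
  if (!(fmin < fmax && fmax < fs / 2)) stop("invalid F0 search band")
  frames <- frame_signal(rec, frame_len, hop, window = "rectangular")
  times <- attr(frames, "times")
  flen <- nrow(frames)
  n_frames <- ncol(frames)
  frames <- sweep(frames, 2, colMeans(frames))

  l_min <- max(2L, floor(fs / fmax))
  l_max <- min(flen - 2L, ceiling(fs / fmin))
  if (l_max <= l_min) stop("frame too short for the F0 search band")

  nfft <- 2^ceiling(log2(2 * flen))
  padded <- rbind(frames, matrix(0, nfft - flen, n_frames))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(Mod(spec)^2, inverse = TRUE)) / nfft

  sq <- frames^2
  cs <- apply(sq, 2, cumsum)
  total <- cs[flen, ]
  rms <- sqrt(total / flen)
  rms_gate <- max(rms) * 0.01

  lags_ext <- (l_min - 1L):(l_max + 1L)
  e1 <- cs[flen - lags_ext, , drop = FALSE]
  e2 <- sweep(-cs[lags_ext, , drop = FALSE], 2, total, `+`)
  denom <- sqrt(pmax(e1 * e2, 0))
  r_ext <- ac[lags_ext + 1L, , drop = FALSE] / ifelse(denom > 0, denom, Inf)

  lag_out <- r_out <- rep(NA_real_, n_frames)
  voiced <- logical(n_frames)
  band <- 2:(nrow(r_ext) - 1L)          # rows corresponding to l_min..l_max

  pick <- function(rj, rows) {
    rb <- rj[rows]
    is_peak <- rb >= rj[rows - 1L] & rb >= rj[rows + 1L]
    if (!any(is_peak)) return(NULL)
    rmax <- max(rb[is_peak])
    # prefer the shortest lag among near-best peaks: on jittery but voiced
    # frames the double-period peak can edge out the true one by a few
    # hundredths, so the margin must absorb that without admitting noise
    # peaks (which sit far below the voicing threshold anyway)
    cand <- which(is_peak & rb >= rmax - 0.05)
    k <- rows[cand[1L]]                 # shortest qualifying lag
    pp <- parabolic_peak(rj[k - 1L], rj[k], rj[k + 1L])
    list(lag = lags_ext[k] + pp$offset, r = min(pp$value, 1 - 1e-9))
  }

  for (j in seq_len(n_frames)) {
    rj <- r_ext[, j]
    if (all(!is.finite(rj))) next
    sel <- pick(rj, band)
    if (is.null(sel)) next
    lag_out[j] <- sel$lag
    r_out[j] <- sel$r
    voiced[j] <- is.finite(sel$r) && sel$r >= voicing_threshold &&
      rms[j] >= rms_gate
  }

  # de-octavization: frames far from the median voiced lag are re-searched
  # near the median; a qualifying peak there replaces the octave candidate
  if (sum(voiced) >= 5) {
    med_lag <- median(lag_out[voiced])
    off <- voiced & (lag_out > 1.5 * med_lag | lag_out < 0.67 * med_lag)
    if (any(off)) {
      rows_near <- band[lags_ext[band] >= 0.67 * med_lag &
                          lags_ext[band] <= 1.5 * med_lag]
      for (j in which(off)) {
        if (length(rows_near) < 3) break
        sel <- pick(r_ext[, j], rows_near)
        if (!is.null(sel) && sel$r >= voicing_threshold) {
          lag_out[j] <- sel$lag
          r_out[j] <- sel$r
        } else {
          voiced[j] <- FALSE
        }
      }
    }
  }
  list(times = times, lag = lag_out, r = r_out, voiced = voiced,
       rms = rms, rate = fs, hop = hop)
}

#' Estimate the fundamental frequency contour
#'
#' Autocorrelation-peak F0 per frame within `[fmin, fmax]`; frames whose
#' normalized autocorrelation peak falls below the voicing threshold (or
#' that are near-silent) are marked unvoiced and carry NA.
#'
#' @param rec an `audio_recording`
#' @param fmin,fmax F0 search band in Hz, `fmin < fmax < rate/2`
#' @param frame_len analysis frame length in seconds (40 ms default; long
#'   enough for two cycles at `fmin`)
#' @param hop hop in seconds
#' @param voicing_threshold minimum normalized autocorrelation peak
#' @return a [frame_series()] of F0 in Hz with the full analysis attached as
#'   attribute `"analysis"`
#' @export
estimate_f0 <- function(rec, fmin = 60, fmax = 400, frame_len = 0.040,
                        hop = 0.010, voicing_threshold = 0.45) {
  pa <- pitch_analysis(rec, fmin, fmax, frame_len, hop, voicing_threshold)
  f0 <- ifelse(pa$voiced, pa$rate / pa$lag, NA_real_)
  out <- frame_series(f0, pa$times, pa$voiced)
  attr(out, "analysis") <- pa
  out
}

hnr_from_r <- function(r, ceiling_db = 40) {
  r <- pmin(pmax(r, 1e-9), 1 - 1e-9)
  pmin(10 * log10(r / (1 - r)), ceiling_db)
}

#' Harmonics-to-noise ratio contour
#'
#' Per voiced frame, HNR in dB is `10 log10(r / (1 - r))` where `r` is the
#' normalized autocorrelation at the detected pitch period, clipped at
#' `ceiling_db`. Unvoiced frames are NA.
#'
#' @inheritParams estimate_f0
#' @param ceiling_db upper clip for the HNR in dB
#' @return a [frame_series()] of HNR in dB
#' @export
hnr <- function(rec, fmin = 60, fmax = 400, frame_len = 0.040, hop = 0.010,
                voicing_threshold = 0.45, ceiling_db = 40) {
  pa <- pitch_analysis(rec, fmin, fmax, frame_len, hop, voicing_threshold)
  vals <- ifelse(pa$voiced, hnr_from_r(pa$r, ceiling_db), NA_real_)
  frame_series(vals, pa$times, pa$voiced)
}
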