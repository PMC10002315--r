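#' Short-time spectral features
#'
#' Per Hamming-windowed frame: linear power summed over FFT bins in the
#' half-open bands [0, 500), [500, 1000) and [1000, 4000) Hz, the
#' power-weighted mean frequency (spectral centroid), the spectral flux
#' (Euclidean distance between consecutive total-power-normalized magnitude
#' spectra, first frame 0), and the frame RMS energy.
#'
#' @param rec an `audio_recording` with rate > 8000 Hz
#' @param frame_len,hop framing in seconds
#' @return a list of [frame_series()]: `band_power_0_500`,
#'   `band_power_500_1000`, `band_power_1000_4000`, `centroid`, `flux`, `rms`
#' @export
spectral_features <- function(rec, frame_len = 0.025, hop = 0.010) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$rate / 2 <= 4000) {
    stop("sample rate too low for the 1000-4000 Hz band")
  }
  sp <- frame_spectra(rec, frame_len, hop)
  power <- sp$power
  freqs <- sp$freqs
  times <- sp$times

  band <- function(lo, hi) {
    sel <- freqs >= lo & freqs < hi
    colSums(power[sel, , drop = FALSE])
  }
  total <- colSums(power)
  centroid <- colSums(power * freqs) / ifelse(total > 0, total, Inf)
  centroid[total == 0] <- NA_real_

  mag <- sqrt(power)
  norm <- sqrt(total)
  magn <- sweep(mag, 2, ifelse(norm > 0, norm, Inf), `/`)
  n_frames <- ncol(power)
  flux <- c(0, sqrt(colSums((magn[, -1, drop = FALSE] -
                               magn[, -n_frames, drop = FALSE])^2)))

  mk <- function(v) frame_series(v, times, rep(TRUE, length(v)))
  list(band_power_0_500 = mk(band(0, 500)),
       band_power_500_1000 = mk(band(500, 1000)),
       band_power_1000_4000 = mk(band(1000, 4000)),
       centroid = mk(centroid),
       flux = mk(flux),
       rms = mk(sp$rms))
}

# shared framing + FFT power spectrum (one-sided, bins 0..nfft/2)
frame_spectra <- function(rec, frame_len = 0.025, hop = 0.010) {
  frames <- frame_signal(rec, frame_len, hop, window = "hamming")
  raw <- frame_signal(rec, frame_len, hop, window = "rectangular")
  fs <- attr(frames, "rate")
  flen <- nrow(frames)
  nfft <- 2^ceiling(log2(flen))
  padded <- rbind(frames, matrix(0, nfft - flen, ncol(frames)))
  spec <- stats::mvfft(padded)[1:(nfft / 2 + 1), , drop = FALSE]
  list(power = Mod(spec)^2,
       freqs = (0:(nfft / 2)) * fs / nfft,
       times = attr(frames, "times"),
       rms = sqrt(colMeans(raw^2)),
       rate = fs, nfft = nfft)
}

mel_scale <- function(f) 2595 * log10(1 + f / 700)
mel_inverse <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, rate) {
  freqs <- (0:(nfft / 2)) * rate / nfft
  edges <- mel_inverse(seq(0, mel_scale(rate / 2), length.out = n_filters + 2))
  fb <- matrix(0, n_filters, length(freqs))
  for (m in seq_len(n_filters)) {
    lo <- edges[m]; mid <- edges[m + 1]; hi <- edges[m + 2]
    up <- freqs >= lo & freqs <= mid
    down <- freqs > mid & freqs <= hi
    fb[m, up] <- (freqs[up] - lo) / (mid - lo)
    fb[m, down] <- (hi - freqs[down]) / (hi - mid)
  }
  fb
}

#' Mel-frequency cepstral coefficients
#'
#' Per frame: triangular mel filterbank (0 to Nyquist) applied to the FFT
#' power spectrum, log compression with a per-frame relative floor, then an
#' orthonormal DCT-II. Coefficients 1..`n_coeff` are returned; the 0th
#' (overall log energy) is excluded, which makes the returned coefficients
#' invariant to global amplitude scaling.
#'
#' @param rec an `audio_recording`
#' @param n_coeff number of coefficients (>= 1), default 12
#' @param n_filters number of mel filters, default 26
#' @param frame_len,hop framing in seconds
#' @return a list with `values` (n frames x n_coeff matrix) and
#'   `frame_times`
#' @export
mfcc <- function(rec, n_coeff = 12, n_filters = 26, frame_len = 0.025,
                 hop = 0.010) {
  stopifnot(n_coeff >= 1, n_filters > n_coeff)
  sp <- frame_spectra(rec, frame_len, hop)
  fb <- mel_filterbank(n_filters, sp$nfft, sp$rate)
  energies <- fb %*% sp$power                  # n_filters x n_frames
  emax <- apply(energies, 2, max)
  floor_vals <- pmax(emax * 1e-8, .Machine$double.xmin)
  energies <- pmax(energies, rep(floor_vals, each = n_filters))
  loge <- log(energies)
  m <- seq_len(n_filters)
  dct <- sqrt(2 / n_filters) *
    outer(seq_len(n_coeff), m, function(k, m) cos(pi * k * (m - 0.5) / n_filters))
  coef <- t(dct %*% loge)                      # n_frames x n_coeff
  colnames(coef) <- paste0("mfcc_", seq_len(n_coeff))
  list(values = coef, frame_times = sp$times)
}
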