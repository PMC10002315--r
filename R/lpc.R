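# Autocorrelation-method linear prediction.
# Returns error-filter coefficients a = c(1, a_1, ..., a_p) such that the
# residual is filter(a, 1, x). A small diagonal ridge keeps the normal
# equations well conditioned on near-degenerate frames.
lpc_coeffs <- function(x, order) {
  n <- length(x)
  if (n <= order + 1) stop("signal too short for LPC order ", order)
  nfft <- 2^ceiling(log2(2 * n))
  sp <- Mod(fft(c(x, rep(0, nfft - n))))^2
  ac <- Re(fft(sp, inverse = TRUE))[1:(order + 1)] / nfft
  if (ac[1] <= 0) return(c(1, rep(0, order)))
  r0 <- ac[1] * (1 + 1e-9)
  rmat <- stats::toeplitz(c(r0, ac[2:order]))
  a <- tryCatch(solve(rmat, ac[2:(order + 1)]),
                error = function(e) rep(0, order))
  c(1, -a)
}

default_lpc_order <- function(rate) 2L + as.integer(round(rate / 1000))

# poles of an LPC model as (frequency Hz, bandwidth Hz) pairs
lpc_pole_freqs <- function(a, rate) {
  roots <- polyroot(rev(a))
  keep <- Im(roots) > 1e-9 & Mod(roots) < 1
  roots <- roots[keep]
  if (length(roots) == 0) {
    return(data.frame(freq = numeric(0), bw = numeric(0)))
  }
  freq <- Arg(roots) / (2 * pi) * rate
  bw <- -rate / pi * log(Mod(roots))
  ord <- order(freq)
  data.frame(freq = freq[ord], bw = bw[ord])
}

#' Formant frequency contours
#'
#' Per voiced frame, the first `n` vocal-tract resonances: the pre-emphasized
#' Hamming-windowed frame is fitted with a linear-prediction model of order
#' `2 + rate/1000`, the complex roots of the prediction polynomial are
#' converted to (frequency, bandwidth) pairs, roots with bandwidth above
#' `bw_cutoff` or frequency below `f_floor` are discarded, and the first `n`
#' surviving frequencies are reported in increasing order. Frames with fewer
#' than `n` surviving roots carry NA in the missing slots; unvoiced frames
#' are all-NA.
#'
#' @param rec an `audio_recording`
#' @param n number of formants (<= 5)
#' @param order LPC order; default `2 + round(rate/1000)`
#' @param bw_cutoff maximum admissible bandwidth in Hz
#' @param f_floor minimum admissible frequency in Hz
#' @param frame_len,hop framing in seconds
#' @param f0 optional precomputed [estimate_f0()] result (for the voicing
#'   mask)
#' @return a list with `values` (n frames x n matrix of Hz) and
#'   `frame_times`
#' @export
formants <- function(rec, n = 5, order = NULL, bw_cutoff = 400, f_floor = 90,
                     frame_len = 0.025, hop = 0.010, f0 = NULL) {
  stopifnot(inherits(rec, "audio_recording"), n >= 1, n <= 5)
  fs <- rec$rate
  if (is.null(order)) order <- default_lpc_order(fs)
  pre <- audio_recording(c(rec$samples[1],
                           rec$samples[-1] - 0.97 * head(rec$samples, -1)),
                         fs)
  frames <- frame_signal(pre, frame_len, hop, window = "hamming")
  times <- attr(frames, "times")
  if (is.null(f0)) f0 <- estimate_f0(rec, hop = hop)
  voiced <- voiced_at(f0, times)

  out <- matrix(NA_real_, length(times), n)
  colnames(out) <- paste0("formant_", seq_len(n))
  for (j in which(voiced)) {
    a <- lpc_coeffs(frames[, j], order)
    pf <- lpc_pole_freqs(a, fs)
    ok <- pf$freq > f_floor & pf$freq < fs / 2 - 50 & pf$bw < bw_cutoff
    f <- pf$freq[ok]
    if (length(f) > 0) out[j, seq_len(min(n, length(f)))] <- f[seq_len(min(n, length(f)))]
  }
  list(values = out, frame_times = times)
}

# nearest-frame lookup of the voicing mask at arbitrary times
voiced_at <- function(f0, times) {
  if (length(f0$frame_times) == 0) return(rep(FALSE, length(times)))
  idx <- findInterval(times, f0$frame_times, all.inside = TRUE)
  near <- ifelse(abs(f0$frame_times[pmin(idx + 1L, length(f0$frame_times))] - times) <
                   abs(f0$frame_times[idx] - times),
                 pmin(idx + 1L, length(f0$frame_times)), idx)
  f0$voiced_mask[near]
}
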