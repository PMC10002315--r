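#' Frame series container
#'
#' Per-frame values of a single acoustic feature with frame centre times and
#' a voicing mask; unvoiced (or otherwise invalid) frames carry NA values.
#'
#' @param values per-frame numeric values (NA where invalid)
#' @param frame_times frame centre times in seconds, strictly increasing
#' @param voiced_mask logical voicing mask
#' @return a `frame_series`
#' @export
frame_series <- function(values, frame_times, voiced_mask = !is.na(values)) {
  stopifnot(length(values) == length(frame_times),
            length(voiced_mask) == length(values))
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing")
  }
  structure(list(values = as.numeric(values),
                 frame_times = as.numeric(frame_times),
                 voiced_mask = as.logical(voiced_mask)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames, %d voiced, mean %.4g\n",
              length(x$values), sum(x$voiced_mask),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Slice a signal into overlapping windowed frames
#'
#' Frames are `frame_len` seconds long, advanced by `hop` seconds; the final
#' partial frame is dropped. Frames are returned as columns, multiplied by
#' the chosen analysis window.
#'
#' @param rec an `audio_recording` (or numeric vector with `rate`)
#' @param frame_len frame length in seconds (>= hop)
#' @param hop hop size in seconds (> 0)
#' @param window "hamming" or "rectangular"
#' @param rate sample rate, required when `rec` is a bare vector
#' @return a numeric matrix (frame length x n frames) with attributes
#'   `times` (frame centres, s) and `rate`
#' @export
frame_signal <- function(rec, frame_len = 0.025, hop = 0.010,
                         window = c("hamming", "rectangular"), rate = NULL) {
  window <- match.arg(window)
  rec <- as_recording(rec, rate)
  if (!(hop > 0) || frame_len < hop) stop("need frame_len >= hop > 0")
  fs <- rec$rate
  flen <- round(frame_len * fs)
  fhop <- round(hop * fs)
  n <- length(rec$samples)
  if (n < flen) stop("recording shorter than one frame")
  n_frames <- floor((n - flen) / fhop) + 1L
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * fhop, `+`)
  frames <- matrix(rec$samples[idx], nrow = flen)
  if (window == "hamming") {
    w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
    frames <- frames * w
  }
  attr(frames, "times") <- ((seq_len(n_frames) - 1L) * fhop + flen / 2) / fs
  attr(frames, "rate") <- fs
  frames
}
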