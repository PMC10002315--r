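#' Construct an audio recording
#'
#' Container for a mono waveform with its sample rate and optional subject /
#' phrase identity. Amplitudes are expected in [-1, 1] and must be finite.
#'
#' @param samples numeric vector of amplitudes
#' @param rate sample rate in Hz
#' @param phrase_id fixed-phrase number (1-21) or NA
#' @param subject_id opaque subject identifier or NA
#' @return an object of class `audio_recording`
#' @export
audio_recording <- function(samples, rate, phrase_id = NA_integer_,
                            subject_id = NA_character_) {
  stopifnot(is.numeric(samples), length(rate) == 1, rate > 0)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite")
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         phrase_id = as.integer(phrase_id), subject_id = subject_id),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.3f s @ %g Hz", length(x$samples) / x$rate,
              x$rate))
  if (!is.na(x$phrase_id)) cat(sprintf(", phrase %d", x$phrase_id))
  if (!is.na(x$subject_id)) cat(sprintf(", subject %s", x$subject_id))
  cat("\n")
  invisible(x)
}

#' @export
length.audio_recording <- function(x) length(x$samples)

#' Duration of a recording in seconds
#' @param rec an `audio_recording`
#' @return duration in seconds
#' @export
duration <- function(rec) length(rec$samples) / rec$rate

as_recording <- function(x, rate = NULL) {
  if (inherits(x, "audio_recording")) return(x)
  if (is.numeric(x)) {
    if (is.null(rate)) stop("rate required for bare sample vectors")
    return(audio_recording(x, rate))
  }
  stop("cannot interpret object as an audio recording")
}

#' Ground-truth synthesis parameters attached to a synthetic recording
#'
#' The voice synthesizer stores the realised per-cycle periods, amplitudes
#' and the noise-free glottal flow alongside the waveform, so that estimators
#' can be checked against the exact generating values.
#'
#' @param rec an `audio_recording` produced by [synthesize_voice()]
#' @return a list with `onsets` (s), `periods` (s), `amplitudes`, `flow`
#'   (noise-free glottal flow at the output rate), or NULL if absent
#' @export
synthesis_truth <- function(rec) attr(rec, "truth")
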