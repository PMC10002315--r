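#' @importFrom stats cor fft rnorm runif sd median wilcox.test predict
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic mixing of a master seed with a stage index, kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param stage stage index (small non-negative integer)
#' @return an integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 48271 + stage * 7919) %% 2147483629)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# parabolic interpolation of an extremum through three equally spaced points;
# returns offset in (-1, 1) relative to the centre point and interpolated value
parabolic_peak <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < 1e-30) {
    return(list(offset = 0, value = y0))
  }
  offset <- 0.5 * (ym1 - yp1) / denom
  offset <- max(-1, min(1, offset))
  value <- y0 - 0.25 * (ym1 - yp1) * offset
  list(offset = offset, value = value)
}
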