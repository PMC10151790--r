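#' Greenwood cochlear frequency-position map
#'
#' Maps a normalised position along the basilar membrane to a characteristic
#' frequency, `f = 165.4 * (10^(2.1 * x) - 1)` Hz, with `x = 0` at the apex
#' (low frequency) and `x = 1` at the base (high frequency). This map spaces
#' the filterbank channels so that equal channel-index spans cover
#' approximately equal log-frequency spans, which is what the multi-scale
#' spectrotemporal contexts rely on.
#'
#' @param x Numeric vector of normalised cochlear positions in `[0, 1]`.
#' @return Characteristic frequency in Hz, same length as `x`.
#' @seealso [greenwood_position()] for the analytic inverse.
#' @export
#' @examples
#' greenwood_cf(c(0, 0.5, 1))
greenwood_cf <- function(x) {
  if (!is.numeric(x) || anyNA(x)) {
    stop("`x` must be numeric with no missing values", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("normalised cochlear position `x` must lie in [0, 1]", call. = FALSE)
  }
  165.4 * (10^(2.1 * x) - 1)
}

#' Inverse Greenwood map
#'
#' Recovers the normalised cochlear position from a characteristic frequency;
#' the analytic inverse of [greenwood_cf()].
#'
#' @param f Frequency in Hz, `f >= 0`.
#' @return Normalised position `x` in `[0, Inf)`; values in `[0, 1]` for
#'   frequencies up to `greenwood_cf(1)` (about 20.6 kHz).
#' @export
greenwood_position <- function(f) {
  if (!is.numeric(f) || anyNA(f) || any(f < 0)) {
    stop("`f` must be a nonnegative numeric vector", call. = FALSE)
  }
  log10(f / 165.4 + 1) / 2.1
}
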