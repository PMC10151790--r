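#' Time-surface parameters
#'
#' The time surface assigns every location the exponentially decayed trace of
#' its most recent event: 1 at the event, decaying with constant `tau_v`.
#' The default decay constant is `fs * 1e-3` samples, i.e. 1 ms of real time.
#'
#' @param fs Sampling rate in Hz.
#' @param tau_v Decay constant in samples (default `fs * 1e-3`).
#' @return A list of class `ts_params`.
#' @export
ts_params <- function(fs = 16000, tau_v = fs * 1e-3) {
  if (tau_v <= 0) stop("`tau_v` must be positive", call. = FALSE)
  structure(list(fs = fs, tau_v = tau_v), class = "ts_params")
}

#' Time-surface value at a lag
#'
#' Closed-form decayed trace `exp(-(t_now - t_last)/tau_v)`.
#'
#' @param t_now Current time (samples).
#' @param t_last Time of the location's most recent previous event.
#' @param tau_v Decay constant in samples.
#' @return Value in `[0, 1]`.
#' @export
time_surface_value <- function(t_now, t_last, tau_v) {
  if (any(t_now < t_last)) stop("`t_now` must be >= `t_last`", call. = FALSE)
  exp(-(t_now - t_last) / tau_v)
}

#' Event-context parameters
#'
#' An event context (E_C) is a fixed-size, resampled time-surface patch
#' around one event: `k` spikes per channel (the anchor plus `k-1` of
#' history), resampled onto `n_samples` uniform grid points spanning the
#' anchor channel's window. To make contexts that differ only by a uniform
#' time dilation identical (the descriptor encodes relative inter-spike
#' timing, not absolute duration), the exponential decay is applied in
#' resampled-grid units with constant `tau_grid`; the default
#' `(n_samples-1)/(k-1)` is the mean spike spacing on the grid, so evenly
#' spaced spikes decay to `exp(-1)` between grid-aligned spikes.
#'
#' @param k Spikes per channel per context (default 4, minimum 2).
#' @param n_samples Resampled length (default 32).
#' @param scales Odd channel counts for 2-D contexts (default
#'   `c(5, 13, 25, 37)`).
#' @param tau_grid Decay constant in resampled-grid samples.
#' @return A list of class `ec_params`.
#' @export
ec_params <- function(k = 4, n_samples = 32, scales = c(5, 13, 25, 37),
                      tau_grid = (n_samples - 1) / (k - 1)) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (n_samples < k) stop("`n_samples` must be >= k", call. = FALSE)
  if (any(scales %% 2 != 1)) stop("every scale must be odd", call. = FALSE)
  structure(list(k = as.integer(k), n_samples = as.integer(n_samples),
                 scales = as.integer(scales), tau_grid = tau_grid),
            class = "ec_params")
}

# Resampled decayed profile over a window, grid-unit decay.
# spike_pos: grid positions (possibly negative) of selected spikes, ascending.
ec_profile <- function(spike_pos, n_samples, tau_grid) {
  vapply(seq_len(n_samples) - 1, function(g) {
    past <- spike_pos[spike_pos <= g + 1e-9]
    if (!length(past)) return(0)
    exp(-(g - max(past)) / tau_grid)
  }, numeric(1))
}

#' Build a 1-D event context
#'
#' Selects the `k` most recent spikes in the anchor's channel ending at (and
#' including) the anchor, maps their times onto the resampled grid spanning
#' `[first selected spike, anchor]`, and evaluates the grid-unit exponential
#' decay from the most recent selected spike at or before each grid point.
#' The anchor grid point is exactly 1.
#'
#' @param anchor_t Anchor spike time (samples).
#' @param times Sorted spike times of one channel (must contain the anchor).
#' @param params An [ec_params()].
#' @param window Optional length-2 window `c(t0, t1)` overriding the default
#'   `[first selected, anchor]` (used to share a window across the rows of a
#'   2-D context).
#' @return Numeric vector of length `n_samples`, or `NULL` if the channel has
#'   fewer than `k` spikes at or before the anchor (skip).
#' @export
build_ec_1d <- function(anchor_t, times, params, window = NULL) {
  past <- times[times <= anchor_t]
  if (length(past) < params$k) return(NULL)
  sel <- past[(length(past) - params$k + 1):length(past)]
  if (is.null(window)) window <- c(sel[1], anchor_t)
  span <- window[2] - window[1]
  if (span <= 0) return(NULL)
  pos <- (sel - window[1]) / span * (params$n_samples - 1)
  ec_profile(pos, params$n_samples, params$tau_grid)
}

#' Build a 2-D (spectrotemporal) event context
#'
#' Takes `scale` adjacent channels centred on the anchor's channel. All rows
#' share the anchor channel's window; per channel the `k` causally nearest
#' spikes (at or before the anchor) are selected and resampled as in
#' [build_ec_1d()]. Rows for channels outside the bank, or with fewer than
#' `k` spikes, are zero-filled. Requires the anchor channel itself to have
#' `k` spikes of history (else skip).
#'
#' @param anchor_t Anchor time. @param anchor_ch Anchor channel (1-based).
#' @param stream An [event_stream()] (or a data.frame with `t`, `channel`).
#' @param scale Odd channel count.
#' @param params An [ec_params()].
#' @return `scale x n_samples` matrix (rows ordered by increasing channel
#'   index), or `NULL` (skip).
#' @export
build_ec_2d <- function(anchor_t, anchor_ch, stream, scale, params) {
  if (scale %% 2 != 1) stop("`scale` must be odd", call. = FALSE)
  ev <- if (inherits(stream, "event_stream")) stream$events else stream
  n_channels <- if (inherits(stream, "event_stream")) stream$n_channels else max(ev$channel)
  ctimes <- ev$t[ev$channel == anchor_ch]
  ctimes <- unique(ctimes[ctimes <= anchor_t])
  if (length(ctimes) < params$k) return(NULL)
  sel <- ctimes[(length(ctimes) - params$k + 1):length(ctimes)]
  window <- c(sel[1], anchor_t)
  if (diff(window) <= 0) return(NULL)
  half <- (scale - 1) / 2
  out <- matrix(0, scale, params$n_samples)
  for (s in seq_len(scale)) {
    cc <- anchor_ch - half + s - 1
    if (cc < 1 || cc > n_channels) next
    tt <- unique(ev$t[ev$channel == cc & ev$t <= anchor_t])
    if (length(tt) < params$k) next
    row <- build_ec_1d(anchor_t, tt, params, window = window)
    if (!is.null(row)) out[s, ] <- row
  }
  out
}

#' Build event contexts for every event in a stream
#'
#' Applies [build_ec_1d()] (`scale = 1`) or [build_ec_2d()] to every event of
#' the stream in order (duplicate (t, channel) records from multiple
#' thresholds/neurons are collapsed first: the context describes channel
#' activity, not neuron identity). Implemented in compiled code; equals the
#' event-by-event R construction.
#'
#' @param stream An [event_stream()].
#' @param params An [ec_params()].
#' @param scale 1 for temporal contexts, or an odd channel count.
#' @return List of class `ec_batch`: `ec` (matrix, one flattened context per
#'   row, channel-major for 2-D), `anchor` (data.frame `t`, `channel`),
#'   `scale`, `n_built`, `n_skipped`.
#' @export
ec_batch <- function(stream, params, scale = 1) {
  stopifnot(inherits(stream, "event_stream"), inherits(params, "ec_params"))
  ev <- stream$events
  keep <- !duplicated(ev[c("t", "channel")])
  ev <- ev[keep, , drop = FALSE]
  d <- scale * params$n_samples
  if (nrow(ev) == 0) {
    return(structure(list(ec = matrix(0, 0, d),
                          anchor = data.frame(t = numeric(), channel = integer()),
                          scale = scale, n_built = 0L, n_skipped = 0L),
                     class = "ec_batch"))
  }
  if (scale == 1) {
    res <- ec_batch_1d_cpp(as.numeric(ev$t), as.integer(ev$channel) - 1L,
                           stream$n_channels, params$k, params$n_samples,
                           params$tau_grid)
  } else {
    if (scale %% 2 != 1) stop("`scale` must be odd", call. = FALSE)
    res <- ec_batch_2d_cpp(as.numeric(ev$t), as.integer(ev$channel) - 1L,
                           stream$n_channels, params$k, params$n_samples,
                           as.integer(scale), params$tau_grid)
  }
  anchor <- ev[res$anchor, c("t", "channel"), drop = FALSE]
  rownames(anchor) <- NULL
  structure(list(ec = res$ec, anchor = anchor, scale = scale,
                 n_built = nrow(res$ec), n_skipped = res$skipped),
            class = "ec_batch")
}

#' @export
print.ec_batch <- function(x, ...) {
  cat(sprintf("<ec_batch: scale %d, %d contexts built, %d skipped>\n",
              x$scale, x$n_built, x$n_skipped))
  invisible(x)
}
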