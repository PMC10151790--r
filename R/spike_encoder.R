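#' LIF spike-encoder configuration
#'
#' Leaky integrate-and-fire neurons convert the lateral-inhibited IHC output
#' of each cochlear channel into asynchronous spike events. The membrane
#' follows `v[t] = v[t-1] + c_lif * (drive[t] - v[t-1])` with
#' `c_lif = 1/(fs * tau_lif)`; when `v > threshold` (strict) a spike is
#' emitted and the membrane is reset to `v_reset` in the same sample.
#'
#' @param fs Sampling rate in Hz.
#' @param tau_lif Membrane time constant in seconds (default 0.01).
#' @param thresholds Strictly increasing firing thresholds (default a single
#'   medium value, 4e-4). Use three values for a low/medium/high layout.
#' @param neurons_per_threshold Neurons sharing each threshold (default 1;
#'   3 gives the nine-neuron, three-threshold layout). Neurons in a group are
#'   desynchronised by deterministic initial potentials
#'   `(j-1)/n * threshold`, recorded in the config.
#' @param v_reset Reset potential (default 0).
#' @return An object of class `lif_config`.
#' @export
lif_config <- function(fs = 16000, tau_lif = 0.01, thresholds = 4e-4,
                       neurons_per_threshold = 1L, v_reset = 0) {
  if (tau_lif <= 0) stop("`tau_lif` must be positive", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  c_lif <- 1 / (fs * tau_lif)
  if (c_lif <= 0 || c_lif > 1) stop("c_lif = 1/(fs*tau_lif) must be in (0, 1]", call. = FALSE)
  n <- as.integer(neurons_per_threshold)
  if (n < 1) stop("`neurons_per_threshold` must be >= 1", call. = FALSE)
  structure(list(fs = fs, tau_lif = tau_lif, c_lif = c_lif,
                 thresholds = as.numeric(thresholds),
                 neurons_per_threshold = n,
                 init_frac = (seq_len(n) - 1) / n,
                 v_reset = v_reset),
            class = "lif_config")
}

#' One LIF membrane update
#'
#' @param v_prev Previous membrane potential.
#' @param drive Input (lateral-inhibited IHC value).
#' @param c_lif Leak/integration coefficient `1/(fs * tau_lif)`.
#' @return Updated membrane potential `v_prev + c_lif * (drive - v_prev)`.
#' @export
lif_step <- function(v_prev, drive, c_lif) {
  v_prev + c_lif * (drive - v_prev)
}

#' Event stream container
#'
#' Time-ordered spike records: `t` (sample index, 0-based), `channel`
#' (1-based, channel 1 = highest CF), `threshold_id`, `neuron_id`.
#'
#' @param events A data.frame with columns `t`, `channel`, `threshold_id`,
#'   `neuron_id`.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of cochlear channels.
#' @param source Free-text provenance tag.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(events, fs, n_channels, source = "") {
  stopifnot(is.data.frame(events),
            all(c("t", "channel", "threshold_id", "neuron_id") %in% names(events)))
  if (nrow(events) > 0) {
    if (is.unsorted(events$t)) stop("events must be time-ordered", call. = FALSE)
    if (any(events$t < 0)) stop("event times must be >= 0", call. = FALSE)
    if (any(events$channel < 1 | events$channel > n_channels)) {
      stop("channel out of range", call. = FALSE)
    }
  }
  structure(list(events = events, fs = fs,
                 n_channels = as.integer(n_channels), source = source),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream: %d spikes, %d channels @ %g Hz>\n",
              nrow(x$events), x$n_channels, x$fs))
  invisible(x)
}

#' Encode a cochleagram into spike events
#'
#' Integrates each channel's `ihc_li` drive with one LIF membrane per
#' (channel, threshold, neuron) and emits a spike whenever the membrane
#' strictly exceeds its threshold, resetting to `v_reset`. The returned
#' stream is globally time-sorted.
#'
#' @param cochleagram A `cochleagram` from [cochlea_process()].
#' @param config A [lif_config()].
#' @return An [event_stream()].
#' @export
lif_encode <- function(cochleagram, config) {
  stopifnot(inherits(cochleagram, "cochleagram"), inherits(config, "lif_config"))
  drive <- cochleagram$ihc_li
  if (nrow(drive) == 0) {
    return(event_stream(data.frame(t = integer(), channel = integer(),
                                   threshold_id = integer(), neuron_id = integer()),
                        config$fs, ncol(drive)))
  }
  res <- lif_encode_cpp(drive, config$c_lif, config$thresholds,
                        config$neurons_per_threshold, config$v_reset,
                        config$init_frac)
  ev <- data.frame(t = res$t, channel = res$channel + 1L,
                   threshold_id = res$threshold_id + 1L,
                   neuron_id = res$neuron_id + 1L)
  ev <- ev[order(ev$t, ev$channel, ev$threshold_id, ev$neuron_id), , drop = FALSE]
  rownames(ev) <- NULL
  event_stream(ev, config$fs, ncol(drive), source = "lif_encode")
}

#' Write / read an event stream as CSV plus a JSON sidecar
#'
#' The CSV holds `t_sample,channel,threshold_id,neuron_id` (and any extra
#' columns, e.g. feature-map `winner_id,scale`); `<path>.json` carries `fs`,
#' `n_channels` and `source`. The round trip is exact.
#'
#' @param stream An [event_stream()].
#' @param path CSV output path.
#' @return `path` invisibly (writer); an [event_stream()] (reader).
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$events
  names(ev)[names(ev) == "t"] <- "t_sample"
  write.csv(ev, path, row.names = FALSE, quote = FALSE)
  meta <- list(fs = stream$fs, n_channels = stream$n_channels,
               source = stream$source)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.csv(path)
  names(ev)[names(ev) == "t_sample"] <- "t"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  event_stream(ev, meta$fs, meta$n_channels, meta$source)
}
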