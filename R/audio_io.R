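#' Audio signal container
#'
#' A mono sampled waveform plus its sampling rate; the entry point of the
#' pipeline.
#'
#' @param samples Numeric vector of samples, all finite.
#' @param fs Sampling rate in Hz (default 16000).
#' @return An object of class `audio_signal` with fields `samples` and `fs`.
#' @export
audio_signal <- function(samples, fs = 16000) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for mono 16-bit PCM and 32-bit IEEE float files.
#' Stereo (or any multi-channel) input is rejected: the pipeline is monaural.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path, call. = FALSE)
  if (fmt$n_channels != 1L) {
    stop("only mono WAV is supported (got ", fmt$n_channels, " channels)", call. = FALSE)
  }
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    s <- readBin(data_raw, "integer", length(data_raw) / 2, 2, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    s <- readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)", call. = FALSE)
  }
  audio_signal(s, fmt$fs)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param sig An [audio_signal()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sig, path) {
  stopifnot(inherits(sig, "audio_signal"))
  s <- pmax(-1, pmin(1, sig$samples))
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")   # PCM
  writeBin(1L, con, 2, endian = "little")   # mono
  writeBin(as.integer(sig$fs), con, 4, endian = "little")
  writeBin(as.integer(sig$fs * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
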