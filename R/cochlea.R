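#' Design a CAR-FAC cochlear filterbank
#'
#' Builds the configuration for a cascade of asymmetric resonators. Channel
#' characteristic frequencies (CFs) are placed by sampling the Greenwood map
#' at `n_channels` equally spaced cochlear positions spanning `cf_range`,
#' ordered base to apex, i.e. CF strictly decreasing with channel index
#' (channel 1 = highest CF). Per-channel two-state coupled-form resonator
#' coefficients are derived from CF and `fs`, with a unity-DC-gain
#' normalisation and a zero placed above the pole (the asymmetry that makes
#' the cascade fall off sharply above each CF).
#'
#' @param n_channels Number of channels (default 64, minimum 2).
#' @param fs Sampling rate in Hz (default 16000).
#' @param cf_range Length-2 numeric, lowest and highest CF in Hz (default
#'   `c(100, 8000)`); must not exceed `fs/2`.
#' @param fac_enabled Enable fast-acting compression (DOHC + AGC loop);
#'   `FALSE` gives an exactly linear CAR cascade.
#' @param zeta_min,zeta_max Relative damping bounds. The AGC moves each
#'   resonator between `zeta_min` (quiet, maximally undamped/sharp) and
#'   `zeta_max` (loud, damped); with FAC off the damping is fixed at
#'   `zeta_min`.
#' @param pole_shift Length-2 numeric `c(s0, s1)`: each channel's pole sits
#'   at `cf * (s0 + s1 * cf/(fs/2))`. The cumulative response of a resonator
#'   cascade peaks a little above each stage's pole, so the pole sits
#'   slightly apical of the nominal CF; the default aligns the cascade's
#'   argmax channel with the nominal CF to within one channel spacing across
#'   the speech band (verified against the analytic response,
#'   [cascade_gain()]).
#' @param ihc_cutoff Inner-hair-cell smoothing cutoff in Hz.
#' @param ihc_gain Output scaling of the IHC detector so that
#'   speech-band signals at typical amplitudes drive the default LIF
#'   threshold usefully.
#' @param agc_tau AGC stage time constants in seconds (4-stage cascade).
#' @param agc_strength Gain of the level-to-undamping feedback.
#' @param li_kernel Lateral-inhibition neighbour weights, odd length, centre
#'   entry ignored (see [lateral_inhibition()]).
#' @param fixed_point Optional list with elements `bm_bits`, `bm_frac`,
#'   `ihc_bits`, `ihc_frac` enabling fixed-point state quantisation
#'   emulation; `NULL` (default) = floating point.
#' @return An object of class `cochlea_config`.
#' @export
design_filterbank <- function(n_channels = 64, fs = 16000,
                              cf_range = c(100, 8000),
                              fac_enabled = TRUE,
                              zeta_min = 0.07, zeta_max = 0.25,
                              pole_shift = c(0.90, 0.04),
                              ihc_cutoff = 3000, ihc_gain = 0.15,
                              agc_tau = 0.002 * 4^(0:3),
                              agc_strength = 30,
                              li_kernel = c(0.5, 0, 0.5),
                              fixed_point = NULL) {
  if (n_channels < 2) stop("`n_channels` must be >= 2", call. = FALSE)
  if (length(cf_range) != 2 || cf_range[1] <= 0 || cf_range[2] <= cf_range[1]) {
    stop("`cf_range` must be an increasing positive pair", call. = FALSE)
  }
  if (cf_range[2] > fs / 2) {
    stop("`cf_range` exceeds the Nyquist frequency fs/2", call. = FALSE)
  }
  if (length(li_kernel) %% 2 != 1) stop("`li_kernel` length must be odd", call. = FALSE)

  # base (high CF) -> apex (low CF): positions descend
  x <- seq(greenwood_position(cf_range[2]), greenwood_position(cf_range[1]),
           length.out = n_channels)
  cf <- greenwood_cf(x)

  pole <- pmin(cf * (pole_shift[1] + pole_shift[2] * cf / (fs / 2)),
               0.995 * fs / 2)
  theta <- 2 * pi * pole / fs
  a0 <- cos(theta)
  c0 <- sin(theta)
  h <- c0                        # zero ratio sqrt(2): h = c0 * (zr^2 - 1)
  r1 <- 1 - zeta_max * theta     # most damped radius
  drz <- (zeta_max - zeta_min) * theta  # available undamping
  r_sharp <- r1 + drz
  # unity DC gain at the undamped operating point
  d1 <- 1 - 2 * a0 * r_sharp + r_sharp^2
  g <- d1 / (d1 + h * r_sharp * c0)

  structure(list(
    n_channels = as.integer(n_channels), fs = fs, cf = cf, pole = pole,
    fac_enabled = isTRUE(fac_enabled),
    zeta_min = zeta_min, zeta_max = zeta_max,
    a0 = a0, c0 = c0, h = h, g = g, r1 = r1, drz = drz,
    ihc_cutoff = ihc_cutoff, ihc_gain = ihc_gain,
    c_ihc = 1 - exp(-2 * pi * ihc_cutoff / fs),
    agc_tau = agc_tau,
    agc_c = 1 - exp(-1 / (agc_tau * fs)),
    agc_w = rep(1 / length(agc_tau), length(agc_tau)),
    agc_strength = agc_strength,
    ohc_vel_scale = 1000, ohc_vel_offset = 0.04,
    li_kernel = li_kernel,
    fixed_point = fixed_point
  ), class = "cochlea_config")
}

#' @export
print.cochlea_config <- function(x, ...) {
  cat(sprintf(
    "<cochlea_config: %d channels, fs = %g Hz, CF %.0f-%.0f Hz, FAC %s>\n",
    x$n_channels, x$fs, min(x$cf), max(x$cf),
    if (x$fac_enabled) "on" else "off"))
  invisible(x)
}

#' Analytic frequency response of the designed cascade
#'
#' Gain of the linear (FAC-off) cascade from input to each channel's BM
#' output, evaluated in closed form from the resonator coefficients. This is
#' independent of the time-domain simulation and serves as its design oracle.
#'
#' @param config A `cochlea_config`.
#' @param freq Frequencies in Hz.
#' @return Matrix `length(freq) x n_channels` of absolute gains.
#' @export
cascade_gain <- function(config, freq) {
  z <- exp(-1i * 2 * pi * freq / config$fs)  # z^{-1}
  r <- config$r1 + config$drz
  out <- matrix(0, length(freq), config$n_channels)
  acc <- rep(1 + 0i, length(freq))
  for (i in seq_len(config$n_channels)) {
    D <- 1 - 2 * config$a0[i] * r[i] * z + (r[i] * z)^2
    H <- config$g[i] * (D + config$h[i] * r[i] * config$c0[i] * z) / D
    acc <- acc * H
    out[, i] <- abs(acc)
  }
  out
}

#' Run the CAR-FAC cochlea over a waveform
#'
#' Sample-synchronous evaluation of the cascade: each channel filters its
#' predecessor's output. With `fac_enabled` the outer-hair-cell nonlinearity
#' and the AGC loop modulate per-channel damping (fast-acting compression);
#' otherwise the cascade is exactly linear. The inner hair cell applies
#' half-wave detection plus smoothing, and lateral inhibition combines
#' neighbouring channels into the spike-encoder drive `ihc_li`.
#'
#' @param signal An [audio_signal()] (its `fs` must match the config's).
#' @param config A `cochlea_config` from [design_filterbank()].
#' @return An object of class `cochleagram`: list with `bm` and `ihc_li`
#'   (`T x n_channels` matrices), `fs`, `cf`.
#' @export
cochlea_process <- function(signal, config) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "cochlea_config"))
  if (any(!is.finite(signal$samples))) stop("NaN/Inf in input", call. = FALSE)
  if (signal$fs != config$fs) {
    stop("signal fs (", signal$fs, ") != config fs (", config$fs, ")", call. = FALSE)
  }
  fp <- config$fixed_point
  res <- carfac_process_cpp(
    signal$samples, config$a0, config$c0, config$h, config$g,
    config$r1, config$drz, config$c_ihc,
    config$agc_c, config$agc_w, config$agc_strength,
    config$ohc_vel_scale, config$ohc_vel_offset,
    config$fac_enabled, config$ihc_gain,
    if (is.null(fp)) 0L else as.integer(fp$bm_bits),
    if (is.null(fp)) 0L else as.integer(fp$bm_frac),
    if (is.null(fp)) 0L else as.integer(fp$ihc_bits),
    if (is.null(fp)) 0L else as.integer(fp$ihc_frac))
  ihc_li <- lateral_inhibition(res$ihc, config$li_kernel)
  structure(list(bm = res$bm, ihc_li = ihc_li, fs = config$fs, cf = config$cf),
            class = "cochleagram")
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram: %d samples x %d channels @ %g Hz>\n",
              nrow(x$bm), ncol(x$bm), x$fs))
  invisible(x)
}

#' Lateral inhibition across frequency channels
#'
#' Each channel's output is its value minus kernel-weighted neighbour values,
#' floored at zero. The kernel is an odd-length vector of weights for channel
#' offsets `-h..h`; the centre entry is ignored. At the channel edges the
#' truncated kernel is renormalised so the available neighbour weights sum to
#' the full kernel's neighbour-weight total.
#'
#' @param ihc Numeric vector (one frame) or `T x n_channels` matrix.
#' @param kernel Odd-length numeric kernel (default `c(0.5, 0, 0.5)`).
#' @return Same shape as `ihc`, nonnegative.
#' @export
lateral_inhibition <- function(ihc, kernel = c(0.5, 0, 0.5)) {
  if (length(kernel) %% 2 != 1) stop("kernel length must be odd", call. = FALSE)
  vec_in <- is.null(dim(ihc))
  m <- if (vec_in) matrix(ihc, nrow = 1) else ihc
  n <- ncol(m)
  half <- (length(kernel) - 1) / 2
  w <- kernel
  w[half + 1] <- 0
  wsum <- sum(w)
  sub <- matrix(0, nrow(m), n)
  off <- seq(-half, half)
  for (ch in seq_len(n)) {
    ok <- ch + off >= 1 & ch + off <= n & off != 0
    ww <- w[ok]
    avail <- sum(ww)
    if (wsum > 0 && avail > 0) ww <- ww * (wsum / avail)
    cols <- ch + off[ok]
    if (length(cols)) sub[, ch] <- as.matrix(m[, cols, drop = FALSE]) %*% ww
  }
  out <- pmax(m - sub, 0)
  if (vec_in) drop(out) else out
}
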