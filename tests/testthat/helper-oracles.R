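# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain loops, literal rule
# application.

# scalar LIF simulation over a drive matrix, one neuron per
# (channel, threshold), spike on strict >, same-sample reset
naive_lif_encode <- function(drive, fs, tau_lif, thresholds, v_reset = 0) {
  c_lif <- 1 / (fs * tau_lif)
  out <- NULL
  for (ch in seq_len(ncol(drive))) {
    for (k in seq_along(thresholds)) {
      v <- 0
      for (t in seq_len(nrow(drive))) {
        v <- v + c_lif * (drive[t, ch] - v)
        if (v > thresholds[k]) {
          out <- rbind(out, c(t - 1L, ch, k, 1L))
          v <- v_reset
        }
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(t = integer(), channel = integer(),
                      threshold_id = integer(), neuron_id = integer()))
  }
  df <- data.frame(t = out[, 1], channel = out[, 2],
                   threshold_id = out[, 3], neuron_id = out[, 4])
  df[order(df$t, df$channel, df$threshold_id), , drop = FALSE]
}

# literal FEAST learning rules with loop arithmetic
naive_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

naive_learn_step <- function(ec, W, Vth, dI, dE, eta) {
  m <- nrow(W)
  sims <- numeric(m)
  for (i in seq_len(m)) sims[i] <- naive_cosine(ec, W[i, ])
  winner <- NA_integer_
  best <- -Inf
  for (i in seq_len(m)) {
    if (sims[i] >= Vth[i] && sims[i] > best) {
      best <- sims[i]
      winner <- i
    }
  }
  if (!is.na(winner)) {
    Vth[winner] <- min(1, Vth[winner] + dI)
    W[winner, ] <- (1 - eta) * W[winner, ] + eta * ec
  } else {
    for (i in seq_len(m)) Vth[i] <- max(0, Vth[i] - dE)
  }
  list(winner = winner, W = W, Vth = Vth)
}

naive_extract_winner <- function(ec, W) {
  best <- -Inf; winner <- NA_integer_
  for (i in seq_len(nrow(W))) {
    s <- naive_cosine(ec, W[i, ])
    if (s > best) { best <- s; winner <- i }
  }
  winner
}

# histogram loop for time binning: counts per (bin, channel, unit) with the
# documented flattening (bin fastest, then channel, then unit)
naive_time_bin <- function(t, channel, unit, n_bins, duration, n_channels, n_units) {
  vec <- numeric(n_bins * n_channels * n_units)
  for (i in seq_along(t)) {
    b <- min(n_bins, floor(t[i] / duration * n_bins) + 1)
    idx <- ((unit[i] - 1) * n_channels + (channel[i] - 1)) * n_bins + b
    vec[idx] <- vec[idx] + 1
  }
  vec
}

# random sparse event stream: at most one event per (t, channel)
random_stream <- function(n_events, n_channels, t_max, seed, fs = 16000) {
  set.seed(seed)
  df <- unique(data.frame(
    t = sample.int(t_max, n_events, replace = TRUE),
    channel = sample.int(n_channels, n_events, replace = TRUE)))
  df <- df[order(df$t, df$channel), , drop = FALSE]
  df$threshold_id <- 1L
  df$neuron_id <- 1L
  rownames(df) <- NULL
  event_stream(df, fs, n_channels, source = "random_stream")
}

# well-separated nonnegative prototype vectors with unit anchors, plus
# jittered samples around them
make_prototypes <- function(m, d, seed) {
  set.seed(seed)
  protos <- matrix(0, m, d)
  for (i in seq_len(m)) {
    nz <- ((i - 1) * floor(d / m)) + seq_len(floor(d / m))
    protos[i, nz] <- runif(length(nz), 0.5, 1)
    protos[i, d] <- 1  # anchor-like cell shared by all
  }
  protos
}

jitter_samples <- function(protos, n_per, sd_frac, seed) {
  set.seed(seed)
  out <- NULL
  labels <- integer()
  for (i in seq_len(nrow(protos))) {
    for (r in seq_len(n_per)) {
      x <- pmax(0, protos[i, ] * (1 + rnorm(ncol(protos), 0, sd_frac)))
      out <- rbind(out, x)
      labels <- c(labels, i)
    }
  }
  rownames(out) <- NULL
  list(x = out, labels = labels)
}
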