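#' FEAST hyper-parameters
#'
#' Feature Extraction using Adaptive Selection Thresholds: `m` competing
#' neurons, each holding a weight vector the shape of an event context and an
#' adaptive cosine-similarity acceptance threshold in `[0, 1]`. During
#' learning a winner raises its own threshold by `delta_i` and mixes the
#' presented context into its weights with rate `eta`; when no neuron's
#' similarity reaches its threshold, every threshold drops by `delta_e`.
#' This balances firing rates across neurons.
#'
#' @param m Neurons per bank (typical 8, 16, 32 or 64).
#' @param delta_i Threshold increase on a win (default 0.001).
#' @param delta_e Global threshold decrease when no neuron wins (default 0.003).
#' @param eta Weight mixing rate (default 0.001).
#' @param epochs Training passes over the batch (default 10).
#' @param seed RNG seed for initialisation and per-epoch shuffling.
#' @param tol Optional early-stop: stop when an epoch's mean `|dW|` falls
#'   below `tol` (default 1e-5; set 0 to disable).
#' @return A list of class `feast_params`.
#' @export
feast_params <- function(m = 32, delta_i = 0.001, delta_e = 0.003,
                         eta = 0.001, epochs = 10, seed = 42, tol = 1e-5) {
  stopifnot(m >= 1, delta_i > 0, delta_e > 0, eta > 0, eta < 1, epochs >= 0)
  structure(list(m = as.integer(m), delta_i = delta_i, delta_e = delta_e,
                 eta = eta, epochs = as.integer(epochs),
                 seed = as.integer(seed), tol = tol),
            class = "feast_params")
}

#' Cosine similarity between a context and a neuron
#'
#' @param ec Flattened event context (nonnegative, not all zero).
#' @param w Neuron weight vector, same length.
#' @return `dot(ec, w) / (||ec|| * ||w||)`.
#' @export
similarity <- function(ec, w) {
  if (length(ec) != length(w)) stop("shape mismatch", call. = FALSE)
  ne <- sqrt(sum(ec^2))
  nw <- sqrt(sum(w^2))
  if (ne == 0 || nw == 0) {
    stop("zero-norm vector: a valid event context has its anchor at 1.0",
         call. = FALSE)
  }
  sum(ec * w) / (ne * nw)
}

#' Initialise a FEAST neuron bank
#'
#' Weights drawn elementwise from a seeded uniform (0,1) then L2-normalised;
#' thresholds uniform (0,1).
#'
#' @param params A [feast_params()].
#' @param d Context length (e.g. `n_samples` or `scale * n_samples`).
#' @param scale Channel count of the bank's contexts (1 for temporal).
#' @return An object of class `feast_bank` with `W` (`m x d`), `Vth`,
#'   `scale`, `trained`, `log`.
#' @export
feast_init <- function(params, d, scale = 1) {
  set.seed(params$seed)
  W <- matrix(runif(params$m * d), params$m, d)
  W <- W / sqrt(rowSums(W^2))
  Vth <- runif(params$m)
  structure(list(W = W, Vth = Vth, scale = as.integer(scale),
                 params = params, trained = FALSE,
                 log = list(mean_dw = numeric(), wins = NULL)),
            class = "feast_bank")
}

#' @export
print.feast_bank <- function(x, ...) {
  cat(sprintf("<feast_bank: %d neurons x %d weights, scale %d, %s>\n",
              nrow(x$W), ncol(x$W), x$scale,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' One FEAST learning step
#'
#' Candidates are neurons whose similarity to `ec` is at least their own
#' threshold; the winner is the candidate of largest similarity (ties to the
#' lowest index). A winner's threshold rises by `delta_i` (clamped at 1) and
#' its weights move toward `ec` by the mixing rate; with no winner all
#' thresholds fall by `delta_e` (clamped at 0) and weights are untouched.
#'
#' @param ec Flattened event context.
#' @param bank A `feast_bank`.
#' @param params A [feast_params()] (defaults to the bank's own).
#' @return List with `winner` (index or `NA`) and the updated `bank`.
#' @export
learn_step <- function(ec, bank, params = bank$params) {
  sims <- vapply(seq_len(nrow(bank$W)), function(i) similarity(ec, bank$W[i, ]),
                 numeric(1))
  eligible <- which(sims >= bank$Vth)
  if (length(eligible)) {
    w <- eligible[which.max(sims[eligible])]
    bank$Vth[w] <- min(1, bank$Vth[w] + params$delta_i)
    bank$W[w, ] <- (1 - params$eta) * bank$W[w, ] + params$eta * ec
    list(winner = w, bank = bank)
  } else {
    bank$Vth <- pmax(0, bank$Vth - params$delta_e)
    list(winner = NA_integer_, bank = bank)
  }
}

#' Train a FEAST neuron bank on an event-context batch
#'
#' Initialises `m` neurons (seeded) and presents the contexts in a fresh
#' random order each epoch, applying [learn_step()] to every presentation
#' (compiled inner loop; identical decisions to the R reference). Per-epoch
#' mean `|dW|` and win counts are recorded in `bank$log`.
#'
#' @param ecs An `ec_batch` (or bare matrix, one context per row).
#' @param params A [feast_params()].
#' @param scale Recorded bank scale (taken from the batch if given one).
#' @return A trained `feast_bank`.
#' @export
feast_train <- function(ecs, params, scale = NULL) {
  mat <- if (inherits(ecs, "ec_batch")) ecs$ec else ecs
  if (is.null(scale)) scale <- if (inherits(ecs, "ec_batch")) ecs$scale else 1L
  n <- nrow(mat)
  if (n == 0) stop("empty context batch", call. = FALSE)
  if (n < params$m) {
    warning("fewer contexts (", n, ") than neurons (", params$m,
            "): features underdetermined", call. = FALSE)
  }
  bank <- feast_init(params, ncol(mat), scale)
  if (params$epochs == 0) return(bank)
  # all shuffles drawn up-front from the seeded RNG (feast_init seeded it)
  order <- vapply(seq_len(params$epochs), function(e) sample.int(n),
                  integer(n))
  if (!is.matrix(order)) order <- matrix(order, nrow = n)
  res <- feast_train_cpp(mat, bank$W, bank$Vth, params$delta_i,
                         params$delta_e, params$eta, order, params$tol)
  bank$W <- res$W
  bank$Vth <- res$Vth
  bank$trained <- TRUE
  bank$log <- list(mean_dw = as.numeric(res$mean_dw), wins = res$wins)
  bank
}

#' Extract feature maps from an event stream
#'
#' With frozen, trained banks, every event with a valid context emits exactly
#' one feature spike per bank: the argmax-cosine neuron (thresholds are
#' ignored during extraction) fires at the event's time and channel in its
#' feature space. Events whose context was skipped produce no feature spike.
#'
#' @param stream An [event_stream()].
#' @param banks A single trained `feast_bank` or a list of banks (one per
#'   scale).
#' @param params An [ec_params()].
#' @return A list of `feature_map` objects (one per bank): event streams
#'   whose events carry `winner_id` and `scale` columns.
#' @export
feast_extract <- function(stream, banks, params) {
  if (inherits(banks, "feast_bank")) banks <- list(banks)
  lapply(banks, function(bank) {
    if (!isTRUE(bank$trained)) stop("bank is untrained", call. = FALSE)
    batch <- ec_batch(stream, params, scale = bank$scale)
    winner <- ec_winners(batch$ec, bank$W)
    ev <- data.frame(t = batch$anchor$t, channel = batch$anchor$channel,
                     threshold_id = 1L, neuron_id = 1L,
                     winner_id = winner, scale = bank$scale)
    fm <- event_stream(ev, stream$fs, stream$n_channels,
                       source = sprintf("feast_extract scale=%d", bank$scale))
    fm$m <- nrow(bank$W)
    class(fm) <- c("feature_map", class(fm))
    fm
  })
}

# argmax cosine winner per context row, ties to lowest index
ec_winners <- function(ec, W) {
  if (nrow(ec) == 0) return(integer())
  en <- ec / sqrt(rowSums(ec^2))
  Wn <- W / sqrt(rowSums(W^2))
  max.col(en %*% t(Wn), ties.method = "first")
}

#' Serialize / restore a FEAST bank (JSON metadata + CSV weight matrix)
#'
#' Full-precision round trip: weights and thresholds are written with 17
#' significant digits, so `read_bank(write_bank(b, p))` reproduces `b`
#' exactly.
#'
#' @param bank A `feast_bank`. @param path Basename; writes `<path>.json`
#'   and `<path>_W.csv`.
#' @return `path` invisibly (writer); a `feast_bank` (reader).
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "feast_bank"))
  meta <- list(m = nrow(bank$W), d = ncol(bank$W), scale = bank$scale,
               trained = bank$trained,
               Vth = sprintf("%.17g", bank$Vth),
               params = unclass(bank$params)[c("m", "delta_i", "delta_e",
                                               "eta", "epochs", "seed", "tol")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  Wchr <- apply(bank$W, 2, function(col) sprintf("%.17g", col))
  write.table(Wchr, paste0(path, "_W.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  W <- as.matrix(read.csv(paste0(path, "_W.csv"), header = FALSE,
                          colClasses = "numeric"))
  dimnames(W) <- NULL
  p <- meta$params
  params <- feast_params(p$m, p$delta_i, p$delta_e, p$eta, p$epochs, p$seed, p$tol)
  structure(list(W = W, Vth = as.numeric(meta$Vth),
                 scale = as.integer(meta$scale), params = params,
                 trained = isTRUE(meta$trained),
                 log = list(mean_dw = numeric(), wins = NULL)),
            class = "feast_bank")
}
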