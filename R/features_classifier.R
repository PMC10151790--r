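#' Fixed time binning of a feature map or event stream
#'
#' Divides `[0, duration)` into `n_bins` equal bins and counts spikes per
#' (bin, channel, unit), where the unit axis is the winning neuron for a
#' feature map (`winner_id`) and a single unit for a raw spike stream. The
#' vector is flattened deterministically: bin index fastest, then channel,
#' then unit (`idx = ((unit-1)*n_channels + channel-1)*n_bins + bin`).
#'
#' @param map A `feature_map` or [event_stream()].
#' @param n_bins Bins per utterance (default 5).
#' @param duration Utterance duration in samples (default: one past the last
#'   spike). Spikes at `t >= duration` land in the last bin.
#' @param label Optional class label carried through to the classifier.
#' @return An object of class `binned_feature`: `vector`, `n_bins`,
#'   `n_channels`, `n_units`, `label`.
#' @export
time_bin <- function(map, n_bins = 5, duration = NULL, label = NA) {
  stopifnot(inherits(map, "event_stream"))
  ev <- map$events
  n_channels <- map$n_channels
  n_units <- if (!is.null(map$m)) map$m else 1L
  if (is.null(duration)) {
    duration <- if (nrow(ev)) max(ev$t) + 1 else 1
  }
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  vec <- numeric(n_bins * n_channels * n_units)
  if (nrow(ev)) {
    bin <- pmin(n_bins, floor(ev$t / duration * n_bins) + 1)
    unit <- if ("winner_id" %in% names(ev)) ev$winner_id else rep(1L, nrow(ev))
    idx <- ((unit - 1L) * n_channels + (ev$channel - 1L)) * n_bins + bin
    tab <- tabulate(idx, nbins = length(vec))
    vec <- as.numeric(tab)
  }
  structure(list(vector = vec, n_bins = as.integer(n_bins),
                 n_channels = n_channels, n_units = as.integer(n_units),
                 label = label),
            class = "binned_feature")
}

#' Baseline features: time-binned cochlear spikes
#'
#' The no-FEAST baseline: [time_bin()] applied directly to the cochlear
#' spike stream.
#'
#' @inheritParams time_bin
#' @param stream An [event_stream()].
#' @return A `binned_feature`.
#' @export
baseline_features <- function(stream, n_bins = 5, duration = NULL, label = NA) {
  time_bin(stream, n_bins = n_bins, duration = duration, label = label)
}

#' Stack binned features into a matrix
#'
#' @param features List of `binned_feature` objects (or plain numeric
#'   vectors, e.g. concatenated multi-bank features).
#' @return List with `x` (matrix, one row per item) and `y` (labels, if the
#'   items carry them).
#' @export
features_matrix <- function(features) {
  vecs <- lapply(features, function(f) if (inherits(f, "binned_feature")) f$vector else f)
  x <- do.call(rbind, vecs)
  y <- vapply(features, function(f) {
    if (inherits(f, "binned_feature")) as.character(f$label) else NA_character_
  }, character(1))
  list(x = x, y = y)
}

#' Linear-classifier evaluation
#'
#' Fits an L2-regularised multinomial linear model (ridge logistic
#' regression via glmnet) on the training features, choosing the
#' regularisation constant by k-fold cross-validation on the training set
#' only, then reports held-out accuracy and the confusion matrix. Feature
#' vectors are L2-normalised before fitting. With fixed `seed` the report is
#' fully deterministic (fold assignment is the only randomness).
#'
#' @param train_x,train_y Training matrix (rows = utterances) and labels.
#' @param test_x,test_y Held-out matrix and labels.
#' @param seed Seed for the cross-validation fold assignment.
#' @param nfolds Cross-validation folds (default 5).
#' @param train_ids,test_ids Optional utterance ids; any overlap is an error
#'   (label leakage).
#' @return An object of class `eval_report`: `accuracy`, `confusion`,
#'   `lambda`, `config`.
#' @export
evaluate_linear <- function(train_x, train_y, test_x, test_y, seed = 1,
                            nfolds = 5, train_ids = NULL, test_ids = NULL) {
  if (!is.null(train_ids) && !is.null(test_ids) &&
      length(intersect(train_ids, test_ids)) > 0) {
    stop("train/test share utterance ids (label leakage)", call. = FALSE)
  }
  train_y <- as.character(train_y)
  test_y <- as.character(test_y)
  classes <- sort(unique(train_y))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  l2norm <- function(x) {
    n <- sqrt(rowSums(x^2))
    n[n == 0] <- 1
    x / n
  }
  xtr <- Matrix::Matrix(l2norm(as.matrix(train_x)), sparse = TRUE)
  xte <- Matrix::Matrix(l2norm(as.matrix(test_x)), sparse = TRUE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), nrow(xtr)))
  cv <- glmnet::cv.glmnet(xtr, factor(train_y, levels = classes),
                          family = "multinomial", alpha = 0,
                          foldid = foldid, type.measure = "class",
                          standardize = FALSE, nlambda = 30)
  pred <- as.character(predict(cv, xte, s = "lambda.min", type = "class"))
  acc <- mean(pred == test_y)
  confusion <- table(truth = factor(test_y, levels = classes),
                     predicted = factor(pred, levels = classes))
  structure(list(accuracy = acc, confusion = confusion,
                 lambda = cv$lambda.min,
                 config = list(seed = seed, nfolds = nfolds,
                               n_train = nrow(xtr), n_test = nrow(xte),
                               classes = classes)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.4f (%d train / %d test, %d classes)>\n",
              x$accuracy, x$config$n_train, x$config$n_test,
              length(x$config$classes)))
  print(x$confusion)
  invisible(x)
}
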