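#' Initialise the student network's parameters
#'
#' The student is a multilayer perceptron mapping a 61-band dB spectrum to
#' a single instantaneous loudness level in phons: 61 inputs, three hidden
#' layers of 150 rectified-linear units, one linear output. Weights are
#' drawn from a fan-in-scaled normal distribution (He initialisation,
#' `sd = sqrt(2 / fan_in)`); biases start at zero.
#'
#' @param seed integer seed.
#' @param sizes layer sizes, default `c(61, 150, 150, 150, 1)`.
#' @return an object of class `mlp_params`: lists `weights` and `biases`
#'   plus the layer sizes and activation tags.
#' @export
init_params <- function(seed = 1, sizes = c(61, 150, 150, 150, 1)) {
  if (length(sizes) < 2) stop("need at least an input and an output layer")
  with_seed(seed, {
    weights <- lapply(seq_len(length(sizes) - 1), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             nrow = sizes[l], ncol = sizes[l + 1])
    })
    biases <- lapply(sizes[-1], function(m) numeric(m))
    structure(list(sizes = sizes, weights = weights, biases = biases,
                   activations = c(rep("relu", length(sizes) - 2), "linear"),
                   seed = as.integer(seed)),
              class = "mlp_params")
  })
}

#' @export
print.mlp_params <- function(x, ...) {
  cat("mlp_params:", paste(x$sizes, collapse = " -> "),
      sprintf("(%d weights)\n",
              sum(vapply(x$weights, length, numeric(1))) +
                sum(vapply(x$biases, length, numeric(1)))))
  invisible(x)
}

#' Forward pass of the student network
#'
#' Affine transform and rectification through the hidden layers, then a
#' linear output unit. Deterministic.
#'
#' @param params an [init_params()] object.
#' @param x input: a length-61 vector, or an `n x 61` matrix of band
#'   spectra (rows = frames). A 61 x n band-spectrum matrix from
#'   [band_spectrum()] can be passed transposed.
#' @return numeric vector of predicted loudness levels in phons.
#' @export
mlp_forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$sizes[1]) {
    stop("input has ", ncol(x), " columns; expected ", params$sizes[1])
  }
  if (!is.null(params$input_center)) {
    x <- sweep(sweep(x, 2, params$input_center), 2, params$input_scale, `/`)
  }
  as.numeric(.mlp_forward_cpp(x, params$weights, params$biases))
}

#' Training configuration
#'
#' @param epochs number of complete passes over the training rows.
#' @param batch_size minibatch size (default 512).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters (defaults
#'   are the standard published ones: 0.001, 0.9, 0.999, 1e-8).
#' @param seed seed controlling initialisation and batch shuffling.
#' @param checkpoints epochs at which validation error is additionally
#'   reported via message (history records every epoch regardless).
#' @param verbose print progress messages.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 500, batch_size = 512,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1,
                         checkpoints = c(22, 100, 500), verbose = FALSE) {
  if (epochs < 1) stop("epochs must be at least 1")
  if (batch_size < 1) stop("batch_size must be at least 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, seed = as.integer(seed),
                 checkpoints = checkpoints, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train the student network by distillation
#'
#' Minimises the mean squared error between the network output and the
#' teacher's loudness labels (monitored as its square root, the RMS error
#' in phons) with the Adam optimiser on shuffled minibatches. Fully
#' reproducible given the config seed.
#'
#' @param data a `labelled_dataset` from [build_corpus()] (must contain
#'   both train and validation rows).
#' @param cfg a [train_config()].
#' @return a list with `params` (trained [init_params()] object) and
#'   `history` (data frame with per-epoch `epoch`, `train_rms`, `val_rms`
#'   in phons).
#' @export
train_mlp <- function(data, cfg = train_config()) {
  stopifnot(inherits(data, "labelled_dataset"),
            inherits(cfg, "train_config"))
  tr <- data$split == "train"
  if (!any(tr) || !any(!tr)) {
    stop("dataset needs both train and validation rows")
  }
  x_tr <- data$inputs[tr, , drop = FALSE]
  y_tr <- data$labels[tr]
  x_va <- data$inputs[!tr, , drop = FALSE]
  y_va <- data$labels[!tr]

  params <- init_params(cfg$seed, c(ncol(x_tr), 150, 150, 150, 1))
  # standardise inputs by the training-set band statistics: an exact affine
  # reparametrisation of the first layer (the dB-in/phon-out interface is
  # unchanged) that conditions the optimisation
  params$input_center <- colMeans(x_tr)
  params$input_scale <- pmax(apply(x_tr, 2, stats::sd), 1e-6)
  x_tr <- sweep(sweep(x_tr, 2, params$input_center), 2,
                params$input_scale, `/`)
  x_va <- sweep(sweep(x_va, 2, params$input_center), 2,
                params$input_scale, `/`)
  # the compiled epoch kernel updates weights, biases and Adam moments in
  # place, so the buffers below are shared with `params` throughout
  w <- params$weights
  b <- params$biases
  mw <- lapply(w, function(m) m * 0)
  vw <- lapply(w, function(m) m * 0)
  mb <- lapply(b, function(v) v * 0)
  vb <- lapply(b, function(v) v * 0)
  n <- nrow(x_tr)
  history <- data.frame(epoch = seq_len(cfg$epochs), train_rms = NA_real_,
                        val_rms = NA_real_)
  steps_per_epoch <- length(seq(1, n, by = cfg$batch_size))

  with_seed(cfg$seed + 1, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      sse <- .train_epoch_cpp(x_tr, y_tr, ord, w, b, mw, vw, mb, vb,
                              cfg$batch_size, cfg$learning_rate,
                              cfg$beta1, cfg$beta2, cfg$epsilon,
                              (epoch - 1L) * steps_per_epoch)
      history$train_rms[epoch] <- sqrt(sse / n)
      val_pred <- .mlp_forward_cpp(x_va, w, b)
      history$val_rms[epoch] <- sqrt(mean((val_pred - y_va)^2))
      if (cfg$verbose && (epoch %in% cfg$checkpoints ||
                          epoch %% 50 == 0 || epoch == cfg$epochs)) {
        message(sprintf("epoch %4d: train RMS %.3f, validation RMS %.3f",
                        epoch, history$train_rms[epoch],
                        history$val_rms[epoch]))
      }
    }
  })
  params$weights <- w
  params$biases <- b
  list(params = params, history = history)
}

#' Persist and restore student weights
#'
#' Single-file container (RDS) embedding a format version and the layer
#' sizes; both are validated on load, and the round trip is bit-exact.
#'
#' @param params an [init_params()] object (typically trained).
#' @param path file path.
#' @param meta optional named list stored alongside (e.g. training seed,
#'   corpus manifest hash).
#' @return `load_params()` returns the `mlp_params` object.
#' @export
save_params <- function(params, path, meta = list()) {
  stopifnot(inherits(params, "mlp_params"))
  saveRDS(list(format = "tvlnet-mlp", version = 1L, sizes = params$sizes,
               params = params, meta = meta), path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable weight file: ", path))
  if (!identical(obj$format, "tvlnet-mlp") || !identical(obj$version, 1L)) {
    stop("not a tvlnet weight file (or unsupported version): ", path)
  }
  p <- obj$params
  ok <- inherits(p, "mlp_params") &&
    identical(p$sizes, obj$sizes) &&
    all(vapply(seq_along(p$weights), function(l) {
      all(dim(p$weights[[l]]) == c(p$sizes[l], p$sizes[l + 1])) &&
        length(p$biases[[l]]) == p$sizes[l + 1]
    }, logical(1)))
  if (!ok) stop("weight file is corrupt (shape mismatch): ", path)
  p
}
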