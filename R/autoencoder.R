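#' Autoencoder hyperparameter configuration
#'
#' Collects every tunable of the stacked multiview convolutional autoencoder.
#' Defaults follow the reference real-data settings: kernel regularisation
#' 2.5e-3, dropout 10\% on the integrative Dense layers (none on the encoded
#' layer), Adam with learning rate 1e-4, batches of 48 CRMs, early stopping
#' with patience 5 and minimum delta 2.5e-4.
#'
#' @param kernel_len Length of every convolutional kernel along the position
#'   axis, in bins.
#' @param conv_filters Number of kernels in each convolutional layer.
#' @param deep_dim Neurons in each of the first three integrative Dense layers.
#' @param encoded_dim Width of the encoded (fourth Dense) layer. Defaults to
#'   `deep_dim`; the compression bottleneck is primarily the conv filter count.
#' @param learning_rate Adam base learning rate.
#' @param kernel_reg L2 penalty applied to all convolutional kernels.
#' @param dropout Dropout fraction on the non-encoded Dense layers.
#' @param loss_weights Optional list with numeric vectors `datasets` (length m)
#'   and/or `regulators` (length n); the per-cell loss weight is their product.
#' @param batch_size CRMs per training batch.
#' @param batches_per_epoch Batches drawn per epoch.
#' @param patience Early-stopping patience, in epochs.
#' @param min_delta Minimum epoch-loss improvement counted as progress.
#' @param max_epochs Hard cap on training epochs.
#' @param seed Seed covering weight initialization, dropout and data shuffling.
#' @return A list of class `anopeak_config`.
#' @export
model_config <- function(kernel_len = 20L, conv_filters = 16L, deep_dim = 32L,
                         encoded_dim = deep_dim, learning_rate = 1e-4,
                         kernel_reg = 2.5e-3, dropout = 0.10,
                         loss_weights = NULL, batch_size = 48L,
                         batches_per_epoch = 10L, patience = 5L,
                         min_delta = 2.5e-4, max_epochs = 48L, seed = 1L) {
  cfg <- list(kernel_len = as.integer(kernel_len),
              conv_filters = as.integer(conv_filters),
              deep_dim = as.integer(deep_dim),
              encoded_dim = as.integer(encoded_dim),
              learning_rate = learning_rate, kernel_reg = kernel_reg,
              dropout = dropout, loss_weights = loss_weights,
              batch_size = as.integer(batch_size),
              batches_per_epoch = as.integer(batches_per_epoch),
              patience = as.integer(patience), min_delta = min_delta,
              max_epochs = as.integer(max_epochs), seed = as.integer(seed))
  stopifnot(cfg$kernel_len > 0, cfg$conv_filters > 0, cfg$deep_dim > 0,
            cfg$encoded_dim > 0, cfg$learning_rate > 0,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$batch_size > 0,
            cfg$max_epochs > 0)
  class(cfg) <- "anopeak_config"
  cfg
}

#' Model configuration used for artificial-data experiments
#'
#' The default profile for simulated CRMs: deep dimension 32, 16 convolutional
#' filters, learning rate 1e-3 and at most 48 epochs with early stopping. The
#' kernel penalty is 0 here: on sparse uncrumbed artificial tensors the
#' real-data default (2.5e-3) exceeds the reconstruction term and collapses
#' the model to an empty rebuilding (see the methods vignette).
#'
#' @param ... Overrides passed on to [model_config()].
#' @return An `anopeak_config`.
#' @export
artificial_profile <- function(...) {
  args <- list(...)
  defaults <- list(deep_dim = 32L, conv_filters = 16L, learning_rate = 1e-3,
                   max_epochs = 48L, kernel_reg = 0)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' Build an (untrained) autoencoder for a given tensor shape
#'
#' The encoder stacks a dataset-combination convolution (window `kernel_len`
#' along X, spanning all m datasets, applied depthwise per regulator), a
#' regulator-combination convolution (spanning all n regulators and the
#' stage-1 filters), and four position-wise Dense layers; the decoder is a
#' convolution reading the whole encoded width followed by a final convolution
#' with one filter per (dataset, regulator) source, reshaped to the input
#' shape. There is no communication along X outside the conv windows.
#'
#' @param mconfig An [model_config()] object.
#' @param tensor_shape Integer vector `c(X, m, n)` of the (padded) tensors the
#'   model will see.
#' @return An object of class `anopeak_model`.
#' @export
build_model <- function(mconfig, tensor_shape) {
  stopifnot(inherits(mconfig, "anopeak_config"), length(tensor_shape) == 3)
  shape <- as.integer(tensor_shape)
  if (shape[1] <= 4L * mconfig$kernel_len) {
    stop("position axis (X = ", shape[1], ") must exceed 4 * kernel_len = ",
         4L * mconfig$kernel_len,
         "; increase the window or reduce kernel_len")
  }
  set.seed(mconfig$seed)
  model <- list(params = nn_init_params(shape, mconfig),
                config = mconfig, shape = shape,
                trained = FALSE, crumbed = FALSE,
                loss_history = numeric(0), best_epoch = NA_integer_)
  class(model) <- "anopeak_model"
  model
}

#' @export
print.anopeak_model <- function(x, ...) {
  cat("anopeak stacked multiview convolutional autoencoder\n")
  cat(sprintf("  tensor shape: X=%d, m=%d datasets, n=%d regulators\n",
              x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  kernel_len=%d, filters=%d, deep_dim=%d, encoded_dim=%d\n",
              x$config$kernel_len, x$config$conv_filters, x$config$deep_dim,
              x$config$encoded_dim))
  if (x$trained) {
    cat(sprintf("  trained: %d epochs, best epoch %d (loss %.5g)\n",
                length(x$loss_history), x$best_epoch,
                x$loss_history[x$best_epoch]))
  } else cat("  untrained\n")
  invisible(x)
}

#' Train the autoencoder
#'
#' Minimizes the (optionally per-dataset / per-regulator weighted) mean squared
#' reconstruction error with Adam, drawing `batches_per_epoch` batches of
#' `batch_size` tensors per epoch. Training stops early when the epoch loss
#' has not improved by at least `min_delta` for `patience` epochs; the weights
#' of the best epoch are kept. Fully deterministic given `mconfig$seed`.
#'
#' @param model An untrained or trained `anopeak_model`.
#' @param tensors A [tensor_set()] of training tensors matching the model shape.
#' @param verbose Print per-epoch losses.
#' @return The trained `anopeak_model` (loss history, best epoch, weights of
#'   the best epoch).
#' @export
train_model <- function(model, tensors, verbose = FALSE) {
  stopifnot(inherits(model, "anopeak_model"), inherits(tensors, "tensor_set"))
  if (!all(tensors$shape == model$shape)) {
    stop("tensor shape ", paste(tensors$shape, collapse = "x"),
         " does not match model shape ", paste(model$shape, collapse = "x"))
  }
  cfg <- model$config
  set.seed(cfg$seed + 1L)
  p <- model$params
  st <- nn_adam_init(p)
  wcell <- nn_cell_weights(model$shape, cfg)
  N <- ncol(tensors$data)
  per_epoch <- cfg$batch_size * cfg$batches_per_epoch

  best_raw <- Inf    # lowest epoch loss: these weights are kept
  es_best <- Inf     # early-stopping reference (min_delta applies here)
  best_p <- p
  best_epoch <- 0L
  wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(N, per_epoch, replace = per_epoch > N)
    losses <- numeric(cfg$batches_per_epoch)
    for (b in seq_len(cfg$batches_per_epoch)) {
      cols <- idx[((b - 1L) * cfg$batch_size + 1L):(b * cfg$batch_size)]
      xb <- tensors$data[, cols, drop = FALSE]
      lg <- nn_loss_grads(p, xb, model$shape, cfg, wcell)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             " (loss = ", lg$loss, "); reduce the learning rate")
      }
      upd <- nn_adam_step(p, lg$grads, st, cfg$learning_rate)
      p <- upd$p
      st <- upd$st
      losses[b] <- lg$loss
    }
    epoch_loss <- mean(losses)
    history <- c(history, epoch_loss)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.6f", epoch, epoch_loss))
    }
    if (epoch_loss < best_raw) {
      best_raw <- epoch_loss
      best_p <- p
      best_epoch <- epoch
    }
    if (epoch_loss < es_best - cfg$min_delta) {
      es_best <- epoch_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best_p
  model$trained <- TRUE
  model$crumbed <- isTRUE(tensors$crumbed)
  model$loss_history <- history
  model$best_epoch <- best_epoch
  model$margin <- tensors$margin
  model$bin_size <- tensors$bin_size
  model
}

#' Reconstruct a tensor through the trained model
#'
#' `reconstruct()` is generic so that any function mapping a tensor to a tensor
#' of the same shape (an oracle or degenerate reconstructor) can stand in for
#' a trained model in the scoring, calibration and evaluation machinery.
#'
#' @param model An `anopeak_model`, or a function `tensor -> tensor`.
#' @param tensor A [crm_tensor] (or 3D array) matching the model shape.
#' @return A `crm_tensor` of identical geometry holding the reconstruction
#'   (raw values; they may be negative).
#' @export
reconstruct <- function(model, tensor) UseMethod("reconstruct")

#' @export
reconstruct.anopeak_model <- function(model, tensor) {
  vals <- tensor_values(tensor)
  if (!all(dim(vals) == model$shape)) stop("tensor shape does not match model")
  xb <- matrix(as.vector(vals), ncol = 1)
  out <- nn_forward(model$params, xb, model$shape, model$config)$out
  rec <- nn_out_to_tensor(out, model$shape, 1L)
  tensor_like(tensor, array(rec, dim = model$shape))
}

#' @export
reconstruct.function <- function(model, tensor) {
  vals <- tensor_values(tensor)
  out <- model(vals)
  if (!all(dim(out) == dim(vals))) stop("reconstructor changed the tensor shape")
  tensor_like(tensor, out)
}

#' Reconstruct every tensor of a set (batched)
#'
#' @param model An `anopeak_model` or reconstructor function.
#' @param tensors A [tensor_set()].
#' @param chunk Tensors per forward batch.
#' @return A matrix of flattened reconstructions, same dims as `tensors$data`.
#' @export
reconstruct_set <- function(model, tensors, chunk = 64L) {
  stopifnot(inherits(tensors, "tensor_set"))
  N <- ncol(tensors$data)
  if (is.function(model)) {
    out <- vapply(seq_len(N), function(j) {
      v <- array(tensors$data[, j], dim = tensors$shape)
      as.vector(model(v))
    }, numeric(nrow(tensors$data)))
    return(matrix(out, nrow = nrow(tensors$data)))
  }
  stopifnot(inherits(model, "anopeak_model"))
  if (!all(tensors$shape == model$shape)) stop("tensor shape does not match model")
  res <- matrix(0, nrow(tensors$data), N)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    xb <- tensors$data[, s:e, drop = FALSE]
    out <- nn_forward(model$params, xb, model$shape, model$config)$out
    res[, s:e] <- nn_out_to_tensor(out, model$shape, ncol(xb))
  }
  res
}

#' Encoded-layer activations for a single tensor
#'
#' @param model A trained `anopeak_model`.
#' @param tensor A [crm_tensor] or 3D array matching the model shape.
#' @return A matrix (encoded_dim x X) of ReLU activations of the encoded layer.
#' @export
encode <- function(model, tensor) {
  stopifnot(inherits(model, "anopeak_model"))
  vals <- tensor_values(tensor)
  xb <- matrix(as.vector(vals), ncol = 1)
  nn_forward(model$params, xb, model$shape, model$config)$enc
}
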