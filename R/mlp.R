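#' Training configuration for the local MLP
#'
#' Defaults follow the study's stochastic-gradient-descent recipe: initial
#' learning rate 0.01 with an exponential decay factor of 0.95 applied per
#' epoch, minibatches of 32, and 150 epochs, with no explicit regularization.
#' Class imbalance is handled by per-sample loss weights inversely
#' proportional to class frequency (see [class_weights()]).
#'
#' @param learning_rate initial SGD learning rate (default 0.01)
#' @param lr_decay multiplicative decay applied once per epoch (default 0.95).
#'   The learning rate at (global) epoch `e` (0-based) is
#'   `learning_rate * lr_decay^e`.
#' @param batch_size minibatch size (default 32)
#' @param epochs number of passes over the training data (default 150)
#' @param standardize if `TRUE` (default), features are z-scored using
#'   training-set statistics before entering the network
#' @param seed integer seed controlling the per-epoch minibatch shuffle
#' @return an object of class `training_config`
#' @export
training_config <- function(learning_rate = 0.01, lr_decay = 0.95,
                            batch_size = 32L, epochs = 150L,
                            standardize = TRUE, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must lie in (0, 1]")
  if (batch_size < 1L) stop("batch_size must be positive")
  if (epochs < 0L) stop("epochs must be nonnegative")
  structure(
    list(learning_rate = learning_rate, lr_decay = lr_decay,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         standardize = isTRUE(standardize), seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Initialize MLP parameters
#'
#' Weights are drawn uniformly in `+-sqrt(6 / (fan_in + fan_out))` (Glorot
#' uniform); biases start at zero. The default architecture is
#' 176 -> 20 -> 20 -> 1: two ReLU hidden layers of 20 units and a single
#' sigmoid output unit for binary CU/CI classification.
#'
#' @param layer_sizes integer vector of at least two positive layer widths,
#'   input first, output last
#' @param seed integer RNG seed
#' @return an object of class `model_params`: a list of layers, each a list
#'   with weight matrix `W` (`fan_in x fan_out`) and bias vector `b`
#' @export
init_params <- function(layer_sizes = c(176L, 20L, 20L, 1L), seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stop("at least two layer sizes are required")
  if (any(layer_sizes < 1L)) stop("all layer sizes must be positive")
  set.seed(seed)
  layers <- vector("list", length(layer_sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- layer_sizes[l]
    fan_out <- layer_sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim),
                 nrow = fan_in, ncol = fan_out),
      b = rep(0, fan_out)
    )
  }
  structure(layers, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  dims <- vapply(x, function(l) nrow(l$W), integer(1))
  dims <- c(dims, ncol(x[[length(x)]]$W))
  cat(sprintf("<model_params> %s (%d parameters)\n",
              paste(dims, collapse = " -> "), count_params(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param params a `model_params` object
#' @return integer count of weight and bias entries
#' @export
count_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Flatten parameters to a single numeric vector
#'
#' Weights and biases of all layers concatenated in layer order; the
#' representation over which aggregation distances are computed.
#'
#' @param params a `model_params` object
#' @return numeric vector
#' @export
flatten_params <- function(params) {
  unlist(lapply(params, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)
}

#' Rebuild a parameter tree from a flat vector
#'
#' Inverse of [flatten_params()] given a shape template.
#'
#' @param template a `model_params` object providing the layer shapes
#' @param values numeric vector of length `count_params(template)`
#' @return a `model_params` object with the given values
#' @export
unflatten_params <- function(template, values) {
  if (length(values) != count_params(template)) {
    stop("values length does not match the template's parameter count")
  }
  pos <- 0L
  for (l in seq_along(template)) {
    nw <- length(template[[l]]$W)
    template[[l]]$W <- matrix(values[pos + seq_len(nw)],
                              nrow = nrow(template[[l]]$W))
    pos <- pos + nw
    nb <- length(template[[l]]$b)
    template[[l]]$b <- values[pos + seq_len(nb)]
    pos <- pos + nb
  }
  template
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the MLP
#'
#' ReLU activations on the hidden layers, sigmoid on the single output unit.
#'
#' @param params a `model_params` object
#' @param X numeric matrix (`n x input_size`) or a [feature_table()]
#' @return numeric vector of probabilities in (0, 1), one per row
#' @export
mlp_forward <- function(params, X) {
  if (inherits(X, "feature_table")) X <- X$features
  X <- as.matrix(X)
  if (ncol(X) != nrow(params[[1]]$W)) {
    stop("input has ", ncol(X), " columns but the model expects ",
         nrow(params[[1]]$W))
  }
  a <- X
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- sweep(a %*% params[[l]]$W, 2L, params[[l]]$b, "+")
    a <- if (l < n_layers) pmax(z, 0) else sigmoid(z)
  }
  as.numeric(a)
}

# Forward pass retaining pre-activations and activations for backprop.
forward_cache <- function(params, X) {
  a <- X
  zs <- vector("list", length(params))
  as <- vector("list", length(params) + 1L)
  as[[1]] <- a
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- sweep(a %*% params[[l]]$W, 2L, params[[l]]$b, "+")
    zs[[l]] <- z
    a <- if (l < n_layers) pmax(z, 0) else sigmoid(z)
    as[[l + 1L]] <- a
  }
  list(zs = zs, as = as, probs = as.numeric(a))
}

#' Inverse-frequency class weights
#'
#' The per-class loss weight is the class frequency inverted and normalized
#' by a factor of 2: `w_c = N / (2 * N_c)`. For a balanced sample both
#' weights equal 1; the minority class receives proportionally more weight.
#'
#' @param labels binary vector (0 = CU, 1 = CI); both classes must be present
#' @return an object of class `class_weights` with fields `weight_cu`,
#'   `weight_ci`
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  n_cu <- sum(labels == 0L)
  n_ci <- sum(labels == 1L)
  if (n_cu == 0L || n_ci == 0L) {
    stop("class weights are undefined: only one class present")
  }
  structure(list(weight_cu = n / (2 * n_cu), weight_ci = n / (2 * n_ci)),
            class = "class_weights")
}

# Per-sample weight vector from class weights.
sample_weights <- function(labels, weights) {
  ifelse(labels == 1L, weights$weight_ci, weights$weight_cu)
}

#' Class-weighted binary cross-entropy
#'
#' Mean over the batch of
#' `w(y_i) * (-y_i * log(p_i) - (1 - y_i) * log(1 - p_i))`, with
#' probabilities clamped away from 0 and 1 by 1e-12.
#'
#' @param probs predicted probabilities
#' @param labels binary labels (0/1), same length
#' @param weights a [class_weights()] object; defaults to unit weights
#' @return nonnegative scalar loss
#' @export
weighted_bce <- function(probs, labels,
                         weights = structure(list(weight_cu = 1, weight_ci = 1),
                                             class = "class_weights")) {
  if (length(probs) != length(labels)) {
    stop("probs and labels must have the same length")
  }
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  y <- as.numeric(labels)
  w <- sample_weights(as.integer(labels), weights)
  mean(w * (-y * log(p) - (1 - y) * log(1 - p)))
}

#' Analytic gradient of the weighted BCE loss
#'
#' Backpropagation through the ReLU/sigmoid MLP. Returned gradients are with
#' respect to the batch-mean weighted loss of [weighted_bce()].
#'
#' @param params a `model_params` object
#' @param X feature matrix (`n x input_size`)
#' @param labels binary labels (0/1)
#' @param weights a [class_weights()] object
#' @return a list with `loss` and `grads` (per layer, matrices `W` and
#'   vectors `b` matching `params` shapes)
#' @export
mlp_gradients <- function(params, X, labels,
                          weights = structure(list(weight_cu = 1, weight_ci = 1),
                                              class = "class_weights")) {
  X <- as.matrix(X)
  y <- as.numeric(labels)
  cache <- forward_cache(params, X)
  n <- nrow(X)
  w <- sample_weights(as.integer(labels), weights)
  loss <- weighted_bce(cache$probs, labels, weights)

  n_layers <- length(params)
  grads <- vector("list", n_layers)
  # sigmoid + BCE: dL/dz_out = w * (p - y) / n
  delta <- matrix(w * (cache$probs - y) / n, ncol = 1L)
  for (l in rev(seq_len(n_layers))) {
    a_prev <- cache$as[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (cache$zs[[l - 1L]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

#' Fit a feature standardizer
#'
#' Column means and standard deviations of the training features; columns
#' with zero variance get scale 1 so they pass through unchanged.
#'
#' @param X numeric matrix or [feature_table()]
#' @return an object of class `feature_scaler` with `center` and `scale`
#' @export
fit_scaler <- function(X) {
  if (inherits(X, "feature_table")) X <- X$features
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' Apply a fitted standardizer
#'
#' @param scaler a [fit_scaler()] result (or `NULL` for identity)
#' @param X numeric matrix or [feature_table()]
#' @return standardized numeric matrix
#' @export
apply_scaler <- function(scaler, X) {
  if (inherits(X, "feature_table")) X <- X$features
  if (is.null(scaler)) return(as.matrix(X))
  sweep(sweep(as.matrix(X), 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Train the MLP on one node's data
#'
#' Minibatch SGD with a seeded per-epoch shuffle and an exponentially
#' decaying learning rate. Class weights are computed once from the node's
#' training labels (unless supplied) and applied per sample in every batch.
#' When training is resumed across federated rounds, `epoch_offset` carries
#' the cumulative epoch count so the learning-rate schedule continues rather
#' than restarting.
#'
#' @param params starting `model_params`
#' @param train a [feature_table()] with both classes present (required for
#'   class weights)
#' @param config a [training_config()]
#' @param scaler optional pre-fitted [fit_scaler()]; if `NULL` and
#'   `config$standardize` is `TRUE`, one is fitted from `train`
#' @param weights optional precomputed [class_weights()]
#' @param epoch_offset global epoch index at which this call starts (0-based)
#' @return a list with `params` (trained), `losses` (per-epoch mean training
#'   loss), and `scaler` (the standardizer used, possibly `NULL`)
#' @export
train_local <- function(params, train, config = training_config(),
                        scaler = NULL, weights = NULL, epoch_offset = 0L) {
  stopifnot(inherits(train, "feature_table"))
  n <- n_samples(train)
  if (n == 0L) stop("training set is empty")
  if (is.null(weights)) weights <- class_weights(train$labels)
  if (is.null(scaler) && config$standardize) scaler <- fit_scaler(train)
  X <- apply_scaler(scaler, train)
  y <- train$labels

  losses <- numeric(config$epochs)
  if (config$epochs == 0L) {
    return(list(params = params, losses = losses, scaler = scaler))
  }
  for (e in seq_len(config$epochs)) {
    global_epoch <- epoch_offset + e - 1L
    lr <- config$learning_rate * config$lr_decay^global_epoch
    set.seed(as.integer((as.numeric(config$seed) + 104729 * global_epoch) %%
                          2147483647))
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      g <- mlp_gradients(params, X[idx, , drop = FALSE], y[idx], weights)
      if (!is.finite(g$loss)) {
        stop("non-finite training loss at epoch ", global_epoch + 1L)
      }
      for (l in seq_along(params)) {
        params[[l]]$W <- params[[l]]$W - lr * g$grads[[l]]$W
        params[[l]]$b <- params[[l]]$b - lr * g$grads[[l]]$b
      }
      batch_losses <- c(batch_losses, g$loss)
    }
    losses[e] <- mean(batch_losses)
  }
  list(params = params, losses = losses, scaler = scaler)
}

#' Predict class probabilities for a feature table
#'
#' @param params a `model_params` object
#' @param table a [feature_table()] (or numeric matrix)
#' @param scaler optional [fit_scaler()] standardizer to apply first
#' @return numeric vector of CI probabilities
#' @export
predict_proba <- function(params, table, scaler = NULL) {
  mlp_forward(params, apply_scaler(scaler, table))
}
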