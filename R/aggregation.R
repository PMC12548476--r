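#' A client's update for one aggregation round
#'
#' @param params the client's post-training `model_params`
#' @param n_samples the client's training-sample count (at least 1)
#' @param client_id string identifying the client
#' @return an object of class `client_update`
#' @export
client_update <- function(params, n_samples, client_id = "client") {
  stopifnot(inherits(params, "model_params"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be at least 1")
  structure(list(params = params, n_samples = n_samples,
                 client_id = as.character(client_id)),
            class = "client_update")
}

check_same_shapes <- function(params_list) {
  if (length(params_list) == 0L) stop("no client updates to aggregate")
  ref <- params_list[[1]]
  for (p in params_list[-1]) {
    if (length(p) != length(ref)) stop("clients have different layer counts")
    for (l in seq_along(p)) {
      if (!identical(dim(p[[l]]$W), dim(ref[[l]]$W)) ||
          length(p[[l]]$b) != length(ref[[l]]$b)) {
        stop("client parameter shapes differ at layer ", l)
      }
    }
  }
  invisible(TRUE)
}

# Entrywise convex combination of parameter trees with coefficients alpha.
combine_params <- function(params_list, alpha) {
  out <- params_list[[1]]
  for (l in seq_along(out)) {
    W <- out[[l]]$W * alpha[1]
    b <- out[[l]]$b * alpha[1]
    for (k in seq_along(params_list)[-1]) {
      W <- W + alpha[k] * params_list[[k]][[l]]$W
      b <- b + alpha[k] * params_list[[k]][[l]]$b
    }
    out[[l]]$W <- W
    out[[l]]$b <- b
  }
  out
}

#' Federated averaging (FedAvg)
#'
#' The global parameters are the sample-size-weighted mean of the client
#' parameters: every entry equals `sum_k (n_k / n) * w_k` where `n_k` is
#' client `k`'s training-sample count and `n = sum_k n_k`. Clients holding
#' more data therefore exert proportionally more influence.
#'
#' @param updates list of [client_update()] objects with identical parameter
#'   shapes
#' @return the aggregated `model_params`
#' @export
fedavg <- function(updates) {
  params_list <- lapply(updates, `[[`, "params")
  check_same_shapes(params_list)
  n_k <- vapply(updates, `[[`, numeric(1), "n_samples")
  combine_params(params_list, n_k / sum(n_k))
}

#' Inverse-distance aggregation weights (IDA)
#'
#' Each client is weighted inversely to its l1 distance from the unweighted
#' average model: with `w_avg` the entrywise mean of the client parameters
#' and `d_k = ||w_avg - w_k||_1` over all weights and biases (flattened),
#' `alpha_k = (1/Z) * (d_k + epsilon)^(-1)`, `Z` normalizing the weights to
#' sum to 1. Outlying updates are thereby downweighted. With exactly two
#' clients both are equidistant from their midpoint, so the weights are
#' always (0.5, 0.5).
#'
#' @param local_params list of `model_params` with identical shapes
#' @param epsilon small positive constant preventing division by zero
#'   (default 1e-8)
#' @return an object of class `aggregation_weights`: list with `alpha`
#'   (summing to 1) and `distances`
#' @export
ida_weights <- function(local_params, epsilon = 1e-8) {
  check_same_shapes(local_params)
  if (epsilon <= 0) stop("epsilon must be positive")
  flat <- lapply(local_params, flatten_params)
  if (any(!vapply(flat, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite client parameters")
  }
  w_avg <- Reduce(`+`, flat) / length(flat)
  d <- vapply(flat, function(v) sum(abs(w_avg - v)), numeric(1))
  inv <- 1 / (d + epsilon)
  structure(list(alpha = inv / sum(inv), distances = d),
            class = "aggregation_weights")
}

#' Inverse-distance aggregation (IDA)
#'
#' Aggregates client parameters as `sum_k alpha_k * w_k` with the weights of
#' [ida_weights()] computed from the updates' parameters.
#'
#' @inheritParams fedavg
#' @param epsilon passed to [ida_weights()]
#' @return the aggregated `model_params`
#' @export
ida_aggregate <- function(updates, epsilon = 1e-8) {
  params_list <- lapply(updates, `[[`, "params")
  w <- ida_weights(params_list, epsilon = epsilon)
  combine_params(params_list, w$alpha)
}

#' Plain-mean aggregation
#'
#' The unweighted entrywise mean of the client parameters; the baseline both
#' FedAvg (equal `n_k`) and IDA (equidistant clients, in particular any two
#' clients) reduce to.
#'
#' @inheritParams fedavg
#' @return the aggregated `model_params`
#' @export
mean_aggregate <- function(updates) {
  params_list <- lapply(updates, `[[`, "params")
  check_same_shapes(params_list)
  combine_params(params_list, rep(1 / length(params_list),
                                  length(params_list)))
}

#' Aggregate client updates by a named method
#'
#' @inheritParams fedavg
#' @param method one of `"fedavg"`, `"ida"`, `"mean"`
#' @param epsilon passed to [ida_aggregate()] when `method = "ida"`
#' @return the aggregated `model_params`
#' @export
aggregate_updates <- function(updates, method = c("fedavg", "ida", "mean"),
                              epsilon = 1e-8) {
  method <- match.arg(method)
  switch(method,
    fedavg = fedavg(updates),
    ida = ida_aggregate(updates, epsilon = epsilon),
    mean = mean_aggregate(updates)
  )
}
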