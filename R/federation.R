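#' Federated-training configuration
#'
#' The total local-epoch budget is `rounds * local_epochs_per_round`; the
#' default of 150 rounds of one local epoch each spends the same 150-epoch
#' budget as local training while aggregating after every epoch (the
#' communication-maximal reading of federated averaging). The learning-rate
#' schedule is global: it decays with the cumulative epoch count across
#' rounds, so federated and local training see identical learning-rate
#' trajectories.
#'
#' @param rounds number of communication rounds (default 150)
#' @param local_epochs_per_round local epochs each client runs per round
#'   (default 1)
#' @param aggregator one of `"fedavg"`, `"ida"`, `"mean"`
#' @param epsilon IDA division-by-zero guard (default 1e-8)
#' @param training a [training_config()]; its `epochs` field is ignored in
#'   favor of the round structure
#' @param hidden integer vector of hidden-layer widths (default `c(20, 20)`)
#' @param seed integer seed for the global parameter initialization
#' @return an object of class `federation_config`
#' @export
federation_config <- function(rounds = 150L, local_epochs_per_round = 1L,
                              aggregator = c("fedavg", "ida", "mean"),
                              epsilon = 1e-8,
                              training = training_config(),
                              hidden = c(20L, 20L), seed = 1L) {
  if (rounds < 1L) stop("rounds must be positive")
  if (local_epochs_per_round < 1L) stop("local_epochs_per_round must be positive")
  structure(
    list(rounds = as.integer(rounds),
         local_epochs_per_round = as.integer(local_epochs_per_round),
         aggregator = match.arg(aggregator), epsilon = epsilon,
         training = training, hidden = as.integer(hidden),
         seed = as.integer(seed)),
    class = "federation_config"
  )
}

#' Individual-training condition
#'
#' Trains one model per institution on its local data only, with no parameter
#' exchange: the baseline against which federated training is compared. A
#' node whose training set cannot be used (e.g. only one class present, so
#' class weights are undefined) is reported as a per-node failure without
#' affecting the other nodes.
#'
#' @param nodes list of [node_dataset()] objects
#' @param training a [training_config()]
#' @param hidden hidden-layer widths
#' @return a named list, one entry per node: on success a list with `params`,
#'   `losses`, `scaler`, `error = NULL`; on failure `error` holds the message
#' @export
run_local_condition <- function(nodes, training = training_config(),
                                hidden = c(20L, 20L)) {
  out <- vector("list", length(nodes))
  names(out) <- vapply(nodes, `[[`, character(1), "node_id")
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    res <- tryCatch({
      p <- ncol(nd$train$features)
      params0 <- init_params(c(p, hidden, 1L), seed = training$seed)
      fit <- train_local(params0, nd$train, config = training)
      list(params = fit$params, losses = fit$losses, scaler = fit$scaler,
           error = NULL)
    }, error = function(e) {
      list(params = NULL, losses = NULL, scaler = NULL,
           error = conditionMessage(e))
    })
    out[[k]] <- res
  }
  out
}

#' Federated-training condition
#'
#' Round-based orchestration: a seeded global model is initialized once; each
#' round it is broadcast to every client, each client runs
#' `local_epochs_per_round` epochs of seeded SGD (continuing the global
#' learning-rate schedule by cumulative epoch count), and the resulting
#' client updates are aggregated with the configured method into the next
#' global model. Feature standardization and class weights are fitted once
#' per client from that client's own training data.
#'
#' @param nodes list of [node_dataset()] objects (each with both classes in
#'   its training set)
#' @param config a [federation_config()]
#' @return a list with `params` (the final global model), `round_log`
#'   (data.frame: one row per round per client with loss, aggregation weight
#'   `alpha`, IDA distance `d`, `n_samples`, and the global-parameter l1
#'   change of the round), and `scalers` (per-node standardizers used for
#'   evaluation)
#' @export
run_federated_condition <- function(nodes, config = federation_config()) {
  if (length(nodes) < 1L) stop("at least one node is required")
  node_ids <- vapply(nodes, `[[`, character(1), "node_id")
  p <- ncol(nodes[[1]]$train$features)

  training <- config$training
  scalers <- lapply(nodes, function(nd) {
    if (training$standardize) fit_scaler(nd$train) else NULL
  })
  names(scalers) <- node_ids
  cw <- lapply(nodes, function(nd) class_weights(nd$train$labels))
  n_k <- vapply(nodes, function(nd) n_samples(nd$train), numeric(1))

  global <- init_params(c(p, config$hidden, 1L), seed = config$seed)
  local_cfg <- training
  local_cfg$epochs <- config$local_epochs_per_round

  log_rows <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    offset <- (r - 1L) * config$local_epochs_per_round
    updates <- vector("list", length(nodes))
    losses <- numeric(length(nodes))
    for (k in seq_along(nodes)) {
      fit <- train_local(global, nodes[[k]]$train, config = local_cfg,
                         scaler = scalers[[k]], weights = cw[[k]],
                         epoch_offset = offset)
      updates[[k]] <- client_update(fit$params, n_k[k], node_ids[k])
      losses[k] <- mean(fit$losses)
    }
    if (config$aggregator == "ida") {
      w <- ida_weights(lapply(updates, `[[`, "params"),
                       epsilon = config$epsilon)
      alpha <- w$alpha
      dists <- w$distances
    } else if (config$aggregator == "fedavg") {
      alpha <- n_k / sum(n_k)
      dists <- rep(NA_real_, length(nodes))
    } else {
      alpha <- rep(1 / length(nodes), length(nodes))
      dists <- rep(NA_real_, length(nodes))
    }
    new_global <- aggregate_updates(updates, method = config$aggregator,
                                    epsilon = config$epsilon)
    flat_new <- flatten_params(new_global)
    if (!all(is.finite(flat_new))) {
      stop("non-finite aggregated parameters at round ", r)
    }
    l1_change <- sum(abs(flat_new - flatten_params(global)))
    global <- new_global
    log_rows[[r]] <- data.frame(
      round = r, client_id = node_ids, loss = losses, alpha = alpha,
      d = dists, n_samples = n_k, global_l1_change = l1_change,
      row.names = NULL
    )
  }
  list(params = global, round_log = do.call(rbind, log_rows),
       scalers = scalers)
}

#' Cross-evaluation of local models
#'
#' Evaluates every successfully trained local model on every node's test set
#' (each institution's model is assessed both on its own held-out data and on
#' the other institution's), using the model's own training standardizer.
#'
#' @param local_fits result of [run_local_condition()]
#' @param nodes the [node_dataset()] list the models were trained on
#' @param threshold decision threshold
#' @param scenario tag recorded in each report
#' @return a list of `metrics_report` objects tagged
#'   `condition = "local(<model node>)"`, `node = <evaluated node>`
#' @export
cross_evaluate_local <- function(local_fits, nodes, threshold = 0.5,
                                 scenario = NA_character_) {
  reports <- list()
  for (model_node in names(local_fits)) {
    fit <- local_fits[[model_node]]
    if (!is.null(fit$error)) next
    for (nd in nodes) {
      reports[[length(reports) + 1L]] <- evaluate_model(
        fit$params, nd$test, scaler = fit$scaler, threshold = threshold,
        node = nd$node_id, condition = paste0("local(", model_node, ")"),
        scenario = scenario
      )
    }
  }
  reports
}

#' Evaluate the global federated model on every node
#'
#' @param fed result of [run_federated_condition()]
#' @param nodes the [node_dataset()] list
#' @param threshold decision threshold
#' @param scenario tag recorded in each report
#' @return a list of `metrics_report` objects tagged `condition = "fl"`
#' @export
evaluate_federated <- function(fed, nodes, threshold = 0.5,
                               scenario = NA_character_) {
  lapply(nodes, function(nd) {
    evaluate_model(fed$params, nd$test, scaler = fed$scalers[[nd$node_id]],
                   threshold = threshold, node = nd$node_id,
                   condition = "fl", scenario = scenario)
  })
}
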