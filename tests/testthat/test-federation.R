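make_nodes_fixture <- function(n = 120, p = 4, seeds = c(51, 52),
                               effect = 1.5) {
  lapply(seq_along(seeds), function(k) {
    ct <- generate_cohort(generator_config(
      n, n_features = p, cu_prevalence = 0.3, n_informative = 2L,
      effect_size = effect, seed = seeds[k]
    ))
    ct$sample_ids <- paste0("n", k, "_", ct$sample_ids)
    sp <- train_test_split(ct, seed = seeds[k])
    node_dataset(paste0("node", k), sp$train, sp$test)
  })
}

test_that("local condition trains nodes independently and deterministically", {
  nodes <- make_nodes_fixture(seeds = c(51, 51))  # identical data
  cfg <- training_config(epochs = 5, batch_size = 16, seed = 9)
  fits <- run_local_condition(nodes, training = cfg, hidden = c(4L, 4L))
  expect_named(fits, c("node1", "node2"))
  expect_null(fits$node1$error)
  expect_identical(fits$node1$params, fits$node2$params)
})

test_that("a single-class node fails alone, without sinking the others", {
  nodes <- make_nodes_fixture()
  broken <- nodes[[1]]
  keep <- broken$train$labels == 1L
  broken <- node_dataset("node1", ft_subset(broken$train, keep),
                         broken$test)
  fits <- run_local_condition(list(broken, nodes[[2]]),
                              training = training_config(epochs = 3, seed = 2),
                              hidden = c(3L))
  expect_match(fits$node1$error, "one class")
  expect_null(fits$node2$error)
  expect_s3_class(fits$node2$params, "model_params")
})

test_that("federation with one client reduces to that client's local run", {
  nodes <- make_nodes_fixture()[1]
  tcfg <- training_config(epochs = 6, batch_size = 16, seed = 3)
  fcfg <- federation_config(rounds = 3, local_epochs_per_round = 2,
                            aggregator = "fedavg", training = tcfg,
                            hidden = c(4L), seed = 3)
  fed <- run_federated_condition(nodes, fcfg)

  p0 <- init_params(c(4L, 4L, 1L), seed = 3)
  solo <- train_local(p0, nodes[[1]]$train, tcfg)
  expect_equal(fed$params, solo$params, tolerance = 1e-12)
  # epoch budget conservation: rounds x local epochs appear in the log
  expect_equal(nrow(fed$round_log), 3L)
})

test_that("identical clients make aggregation a fixed point, matching solo training", {
  nodes <- make_nodes_fixture(seeds = c(51, 51))
  tcfg <- training_config(epochs = 4, batch_size = 16, seed = 5)
  for (m in c("fedavg", "ida", "mean")) {
    fcfg <- federation_config(rounds = 4, local_epochs_per_round = 1,
                              aggregator = m, training = tcfg,
                              hidden = c(4L), seed = 5)
    fed <- run_federated_condition(nodes, fcfg)
    solo <- train_local(init_params(c(4L, 4L, 1L), seed = 5),
                        nodes[[1]]$train,
                        training_config(epochs = 4, batch_size = 16, seed = 5))
    expect_equal(fed$params, solo$params, tolerance = 1e-9)
  }
})

test_that("round logs carry normalized weights and finite losses", {
  nodes <- make_nodes_fixture(n = 100, seeds = c(61, 62))
  fcfg <- federation_config(rounds = 5, aggregator = "ida",
                            training = training_config(epochs = 1,
                                                       batch_size = 16,
                                                       seed = 8),
                            hidden = c(4L), seed = 8)
  fed <- run_federated_condition(nodes, fcfg)
  log <- fed$round_log
  expect_equal(nrow(log), 10L)  # 5 rounds x 2 clients
  alpha_sums <- as.numeric(tapply(log$alpha, log$round, sum))
  expect_equal(alpha_sums, rep(1, 5), tolerance = 1e-12)
  expect_true(all(is.finite(log$loss)))
  expect_true(all(log$d >= 0))
  # with two clients IDA weights are forced to one half
  expect_equal(log$alpha, rep(0.5, 10), tolerance = 1e-12)
})

test_that("quantity-skewed federation favors the small node's recall", {
  # one seed of the rescue experiment at reduced size: the small node's
  # federated sensitivity should not collapse the way its local model can
  ct <- generate_cohort(generator_config(600, n_features = 20,
                                         n_informative = 5L,
                                         effect_size = effect_size_for_auc(0.9, 5),
                                         cu_prevalence = 0.15, seed = 71))
  nodes <- make_node_datasets(ct, scenario_preset("scenario2"), seed = 71)
  tcfg <- training_config(epochs = 40, seed = 71)
  local_fit <- run_local_condition(nodes[1], training = tcfg)
  fed <- run_federated_condition(nodes, federation_config(
    rounds = 40, aggregator = "fedavg", training = tcfg, seed = 71
  ))
  small_test <- nodes[[1]]$test
  loc <- evaluate_model(local_fit$node1$params, small_test,
                        local_fit$node1$scaler)
  glob <- evaluate_model(fed$params, small_test, fed$scalers$node1)
  expect_gt(glob$balanced_accuracy, 0.5)
  expect_gte(glob$balanced_accuracy, loc$balanced_accuracy - 0.1)
})
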