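test_that("parameter initialization has the right shapes, count and bounds", {
  p <- init_params(c(176L, 20L, 20L, 1L), seed = 1)
  expect_length(p, 3L)
  expect_equal(count_params(p), 176 * 20 + 20 + 20 * 20 + 20 + 20 * 1 + 1)  # 4401
  expect_true(all(vapply(p, function(l) all(l$b == 0), logical(1))))
  for (l in p) {
    lim <- sqrt(6 / (nrow(l$W) + ncol(l$W)))
    expect_true(all(abs(l$W) <= lim))
  }

  expect_identical(init_params(c(10L, 3L, 1L), seed = 5),
                   init_params(c(10L, 3L, 1L), seed = 5))
  tiny <- init_params(c(1L, 1L), seed = 2)
  expect_equal(dim(tiny[[1]]$W), c(1L, 1L))
  expect_equal(tiny[[1]]$b, 0)
  expect_error(init_params(c(5L), seed = 1), "two layer sizes")
  expect_error(init_params(c(5L, 0L), seed = 1), "positive")
})

test_that("flatten/unflatten round-trips the parameter tree", {
  p <- make_random_params(c(4L, 3L, 2L), seed = 3)
  v <- flatten_params(p)
  expect_length(v, count_params(p))
  expect_equal(unflatten_params(p, v), p)
  expect_error(unflatten_params(p, v[-1]), "length")
})

test_that("forward pass obeys the activation structure", {
  zero <- unflatten_params(init_params(c(4L, 3L, 1L), 1),
                           rep(0, count_params(init_params(c(4L, 3L, 1L), 1))))
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(mlp_forward(zero, X), rep(0.5, 5))  # sigmoid(0)

  p <- make_random_params(c(4L, 3L, 1L), seed = 9)
  probs <- mlp_forward(p, X)
  expect_length(probs, 5L)
  expect_true(all(probs > 0 & probs < 1))
  expect_error(mlp_forward(p, matrix(0, 2, 3)), "columns")
})

test_that("inverse-frequency class weights follow N / (2 N_c)", {
  w <- class_weights(c(rep(1L, 50), rep(0L, 50)))
  expect_equal(w$weight_cu, 1)
  expect_equal(w$weight_ci, 1)

  w2 <- class_weights(c(rep(1L, 90), rep(0L, 10)))
  expect_equal(w2$weight_ci, 100 / (2 * 90))
  expect_equal(w2$weight_cu, 5)

  expect_error(class_weights(rep(1L, 20)), "one class")
})

test_that("weighted binary cross-entropy matches hand-computed values", {
  unit <- class_weights(c(0L, 1L))
  expect_equal(weighted_bce(c(0.5, 0.5), c(1L, 0L), unit), log(2))
  expect_lt(weighted_bce(c(1, 0, 1), c(1L, 0L, 1L), unit), 1e-10)

  w <- structure(list(weight_cu = 0.5, weight_ci = 2), class = "class_weights")
  expect_equal(weighted_bce(c(0.8, 0.3), c(1L, 0L), w),
               mean(c(2 * -log(0.8), 0.5 * -log(0.7))))
  expect_error(weighted_bce(c(0.5), c(1L, 0L)), "length")
})

test_that("backprop matches central finite differences on every layer", {
  w <- structure(list(weight_cu = 0.7, weight_ci = 1.8),
                 class = "class_weights")
  for (sizes in list(c(7L, 4L, 3L, 1L), c(176L, 20L, 20L, 1L))) {
    set.seed(2024)
    X <- matrix(rnorm(5 * sizes[1]), 5, sizes[1])
    y <- c(1L, 0L, 1L, 1L, 0L)
    p <- init_params(sizes, seed = 12)
    g <- mlp_gradients(p, X, y, w)
    analytic <- unlist(lapply(g$grads, function(l) c(as.numeric(l$W), l$b)))
    numeric <- numeric_gradient(p, X, y, w)
    denom <- pmax(abs(numeric), 1e-3)
    expect_lt(max(abs(analytic - numeric) / denom), 1e-4)
  }
})

test_that("standardization leaves train columns centered and scaled", {
  ct <- make_toy_cohort(n = 80, p = 6, seed = 21)
  ct$features <- sweep(ct$features, 2L, c(10, 100, 1, 5, 50, 0.1), "*")
  sc <- fit_scaler(ct)
  Z <- apply_scaler(sc, ct)
  expect_equal(unname(colMeans(Z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 6), tolerance = 1e-12)

  const <- matrix(c(1, 1, 1, 2, 3, 4), ncol = 2)
  Zc <- apply_scaler(fit_scaler(const), const)
  expect_true(all(is.finite(Zc)))
})

test_that("training descends, decays the learning rate, and is seeded", {
  ct <- make_toy_cohort(n = 20, p = 2, effect = 4, prevalence = 0.5, seed = 31)
  cfg <- training_config(epochs = 30, batch_size = 8, seed = 4)
  p0 <- init_params(c(2L, 4L, 1L), seed = 4)

  fit <- train_local(p0, ct, cfg)
  expect_lt(fit$losses[30], fit$losses[1])
  expect_true(all(is.finite(fit$losses)))

  refit <- train_local(p0, ct, cfg)
  expect_identical(fit$params, refit$params)

  none <- train_local(p0, ct, training_config(epochs = 0))
  expect_identical(none$params, p0)
})

test_that("epoch offset continues the learning-rate schedule", {
  # two epochs in one call == 1 epoch + 1 epoch resumed with offset 1
  ct <- make_toy_cohort(n = 24, p = 3, seed = 41)
  cfg2 <- training_config(epochs = 2, batch_size = 8, seed = 6)
  cfg1 <- training_config(epochs = 1, batch_size = 8, seed = 6)
  p0 <- init_params(c(3L, 4L, 1L), seed = 6)
  sc <- fit_scaler(ct)
  w <- class_weights(ct$labels)

  once <- train_local(p0, ct, cfg2, scaler = sc, weights = w)
  stepped <- train_local(p0, ct, cfg1, scaler = sc, weights = w)
  stepped <- train_local(stepped$params, ct, cfg1, scaler = sc, weights = w,
                         epoch_offset = 1L)
  expect_equal(stepped$params, once$params, tolerance = 1e-12)
})

test_that("the default recipe learns a strong synthetic signal", {
  cfg <- generator_config(2000, effect_size = 1.5, n_informative = 10,
                          seed = 7)
  ct <- generate_cohort(cfg)
  sp <- train_test_split(ct, seed = 1)
  fit <- train_local(init_params(c(176L, 20L, 20L, 1L), seed = 1), sp$train,
                     training_config(seed = 3))
  rep <- evaluate_model(fit$params, sp$test, fit$scaler)
  expect_gt(rep$auc, 0.85)
  # Bayes optimum upper-bounds the trained model
  expect_lte(rep$auc, 1)
})
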