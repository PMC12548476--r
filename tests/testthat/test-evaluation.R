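test_that("confusion matrix counts match hand tallies", {
  cm <- confusion(c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1),
                  c(1L, 1L, 0L, 1L, 0L, 0L), threshold = 0.5)
  expect_equal(cm$tp, 2L)
  expect_equal(cm$fn, 1L)
  expect_equal(cm$fp, 1L)
  expect_equal(cm$tn, 2L)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 6L)

  all_ci <- confusion(rep(1, 4), rep(1L, 4))
  expect_equal(unlist(all_ci), c(tp = 4L, fp = 0L, tn = 0L, fn = 0L))

  everything_ci <- confusion(c(0.1, 0.9), c(0L, 1L), threshold = 0)
  expect_equal(everything_ci$fp + everything_ci$tp, 2L)

  expect_error(confusion(numeric(0), integer(0)), "empty")
})

test_that("rank-based AUC equals the exhaustive pairwise oracle", {
  set.seed(606)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auc_rank(scores, labels), pairwise_auc(scores, labels))
  }
})

test_that("AUC is monotone-invariant and handles edge cases", {
  set.seed(17)
  scores <- rnorm(40)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.3, 0.7))
  base <- auc_rank(scores, labels)
  expect_equal(auc_rank(exp(scores), labels), base)
  expect_equal(auc_rank(2 * scores + 5, labels), base)

  expect_equal(auc_rank(rep(0.5, 20), rep(c(0L, 1L), 10)), 0.5)  # ties -> 1/2
  expect_true(is.na(auc_rank(scores, rep(1L, 40))))
})

test_that("the six-metric panel satisfies its internal identities", {
  set.seed(23)
  probs <- runif(200)
  labels <- as.integer(runif(200) < probs)  # informative but imperfect
  r <- classification_metrics(probs, labels)
  expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2)
  expect_equal(r$f1, 2 * r$precision * r$sensitivity /
                 (r$precision + r$sensitivity))
  expect_equal(r$confusion$tp + r$confusion$fp + r$confusion$tn +
                 r$confusion$fn, 200L)

  perfect <- classification_metrics(c(rep(0.9, 5), rep(0.1, 5)),
                                    c(rep(1L, 5), rep(0L, 5)))
  for (m in c("balanced_accuracy", "precision", "sensitivity",
              "specificity", "f1", "auc")) {
    expect_equal(perfect[[m]], 1)
  }
})

test_that("zero-denominator metrics are flagged NA, never silently 0", {
  # nothing predicted positive: precision undefined
  r <- classification_metrics(rep(0.1, 10), c(rep(1L, 5), rep(0L, 5)))
  expect_true(is.na(r$precision))
  expect_true("precision" %in% r$undefined)
  expect_equal(r$sensitivity, 0)
  expect_equal(r$specificity, 1)
})

test_that("balanced accuracy recovers published-style sensitivity/specificity pairs", {
  # confusion counts realizing each (sensitivity, specificity) pair at 1%
  # resolution, pushed through the package's metric pathway
  make_probs <- function(tp, fn, tn, fp) {
    list(probs = c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp)),
         labels = c(rep(1L, tp + fn), rep(0L, tn + fp)))
  }
  hi <- make_probs(93, 7, 67, 33)   # sensitivity 0.93, specificity 0.67
  r_hi <- classification_metrics(hi$probs, hi$labels)
  expect_equal(r_hi$balanced_accuracy, 0.80)

  lo <- make_probs(2, 98, 100, 0)   # sensitivity 0.02, specificity 1.00
  r_lo <- classification_metrics(lo$probs, lo$labels)
  expect_equal(r_lo$balanced_accuracy, 0.51)
})

test_that("reported two-node study rows obey the balanced-accuracy identity", {
  # (balanced accuracy, sensitivity, specificity) triples from the reference
  # two-institution experiment, all rounded to 2 decimals
  rows <- rbind(
    c(0.71, 0.69, 0.73), c(0.73, 0.71, 0.76),
    c(0.73, 0.82, 0.64), c(0.79, 0.83, 0.76),
    c(0.51, 0.02, 1.00), c(0.76, 0.76, 0.77),
    c(0.80, 0.93, 0.67), c(0.70, 0.90, 0.51),
    c(0.70, 0.71, 0.69), c(0.74, 0.70, 0.77),
    c(0.71, 0.57, 0.85), c(0.72, 0.60, 0.85)
  )
  expect_true(all(abs(rows[, 1] - (rows[, 2] + rows[, 3]) / 2) <= 0.005 + 1e-9))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    scores <- round(rnorm(60), 1)
    labels <- sample(0:1, 60, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  }
})
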