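#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic cohort of acoustic-feature-like vectors with a binary
#' cognitive-status label. Features are class-conditional Gaussians with
#' identity covariance: non-informative features are standard normal in both
#' classes, while each informative feature is shifted upward by `effect_size`
#' (in standard-deviation units) in the CI class. This form gives a
#' closed-form Bayes-optimal AUC (see [bayes_auc()]) used to validate the
#' whole pipeline.
#'
#' @param n_samples number of participants to simulate.
#' @param n_features number of features (default 176: two speech tasks times
#'   88 eGeMAPS-style descriptors).
#' @param cu_prevalence fraction of cognitively unimpaired (CU) participants,
#'   in (0, 1). Default 0.099 matches a memory-clinic population where most
#'   assessed individuals are impaired. The realized CU count is the exact
#'   quota `round(n_samples * cu_prevalence)`, not a Bernoulli draw.
#' @param n_informative number of informative features (must be
#'   `<= n_features`). Default 10, capped at `n_features`.
#' @param effect_size standardized mean shift per informative feature between
#'   classes; nonnegative. The default is calibrated so the Bayes-optimal AUC
#'   is 0.90 given `n_informative` (see [effect_size_for_auc()]), a
#'   discriminability comparable to a good acoustic biomarker panel.
#' @param site_shift nonnegative additive mean offset applied to every
#'   feature of one simulated site ("siteB", half the cohort) to emulate
#'   cross-site covariate shift. Default 0 (no site structure).
#' @param label_noise probability in `[0, 0.5)` that a label is independently
#'   flipped after feature generation. Default 0.
#' @param seed integer RNG seed; the same config and seed give bit-identical
#'   cohorts.
#'
#' @return an object of class `generator_config`
#' @export
generator_config <- function(n_samples,
                             n_features = 176L,
                             cu_prevalence = 0.099,
                             n_informative = min(10L, n_features),
                             effect_size = effect_size_for_auc(0.90, n_informative),
                             site_shift = 0,
                             label_noise = 0,
                             seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  if (n_samples < 1L) stop("n_samples must be positive")
  if (n_features < 1L) stop("n_features must be positive")
  if (cu_prevalence <= 0 || cu_prevalence >= 1) {
    stop("cu_prevalence must lie strictly between 0 and 1")
  }
  if (n_informative < 0L || n_informative > n_features) {
    stop("n_informative (", n_informative, ") must be between 0 and n_features (",
         n_features, ")")
  }
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (site_shift < 0) stop("site_shift must be nonnegative")
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)")
  }
  structure(
    list(n_samples = n_samples, n_features = n_features,
         cu_prevalence = cu_prevalence, n_informative = n_informative,
         effect_size = effect_size, site_shift = site_shift,
         label_noise = label_noise, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Bayes-optimal AUC of the generator's two-class Gaussian model
#'
#' For equal identity covariances and a mean separation of `effect_size` on
#' each of `n_informative` independent features, the optimal discriminant is
#' linear and its AUC is `pnorm(effect_size * sqrt(n_informative) / sqrt(2))`.
#'
#' @param effect_size per-feature standardized mean shift
#' @param n_informative number of shifted features
#' @return the Bayes-optimal AUC in `[0.5, 1]`
#' @export
bayes_auc <- function(effect_size, n_informative) {
  stats::pnorm(effect_size * sqrt(n_informative) / sqrt(2))
}

#' Effect size achieving a target Bayes-optimal AUC
#'
#' Inverse of [bayes_auc()] in `effect_size`.
#'
#' @param auc target Bayes AUC in (0.5, 1)
#' @param n_informative number of informative features
#' @return the per-feature effect size
#' @export
effect_size_for_auc <- function(auc, n_informative) {
  if (auc <= 0.5 || auc >= 1) stop("auc must lie in (0.5, 1)")
  stats::qnorm(auc) * sqrt(2) / sqrt(n_informative)
}

#' Generate a synthetic labeled cohort
#'
#' Draws `n_samples` feature vectors from the class-conditional Gaussian
#' model described in [generator_config()]. The CU class count is the exact
#' quota `round(n_samples * cu_prevalence)`; which rows are CU is a seeded
#' draw. If `label_noise > 0`, labels (only) are flipped independently after
#' feature generation, so feature-class structure is preserved. If
#' `site_shift > 0`, rows are split into two equal sites and every feature of
#' "siteB" rows is offset by `site_shift`.
#'
#' @param config a [generator_config()]
#' @return a [feature_table()] with `n_samples` rows
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_features

  n_cu <- as.integer(round(n * config$cu_prevalence))
  labels <- rep(1L, n)
  cu_rows <- sample.int(n, n_cu)
  labels[cu_rows] <- 0L

  features <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  if (config$n_informative > 0L && config$effect_size > 0) {
    ci_rows <- which(labels == 1L)
    inform <- seq_len(config$n_informative)
    features[ci_rows, inform] <- features[ci_rows, inform] + config$effect_size
  }

  site <- NULL
  if (config$site_shift > 0) {
    site <- rep("siteA", n)
    b_rows <- sample.int(n, floor(n / 2))
    site[b_rows] <- "siteB"
    features[b_rows, ] <- features[b_rows, ] + config$site_shift
  }

  if (config$label_noise > 0) {
    flip <- stats::runif(n) < config$label_noise
    labels[flip] <- 1L - labels[flip]
  }

  colnames(features) <- sprintf("f%03d", seq_len(p))
  feature_table(features, labels,
                sample_ids = sprintf("s%06d", seq_len(n)), site = site)
}

#' Bayes-optimal scores under the generator model
#'
#' The known-means linear discriminant for the generator's Gaussian model:
#' the sum of the informative features scaled by the effect size. Used as a
#' Monte-Carlo oracle for the closed-form Bayes AUC, independent of any
#' trained classifier.
#'
#' @param table a [feature_table()] produced by [generate_cohort()]
#' @param config the [generator_config()] that produced it
#' @return numeric score per row (higher = more CI-like)
#' @export
bayes_scores <- function(table, config) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "generator_config"))
  if (config$n_informative == 0L) return(rep(0, n_samples(table)))
  inform <- seq_len(config$n_informative)
  as.numeric(table$features[, inform, drop = FALSE] %*%
               rep(config$effect_size, config$n_informative))
}
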