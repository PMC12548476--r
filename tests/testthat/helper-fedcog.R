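# Shared fixtures, all built in code.

# A small labeled cohort with a clear class signal.
make_toy_cohort <- function(n = 60, p = 5, effect = 2, prevalence = 0.3,
                            seed = 101) {
  generate_cohort(generator_config(
    n_samples = n, n_features = p, cu_prevalence = prevalence,
    n_informative = min(2L, p), effect_size = effect, seed = seed
  ))
}

# model_params holding a single scalar weight (and one zero bias).
make_scalar_params <- function(w, b = 0) {
  structure(list(list(W = matrix(w, 1L, 1L), b = b)), class = "model_params")
}

# Random small parameter tree.
make_random_params <- function(sizes = c(3L, 2L, 1L), seed = 1L) {
  init_params(sizes, seed = seed)
}

# Central finite-difference gradient of the weighted BCE loss w.r.t. every
# parameter entry; the independent oracle for backpropagation.
numeric_gradient <- function(params, X, labels, weights, h = 1e-5) {
  flat <- flatten_params(params)
  grad <- numeric(length(flat))
  for (i in seq_along(flat)) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    lp <- weighted_bce(mlp_forward(unflatten_params(params, up), X),
                       labels, weights)
    lm <- weighted_bce(mlp_forward(unflatten_params(params, dn), X),
                       labels, weights)
    grad[i] <- (lp - lm) / (2 * h)
  }
  grad
}

# Exhaustive pairwise AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}
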