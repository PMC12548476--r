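#' Virtual-institution scenario specification
#'
#' Describes how one cohort is split across virtual institutions (nodes):
#' each node's share of the total cases and the fraction of that node's cases
#' that are cognitively impaired (CI). Three named presets capture the
#' canonical heterogeneity scenarios (see [scenario_preset()]); arbitrary
#' node counts and fractions are accepted as `custom`.
#'
#' @param node_fractions numeric vector, one entry per node, of each node's
#'   fraction of the total cases; must sum to 1 (within 1e-9).
#' @param node_ci_fraction numeric vector of the same length: target fraction
#'   of each node's cases that are CI, each in `[0, 1]`. The last node's
#'   realized composition is the remainder of the class pools (see
#'   [partition_cohort()]).
#' @param name scenario name; one of `"scenario1"`, `"scenario2"`,
#'   `"scenario3"`, `"custom"`.
#' @return an object of class `scenario_spec`
#' @export
scenario_spec <- function(node_fractions, node_ci_fraction, name = "custom") {
  if (length(node_fractions) != length(node_ci_fraction)) {
    stop("node_fractions and node_ci_fraction must have the same length")
  }
  if (length(node_fractions) < 1L) stop("at least one node is required")
  if (abs(sum(node_fractions) - 1) > 1e-9) {
    stop("node_fractions must sum to 1 (got ", sum(node_fractions), ")")
  }
  if (any(node_fractions < 0)) stop("node_fractions must be nonnegative")
  if (any(node_ci_fraction < 0 | node_ci_fraction > 1)) {
    stop("each node_ci_fraction must lie in [0, 1]")
  }
  name <- match.arg(name, c("scenario1", "scenario2", "scenario3", "custom"))
  structure(
    list(name = name, node_fractions = as.numeric(node_fractions),
         node_ci_fraction = as.numeric(node_ci_fraction)),
    class = "scenario_spec"
  )
}

#' Named two-institution scenario presets
#'
#' * `scenario1` — uniform sample size: each node holds 50% of the cases with
#'   a 90% CI composition (quantity- and label-balanced).
#' * `scenario2` — quantity skew: node 1 holds 10% of the cases, node 2 holds
#'   90%, both at 90% CI.
#' * `scenario3` — label skew: node 1 (about 62% of cases) is almost purely
#'   CI (97%), node 2 holds the CU-rich remainder (about 78% CI realized).
#'
#' @param name one of `"scenario1"`, `"scenario2"`, `"scenario3"`
#' @return a [scenario_spec()]
#' @export
scenario_preset <- function(name = c("scenario1", "scenario2", "scenario3")) {
  name <- match.arg(name)
  switch(name,
    scenario1 = scenario_spec(c(0.5, 0.5), c(0.9, 0.9), name = "scenario1"),
    scenario2 = scenario_spec(c(0.1, 0.9), c(0.9, 0.9), name = "scenario2"),
    scenario3 = scenario_spec(c(1395, 844) / 2239, c(0.97, 0.78),
                              name = "scenario3")
  )
}

#' Partition a cohort into virtual institutions
#'
#' Node sizes follow the floor convention: node `k` receives
#' `floor(node_fractions[k] * N)` cases for every node but the last, which
#' receives the remainder, so the partition is exhaustive. Within each
#' non-final node the CI count is `round(node_ci_fraction[k] * size_k)`,
#' filled by seeded sampling without replacement from the matching class
#' pools; the final node receives whatever remains of each class pool (its
#' realized CI fraction therefore floats to whatever the cohort's overall
#' composition leaves over, which is the only allocation consistent with an
#' exhaustive partition and fixed per-node quotas).
#'
#' @param table a [feature_table()] cohort
#' @param spec a [scenario_spec()]
#' @param seed integer seed for the assignment draw
#' @return a named list of [feature_table()] objects, one per node, with
#'   `site` set to the node id (`node1`, `node2`, ...)
#' @export
partition_cohort <- function(table, spec, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "scenario_spec"))
  n <- n_samples(table)
  k_nodes <- length(spec$node_fractions)

  sizes <- floor(spec$node_fractions * n + 1e-9)
  sizes[k_nodes] <- n - sum(sizes[-k_nodes])
  if (sizes[k_nodes] < 0) stop("node fractions overdraw the cohort")

  ci_quota <- integer(k_nodes)
  for (k in seq_len(k_nodes - 1L)) {
    ci_quota[k] <- as.integer(round(spec$node_ci_fraction[k] * sizes[k]))
  }

  set.seed(seed)
  ci_pool <- sample(which(table$labels == 1L))
  cu_pool <- sample(which(table$labels == 0L))

  nodes <- vector("list", k_nodes)
  names(nodes) <- sprintf("node%d", seq_len(k_nodes))
  for (k in seq_len(k_nodes)) {
    if (k < k_nodes) {
      n_ci <- ci_quota[k]
      n_cu <- sizes[k] - n_ci
    } else {
      n_ci <- length(ci_pool)
      n_cu <- length(cu_pool)
      if (n_ci + n_cu != sizes[k]) {
        stop("internal error: remainder does not fill node", k)
      }
    }
    if (n_ci > length(ci_pool)) {
      stop("infeasible quota: node", k, " needs ", n_ci,
           " CI cases but only ", length(ci_pool), " remain")
    }
    if (n_cu < 0 || n_cu > length(cu_pool)) {
      stop("infeasible quota: node", k, " needs ", max(n_cu, 0),
           " CU cases but only ", length(cu_pool), " remain")
    }
    take_ci <- utils::head(ci_pool, n_ci)
    take_cu <- utils::head(cu_pool, n_cu)
    ci_pool <- utils::tail(ci_pool, length(ci_pool) - n_ci)
    cu_pool <- utils::tail(cu_pool, length(cu_pool) - n_cu)
    idx <- sort(c(take_ci, take_cu))
    node_ft <- ft_subset(table, idx)
    node_ft$site <- rep(names(nodes)[k], length(idx))
    nodes[[k]] <- node_ft
  }
  nodes
}

#' Stratified 70/30 train/test split
#'
#' The train size is `floor(train_fraction * N)`; the split is stratified by
#' class using largest-remainder allocation constrained to that total, so the
#' per-class training shares are as close to `train_fraction` as integer
#' counts allow. Train and test are disjoint by `sample_id`.
#'
#' @param table a non-empty [feature_table()]
#' @param train_fraction fraction of rows assigned to training, in (0, 1);
#'   default 0.70
#' @param seed integer seed for the within-class shuffle
#' @return a list with elements `train` and `test`, both [feature_table()]s
#' @export
train_test_split <- function(table, train_fraction = 0.70, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  n <- n_samples(table)
  if (n == 0L) stop("cannot split an empty feature table")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- as.integer(floor(train_fraction * n + 1e-9))

  classes <- sort(unique(table$labels))
  exact <- vapply(classes, function(cl) {
    train_fraction * sum(table$labels == cl)
  }, numeric(1))
  base <- floor(exact + 1e-9)
  leftover <- n_train - sum(base)
  if (leftover > 0) {
    frac <- exact - base
    bump <- order(frac, decreasing = TRUE)[seq_len(leftover)]
    base[bump] <- base[bump] + 1L
  } else if (leftover < 0) {
    frac <- exact - base
    drop <- order(frac, decreasing = FALSE)[seq_len(-leftover)]
    base[drop] <- base[drop] - 1L
  }

  set.seed(seed)
  train_idx <- integer(0)
  for (i in seq_along(classes)) {
    rows <- which(table$labels == classes[i])
    rows <- sample(rows)
    n_cl_train <- base[i]
    if (n_cl_train > length(rows)) n_cl_train <- length(rows)
    train_idx <- c(train_idx, rows[seq_len(n_cl_train)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)

  train <- ft_subset(table, train_idx)
  test <- ft_subset(table, test_idx)
  if (length(classes) == 2L) {
    if (any(tabulate(train$labels + 1L, 2L) == 0L)) {
      warning("a class has 0 training members after allocation")
    }
    if (any(tabulate(test$labels + 1L, 2L) == 0L)) {
      warning("a class has 0 test members after allocation")
    }
  }
  list(train = train, test = test)
}

#' Node dataset: one institution's train/test pair
#'
#' @param node_id string naming the node
#' @param train,test disjoint [feature_table()]s
#' @return an object of class `node_dataset`
#' @export
node_dataset <- function(node_id, train, test) {
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (length(intersect(train$sample_ids, test$sample_ids)) > 0L) {
    stop("train and test overlap by sample_id")
  }
  structure(list(node_id = node_id, train = train, test = test),
            class = "node_dataset")
}

#' Partition a cohort into per-node train/test datasets
#'
#' Convenience wrapper: [partition_cohort()] followed by a per-node
#' [train_test_split()]. Split seeds are derived deterministically from
#' `seed` (one offset per node) so nodes shuffle independently.
#'
#' @inheritParams partition_cohort
#' @param train_fraction passed to [train_test_split()]
#' @return a list of [node_dataset()] objects
#' @export
make_node_datasets <- function(table, spec, seed = 1L, train_fraction = 0.70) {
  nodes <- partition_cohort(table, spec, seed = seed)
  out <- vector("list", length(nodes))
  names(out) <- names(nodes)
  for (k in seq_along(nodes)) {
    if (n_samples(nodes[[k]]) == 0L) {
      stop("node ", names(nodes)[k], " is empty and cannot be split")
    }
    sp <- train_test_split(nodes[[k]], train_fraction = train_fraction,
                           seed = seed + 1000L * k)
    out[[k]] <- node_dataset(names(nodes)[k], sp$train, sp$test)
  }
  out
}

#' Per-node sample counts
#'
#' @param nodes a list of [node_dataset()] objects
#' @return data.frame with node, total, train, test, and per-class counts
#' @export
node_counts <- function(nodes) {
  do.call(rbind, lapply(nodes, function(nd) {
    data.frame(
      node = nd$node_id,
      total = n_samples(nd$train) + n_samples(nd$test),
      train = n_samples(nd$train),
      test = n_samples(nd$test),
      train_ci = sum(nd$train$labels == 1L),
      train_cu = sum(nd$train$labels == 0L),
      test_ci = sum(nd$test$labels == 1L),
      test_cu = sum(nd$test$labels == 0L),
      row.names = NULL
    )
  }))
}
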