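#' Derive per-stage seeds from a master seed
#'
#' Each pipeline stage draws from its own deterministic seed so that changing
#' one stage's stochastic behavior never perturbs another's. Stage seeds are
#' `(master + 10007 * stage_index) mod (2^31 - 1)` with stages ordered
#' generate, partition, local, federated.
#'
#' @param master_seed integer master seed
#' @return named integer vector with elements `generate`, `partition`,
#'   `local`, `federated`
#' @export
derive_stage_seeds <- function(master_seed) {
  stages <- c(generate = 1, partition = 2, local = 3, federated = 4)
  out <- (as.numeric(master_seed) + 10007 * stages) %% 2147483647
  stats::setNames(as.integer(out), names(stages))
}

#' Full experiment configuration
#'
#' Bundles the generator, scenario, training and federation settings for one
#' end-to-end run comparing the individual and federated training conditions.
#'
#' @param generator a [generator_config()]; its `seed` is overridden by the
#'   derived stage seed
#' @param scenario a [scenario_spec()]
#' @param training a [training_config()]
#' @param federation a [federation_config()]
#' @param threshold decision threshold for the metric panel (default 0.5)
#' @param seed master seed from which all stage seeds are derived (see
#'   [derive_stage_seeds()])
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(generator, scenario = scenario_preset("scenario1"),
                              training = training_config(),
                              federation = federation_config(training = training),
                              threshold = 0.5, seed = 1L) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(scenario, "scenario_spec"),
            inherits(training, "training_config"),
            inherits(federation, "federation_config"))
  structure(
    list(generator = generator, scenario = scenario, training = training,
         federation = federation, threshold = threshold,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run one end-to-end heterogeneity experiment
#'
#' Pipeline: generate a synthetic cohort, partition it into virtual
#' institutions per the scenario, split each node 70/30, train the
#' individual-condition models and cross-evaluate each on every node's test
#' set, train the federated condition and evaluate the global model on every
#' node's test set, and assemble the metric panel.
#'
#' If `out_dir` is given, artifacts are written there: per-node train/test
#' CSVs, the metric panel as CSV and JSON, confusion matrices, round logs
#' (JSON lines) and a run manifest (config snapshot, derived seeds, counts,
#' artifact paths) sufficient to re-run the experiment bit-identically.
#'
#' @param config an [experiment_config()]
#' @param out_dir optional output directory (created if missing)
#' @param write_tables if `TRUE` (and `out_dir` is set), write per-node
#'   feature tables as CSV; off by default since they can be large
#' @return a list with `nodes` (datasets), `counts` (per-node sample counts),
#'   `local` and `federated` fits, `reports` (list of `metrics_report`),
#'   `table` (the flattened metric panel), and `manifest`
#' @export
run_experiment <- function(config, out_dir = NULL, write_tables = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_stage_seeds(config$seed)

  gen <- config$generator
  gen$seed <- seeds[["generate"]]
  cohort <- generate_cohort(gen)

  nodes <- make_node_datasets(cohort, config$scenario,
                              seed = seeds[["partition"]])
  counts <- node_counts(nodes)

  training <- config$training
  training$seed <- seeds[["local"]]
  local_fits <- run_local_condition(nodes, training = training,
                                    hidden = config$federation$hidden)

  fed_cfg <- config$federation
  fed_cfg$seed <- seeds[["federated"]]
  fed_cfg$training$seed <- seeds[["federated"]]
  fed <- run_federated_condition(nodes, config = fed_cfg)

  scen <- config$scenario$name
  reports <- c(
    cross_evaluate_local(local_fits, nodes, threshold = config$threshold,
                         scenario = scen),
    evaluate_federated(fed, nodes, threshold = config$threshold,
                       scenario = scen)
  )
  panel <- metrics_table(reports)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fedcog")),
    master_seed = config$seed,
    stage_seeds = as.list(seeds),
    generator = unclass(config$generator),
    scenario = unclass(config$scenario),
    training = unclass(config$training),
    federation = unclass(config$federation[setdiff(names(config$federation),
                                                   "training")]),
    threshold = config$threshold,
    counts = counts,
    artifacts = character(0),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    artifacts <- character(0)
    if (write_tables) {
      for (nd in nodes) {
        for (split in c("train", "test")) {
          path <- file.path(out_dir, paste0(nd$node_id, "_", split, ".csv"))
          write_feature_table(nd[[split]], path)
          artifacts <- c(artifacts, path)
        }
      }
    }
    panel_csv <- file.path(out_dir, "metrics.csv")
    utils::write.csv(panel, panel_csv, row.names = FALSE)
    panel_json <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(panel, panel_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
    counts_json <- file.path(out_dir, "counts.json")
    jsonlite::write_json(counts, counts_json, auto_unbox = TRUE, digits = NA)
    rounds_path <- file.path(out_dir, "round_log.jsonl")
    writeLines(
      vapply(seq_len(nrow(fed$round_log)), function(i) {
        jsonlite::toJSON(as.list(fed$round_log[i, ]), auto_unbox = TRUE,
                         digits = NA, na = "null")
      }, character(1)),
      rounds_path
    )
    artifacts <- c(artifacts, panel_csv, panel_json, counts_json, rounds_path)
    manifest$artifacts <- artifacts
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
  }

  list(nodes = nodes, counts = counts, local = local_fits, federated = fed,
       reports = reports, table = panel, manifest = manifest)
}

#' Serialize model parameters to JSON
#'
#' Portable layered container (nested numeric arrays) for checkpointing and
#' aggregation transport.
#'
#' @param params a `model_params` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model_params <- function(params, path) {
  payload <- lapply(params, function(l) {
    list(W = unname(as.matrix(l$W)), b = l$b)
  })
  jsonlite::write_json(payload, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path file written by [write_model_params()]
#' @return a `model_params` object
#' @export
read_model_params <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(payload, function(el) {
    W <- do.call(rbind, lapply(el$W, function(r) as.numeric(unlist(r))))
    list(W = W, b = as.numeric(unlist(el$b)))
  })
  structure(layers, class = "model_params")
}
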