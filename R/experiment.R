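#' Experiment configuration
#'
#' Declarative description of a reproducible experiment: which
#' architecture to build, how to initialize and prune it, the dataset, the
#' seeds (ten independent repetitions by default, so summary cells report
#' a standard deviation over ten values), and optional disturbance
#' settings. Configurations can be written in YAML and loaded with
#' [read_experiment_config()].
#'
#' @param name Experiment label (used in output file names).
#' @param arch Architecture selector: a list with `kind` in
#'   `c("lenet_300_100", "lenet_4x300", "recurrent_gnp",
#'   "recurrent_encoded", "small_world")` and its parameters (`n`, `k`,
#'   `input_nodes`, ...), or directly a `layered_architecture` /
#'   [connectome_spec_bundle()].
#' @param init Initialization method (see [init_config()]) or
#'   `"structure_implantation"` / `"winning_ticket"` with `init_source` a
#'   [ternary_structure()] or trained `model_state`.
#' @param init_source Structure or trained model for implantation inits.
#' @param prune `"none"`, `"iterative"` or `"bio"`.
#' @param prune_c Mean degree for pruning / implanted structures.
#' @param dataset List of [generate_classification_dataset()] arguments,
#'   or a [labeled_dataset()].
#' @param solver Optional [solver_config()] override.
#' @param seeds Integer vector of repetition seeds (default `1:10`).
#' @param sigma,target,blocked Optional disturbance settings (see
#'   [perturbation_config()]).
#' @param out_dir Output directory.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(name, arch, init = "glorot",
                              init_source = NULL,
                              prune = "none", prune_c = NULL,
                              dataset = list(n_per_class = 60,
                                             noise_sd = 0.25),
                              solver = NULL, seeds = 1:10,
                              sigma = NULL, target = "weights",
                              blocked = FALSE, out_dir = tempdir()) {
  if (!length(seeds)) stop_config("seed list must be non-empty")
  structure(list(name = name, arch = arch, init = init,
                 init_source = init_source, prune = prune,
                 prune_c = prune_c, dataset = dataset, solver = solver,
                 seeds = as.integer(seeds), sigma = sigma, target = target,
                 blocked = blocked, out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file with the fields of [experiment_config()].
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experiment_config, y)
}

## FNV-1a over the serialized config: a stable short fingerprint embedded
## in every output file so runs can be traced back to their settings.
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.build_arch <- function(sel) {
  if (inherits(sel, "layered_architecture") ||
      inherits(sel, "connectome_spec_bundle")) {
    return(sel)
  }
  kind <- sel$kind
  switch(kind,
         lenet_300_100 = arch_lenet_300_100(),
         lenet_4x300 = arch_lenet_4x300(),
         recurrent_gnp = arch_recurrent_gnp(
           n = sel$n %||% 1194L, input_nodes = sel$input_nodes %||% 784L),
         recurrent_encoded = arch_recurrent_encoded(n = sel$n %||% 177L),
         stop_config("unknown architecture selector: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.init_model <- function(model, config, seed) {
  if (config$init %in% c("glorot", "uniform", "irnn", "lightning",
                         "dense_diversity", "sparse_diversity")) {
    init_random(model, init_config(config$init, seed = seed))
  } else if (config$init == "structure_implantation") {
    if (!inherits(config$init_source, "ternary_structure")) {
      stop_config("structure_implantation needs a ternary_structure source")
    }
    implant_structure(model, config$init_source, seed = seed)
  } else if (config$init == "winning_ticket") {
    if (!inherits(config$init_source, "model_state")) {
      stop_config("winning_ticket needs a trained model_state source")
    }
    implant_winning_ticket(model, config$init_source,
                           c = config$prune_c %||% 5, seed = seed)
  } else {
    stop_config("unknown init method: ", config$init)
  }
}

#' Run a configured experiment
#'
#' Executes generation, initialization, training (with optional pruning
#' and disturbance) for every seed of the configuration, then writes the
#' artifacts to `out_dir`: one learning-curve CSV per seed, a
#' `summary.csv` (per-seed best accuracy, learn-curve sum, gamma/delta),
#' and a `summary.json` with means, standard deviations, the graph-count
#' report of the architecture and the configuration hash. Identical
#' configurations produce identical summaries.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list with `records` (per-seed `training_record`s),
#'   `summary` (data frame) and `out_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  out <- file.path(config$out_dir, paste0(config$name, "-", hash))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dataset <- if (inherits(config$dataset, "labeled_dataset")) {
    config$dataset
  } else {
    do.call(generate_classification_dataset,
            c(config$dataset, list(seed = config$seeds[1L] + 1000L)))
  }
  arch <- .build_arch(config$arch)
  perturb <- if (!is.null(config$sigma)) {
    perturbation_config(config$sigma, config$target, config$blocked)
  } else NULL
  records <- lapply(config$seeds, function(seed) {
    model <- build_model(arch, seed = seed)
    model <- .init_model(model, config, seed)
    rec <- tryCatch(
      train_model(model, dataset, solver = config$solver,
                  prune = config$prune, prune_c = config$prune_c,
                  perturb = perturb, seed = seed),
      error = function(e) {
        message(sprintf("[%s %s] training stage failed for seed %d: %s",
                        config$name, hash, seed, conditionMessage(e)))
        NULL
      })
    if (!is.null(rec)) {
      write_learning_curve(rec, file.path(out, sprintf("curve_seed%d.csv",
                                                       seed)))
    }
    rec
  })
  ok <- !vapply(records, is.null, logical(1))
  summary_df <- data.frame(
    seed = config$seeds[ok],
    best_accuracy = vapply(records[ok], function(r) r$best_accuracy,
                           numeric(1)),
    learn_curve_sum = vapply(records[ok], function(r) r$learn_curve_sum,
                             numeric(1)),
    gamma = vapply(records[ok], function(r) r$gamma, numeric(1)),
    delta = vapply(records[ok], function(r) r$delta, numeric(1)))
  utils::write.csv(summary_df, file.path(out, "summary.csv"),
                   row.names = FALSE)
  real_arch <- if (inherits(arch, "connectome_spec_bundle")) {
    arch$architecture
  } else arch
  gcr <- graph_count_report(real_arch,
                            c = config$prune_c %||% 22)
  jsonlite::write_json(
    list(name = config$name, config_hash = hash,
         seeds = config$seeds,
         n_completed = sum(ok),
         best_accuracy_mean = mean(summary_df$best_accuracy),
         best_accuracy_sd = stats::sd(summary_df$best_accuracy),
         learn_curve_sum_mean = mean(summary_df$learn_curve_sum),
         learn_curve_sum_sd = stats::sd(summary_df$learn_curve_sum),
         graph_counts = list(
           possible_edges = gcr$possible_edges,
           existing_edges = gcr$existing_edges,
           log10_unique_graphs = gcr$log10_unique_graphs,
           log10_isomorphisms = gcr$log10_isomorphisms)),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(records = records, summary = summary_df, out_dir = out,
                 config_hash = hash))
}
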