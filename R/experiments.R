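# Experiment orchestration: a single config schema drives chain fitting,
# regime comparison, the two ablation protocols and the modality-count
# sweep. Accuracy is the ablation criterion; full metric reports are still
# emitted.

#' Experiment configuration
#'
#' One schema shared by every CLI subcommand. Data come either from CSV
#' (`data$csv` + `data$partition`) or from the synthetic generator
#' (`generator$...`). Every stochastic component's seed is explicit.
#'
#' @param data list: `csv`, `partition` (config path), `outcome`,
#'   `id_column`.
#' @param generator list: `n_samples`, `class_dependent`, `plant` (named
#'   list block -> standardized effect), `correlation`, `prevalence`.
#' @param model list: `families`, `residual_mode`, `eps`, `rule`.
#' @param seeds list: `split`, `model`, `bootstrap`, `generator`.
#' @param evaluation list: `resamples`, `n_bins`, `ratio`, `stratified`.
#' @param output_dir run directory for CLI outputs.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(data = NULL, generator = NULL,
                              model = list(), seeds = list(),
                              evaluation = list(), output_dir = ".") {
  if (is.null(data) && is.null(generator))
    pf_stop("config needs a 'data' or 'generator' section", "profuse_error_spec")
  model <- modifyList(list(families = "gbt",
                           residual_mode = "prob_residual",
                           eps = 1e-6, rule = "all_variables"), model)
  seeds <- modifyList(list(split = 1L, model = 1L, bootstrap = 1L,
                           generator = 1L), seeds)
  evaluation <- modifyList(list(resamples = 500L, n_bins = 10L,
                                ratio = 0.7, stratified = TRUE), evaluation)
  structure(list(data = data, generator = generator, model = model,
                 seeds = lapply(seeds, as.integer), evaluation = evaluation,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Read / write an experiment config (YAML or JSON)
#'
#' @param path config file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  cfg <- read_config_file(path)
  experiment_config(data = cfg$data, generator = cfg$generator,
                    model = cfg$model %||% list(),
                    seeds = cfg$seeds %||% list(),
                    evaluation = cfg$evaluation %||% list(),
                    output_dir = cfg$output_dir %||% ".")
}

#' @rdname read_experiment_config
#' @param config an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  write_config_file(unclass(config), path)
  invisible(path)
}

# Resolve the config's data source into (table, partition).
load_experiment_inputs <- function(config) {
  if (!is.null(config$data) && !is.null(config$data$csv)) {
    part <- read_partition(config$data$partition)
    tab <- read_cohort_csv(config$data$csv,
                           outcome = config$data$outcome %||% part$outcome,
                           id_column = config$data$id_column %||% "sample_id")
    return(list(table = aggregate_repeats(tab), partition = part))
  }
  g <- config$generator
  params <- table1_default_params(class_dependent =
                                    isTRUE(g$class_dependent))
  if (!is.null(g$n_samples)) params$n_samples <- as.integer(g$n_samples)
  if (!is.null(g$prevalence)) params$prevalence <- g$prevalence
  if (!is.null(g$correlation)) params$block_correlation <- g$correlation
  if (!is.null(g$availability))
    for (b in names(g$availability))
      params$availability[[b]] <- rep_len(unlist(g$availability[[b]]), 2L)
  if (!is.null(g$plant))
    for (b in names(g$plant))
      params <- plant_signal(params, b, g$plant[[b]])
  gen <- generate_cohort(params, seed = config$seeds$generator)
  list(table = gen$table, partition = default_partition(params),
       truth = gen$truth, params = params)
}

# Fit on the train split, evaluate on the test split at each sample's
# achievable depth. Shared by ablations, sweep and the CLI.
chain_experiment <- function(table, partition, config, max_depth = NULL) {
  sp <- train_test_split(table, config$evaluation$ratio,
                         seed_stream(config$seeds$split, "split"),
                         stratified = config$evaluation$stratified)
  chain <- fit_chain(subset_samples(table, sp$train_ids), partition,
                     families = config$model$families,
                     residual_mode = config$model$residual_mode,
                     seed = config$seeds$model, eps = config$model$eps,
                     rule = config$model$rule)
  test <- subset_samples(table, sp$test_ids)
  pred <- predict(chain, test, max_depth = max_depth)
  ok <- !is.na(pred$probability)
  report <- metric_report(pred$probability[ok], test$outcome[ok],
                          resamples = config$evaluation$resamples,
                          seed = seed_stream(config$seeds$bootstrap, "chain"),
                          n_bins = config$evaluation$n_bins)
  list(chain = chain, split = sp, prediction = pred, report = report,
       accuracy = report$accuracy)
}

#' Sequential-prefix ablation
#'
#' Fits the full chain once, then evaluates it capped at depths `1..T`
#' (prefixes of the fused order): depth `T` equals the full chain, depth 1
#' is the demographics-only baseline.
#'
#' @param table a [cohort_table()].
#' @param partition a [modality_partition()] in fused order.
#' @param config an [experiment_config()].
#' @return an `ablation_result` (protocol `"sequential_prefix"`).
#' @export
ablate_sequential <- function(table, partition, config = experiment_config(
                                generator = list())) {
  full <- chain_experiment(table, partition, config)
  T_ <- length(full$chain$stages)
  test <- subset_samples(table, full$split$test_ids)
  acc <- vapply(seq_len(T_), function(d) {
    pred <- predict(full$chain, test, max_depth = d)
    ok <- !is.na(pred$label)
    mean(pred$label[ok] == test$outcome[ok])
  }, 0)
  structure(list(protocol = "sequential_prefix",
                 depths = seq_len(T_),
                 blocks = names(partition$blocks)[seq_len(T_)],
                 accuracy = acc, reference = full$accuracy,
                 report = full$report),
            class = "ablation_result")
}

#' Single-block-removal ablation
#'
#' For each block in positions `2..T` the chain is retrained with that
#' block removed and the surviving order intact, then evaluated on the
#' same held-out split.
#'
#' @inheritParams ablate_sequential
#' @param include_first also ablate block 1.
#' @return an `ablation_result` (protocol `"single_removal"`).
#' @export
ablate_single <- function(table, partition, config = experiment_config(
                            generator = list()), include_first = FALSE) {
  T_ <- n_blocks(partition)
  if (T_ < 2L) pf_stop("single-removal ablation needs T >= 2",
                       "profuse_error_arg")
  full <- chain_experiment(table, partition, config)
  positions <- if (include_first) seq_len(T_) else 2:T_
  acc <- vapply(positions, function(b) {
    keep <- setdiff(seq_len(T_), b)
    if (!length(keep)) pf_stop("removal leaves zero blocks",
                               "profuse_error_arg")
    part_b <- modality_partition(partition$blocks[keep],
                                 fixed_prefix = min(partition$fixed_prefix,
                                                    length(keep)),
                                 outcome = partition$outcome)
    chain_experiment(table, part_b, config)$accuracy
  }, 0)
  structure(list(protocol = "single_removal",
                 removed = names(partition$blocks)[positions],
                 accuracy = acc, reference = full$accuracy,
                 report = full$report),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("ablation_result (%s), reference accuracy %.4f\n",
              x$protocol, x$reference))
  lab <- if (x$protocol == "sequential_prefix")
    sprintf("depth %d (%s)", x$depths, x$blocks)
  else sprintf("-%s", x$removed)
  for (i in seq_along(x$accuracy))
    cat(sprintf("  %-32s %.4f\n", lab[i], x$accuracy[i]))
  invisible(x)
}

#' Modality-count sweep: chain vs baseline regimes per depth
#'
#' For each depth `d` the data are restricted to the first `d` blocks and
#' the chain plus the applicable baseline regimes are run. A regime that
#' is infeasible at a depth (for example a complete-case set below the
#' minimum class count) is recorded with its error message rather than
#' aborting the sweep.
#'
#' @inheritParams ablate_sequential
#' @param depths subset of `1..T` (default all).
#' @param regime_families baseline families to run per regime (default all
#'   six).
#' @return list of per-depth bundles: `chain` report and per-regime
#'   results.
#' @export
modality_sweep <- function(table, partition, config = experiment_config(
                             generator = list()), depths = NULL,
                           regime_families = FAMILIES) {
  T_ <- n_blocks(partition)
  depths <- depths %||% seq_len(T_)
  if (!all(depths %in% seq_len(T_)))
    pf_stop("depths must lie in 1..T", "profuse_error_arg")
  lapply(depths, function(d) {
    part_d <- modality_partition(partition$blocks[seq_len(d)],
                                 fixed_prefix = min(partition$fixed_prefix, d),
                                 outcome = partition$outcome)
    tab_d <- subset_variables(table, block_vars(part_d, d))
    ch <- chain_experiment(tab_d, part_d, config)
    regimes <- lapply(c("max_sample", "complete_case", "imputed"),
                      function(rg) {
      tryCatch(run_regime(tab_d, part_d, rg,
                          configs = regime_families,
                          split_seed = config$seeds$split,
                          stratified = config$evaluation$stratified,
                          resamples = config$evaluation$resamples),
               profuse_error = function(e)
                 list(regime = rg, error = conditionMessage(e)))
    })
    names(regimes) <- c("max_sample", "complete_case", "imputed")
    list(depth = as.integer(d), chain = ch$report, chain_accuracy = ch$accuracy,
         regimes = regimes)
  })
}
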