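# Experiment orchestration and CLI: ablations, sweep, config round trips,
# byte-level reproducibility.

exp_cfg <- function(...) {
  experiment_config(generator = list(n_samples = 300),
                    model = list(families = "logistic"),
                    evaluation = list(resamples = 20), ...)
}

test_that("sequential ablation: depth T equals the full chain", {
  p <- plant_signal(plant_signal(tiny_params(n = 500), "a", 1), "b", 1)
  g <- generate_cohort(p, seed = 41)
  res <- ablate_sequential(g$table, tiny_partition(), exp_cfg())
  expect_equal(res$accuracy[3], res$reference)
  expect_length(res$accuracy, 3)
  expect_equal(res$protocol, "sequential_prefix")
})

test_that("sequential ablation sees the accuracy jump at the signal block", {
  # signal only in block b: depth 1 is chance, depth >= 2 is strong
  p <- plant_signal(plant_signal(plant_signal(
    tiny_params(n = 900), "a", 0), "b", 2), "c", 0)
  g <- generate_cohort(p, seed = 42)
  cfg <- experiment_config(generator = list(n_samples = 900),
                           model = list(families = "gbt"),
                           evaluation = list(resamples = 20))
  res <- ablate_sequential(g$table, tiny_partition(), cfg)
  expect_lt(res$accuracy[1], 0.62)
  expect_gt(res$accuracy[2] - res$accuracy[1], 0.2)
  expect_gt(res$accuracy[3], 0.8)  # plateau holds
})

test_that("pure-noise cohorts stay flat near chance at every depth", {
  p <- plant_signal(plant_signal(plant_signal(
    tiny_params(n = 700), "a", 0), "b", 0), "c", 0)
  g <- generate_cohort(p, seed = 43)
  res <- ablate_sequential(g$table, tiny_partition(), exp_cfg())
  expect_true(all(abs(res$accuracy - 0.5) < 0.12))
})

test_that("single-removal ablation keeps order and detects the signal block", {
  p <- plant_signal(plant_signal(plant_signal(
    tiny_params(n = 900), "a", 0), "b", 2), "c", 0)
  g <- generate_cohort(p, seed = 44)
  cfg <- experiment_config(generator = list(n_samples = 900),
                           model = list(families = "gbt"),
                           evaluation = list(resamples = 20))
  res <- ablate_single(g$table, tiny_partition(), cfg)
  expect_equal(res$removed, c("b", "c"))
  # removing the only signal block collapses accuracy to ~chance
  expect_lt(res$accuracy[res$removed == "b"], 0.62)
  # removing a pure-noise block barely moves accuracy
  expect_lt(abs(res$accuracy[res$removed == "c"] - res$reference), 0.05)
  # re-adding the removed block reproduces the full chain exactly
  again <- ablate_single(g$table, tiny_partition(), cfg)
  expect_identical(res$accuracy, again$accuracy)
  expect_identical(res$reference, again$reference)

  expect_error(ablate_single(g$table,
                             modality_partition(list(a = c("a1", "a2", "a3"))),
                             cfg),
               class = "profuse_error_arg")
})

test_that("modality_sweep returns one bundle per depth", {
  g <- generate_cohort(tiny_params(n = 300, avail_b = 0.8, avail_c = 0.8),
                       seed = 45)
  res <- modality_sweep(g$table, tiny_partition(), exp_cfg(),
                        depths = c(2, 3), regime_families = "logistic")
  expect_length(res, 2)
  expect_equal(vapply(res, `[[`, 0L, "depth"), c(2L, 3L))
  expect_named(res[[1]]$regimes, c("max_sample", "complete_case", "imputed"))
  expect_error(modality_sweep(g$table, tiny_partition(), exp_cfg(),
                              depths = 5),
               class = "profuse_error_arg")
  # depth-1 sweep point: the chain reduces to stage 1
  r1 <- modality_sweep(g$table, tiny_partition(), exp_cfg(), depths = 1,
                       regime_families = "logistic")
  expect_equal(r1[[1]]$depth, 1L)
})

test_that("experiment config round-trips through YAML and JSON", {
  cfg <- experiment_config(generator = list(n_samples = 123,
                                            plant = list(b = 1.5)),
                           model = list(families = c("gbt", "logistic")),
                           seeds = list(split = 4, model = 5),
                           evaluation = list(resamples = 77))
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_experiment_config(cfg, f)
    back <- read_experiment_config(f)
    expect_equal(back$generator$n_samples, 123)
    expect_equal(back$generator$plant$b, 1.5)
    expect_equal(back$model$families, c("gbt", "logistic"))
    expect_equal(back$seeds$split, 4L)
    expect_equal(back$seeds$model, 5L)
    expect_equal(back$evaluation$resamples, 77)
    unlink(f)
  }
  expect_error(experiment_config(), class = "profuse_error_spec")
})

test_that("cohort CSV and partition configs round-trip", {
  g <- generate_cohort(tiny_params(n = 40, avail_b = 0.5), seed = 46)
  d <- tempfile(); dir.create(d)
  csv <- file.path(d, "cohort.csv")
  write_cohort_csv(g$table, csv, truth = g$truth)
  expect_true(file.exists(file.path(d, "cohort_truth.csv")))
  back <- read_cohort_csv(csv, id_column = "sample_id")
  expect_equal(back$data, g$table$data, tolerance = 1e-12)
  expect_identical(back$outcome, g$table$outcome)
  expect_identical(back$sample_ids, g$table$sample_ids)

  pf <- file.path(d, "partition.yaml")
  write_partition(tiny_partition(), pf)
  p2 <- read_partition(pf)
  expect_identical(p2$blocks, tiny_partition()$blocks)
  expect_identical(p2$fixed_prefix, tiny_partition()$fixed_prefix)
  unlink(d, recursive = TRUE)
})

test_that("repeats CSV is consumed through the reader", {
  g <- generate_cohort(tiny_params(n = 20), seed = 47)
  d <- tempfile(); dir.create(d)
  csv <- file.path(d, "cohort.csv")
  write_cohort_csv(g$table, csv)
  rp <- file.path(d, "repeats.csv")
  write.csv(data.frame(sample_id = c("1", "1", "2"),
                       variable = c("b1", "b1", "c1"),
                       value = c(5, 7, 2)),
            rp, row.names = FALSE)
  tab <- read_cohort_csv(csv, id_column = "sample_id", repeats_path = rp)
  tab <- aggregate_repeats(tab)
  expect_equal(tab$data$b1[1], 6)
  expect_equal(tab$data$c1[2], 2)
  unlink(d, recursive = TRUE)
})

test_that("CLI subcommands run and byte-reproduce their outputs", {
  d <- tempfile(); dir.create(d)
  cfgf <- file.path(d, "cfg.yaml")
  write_experiment_config(
    experiment_config(generator = list(n_samples = 200),
                      model = list(families = "logistic"),
                      evaluation = list(resamples = 25),
                      seeds = list(split = 2, model = 2, bootstrap = 2,
                                   generator = 2)),
    cfgf)

  out1 <- file.path(d, "run1"); out2 <- file.path(d, "run2")
  for (o in c(out1, out2)) {
    profuse_cli(c("simulate", "--config", cfgf, "--out", o))
    profuse_cli(c("fit", "--config", cfgf, "--out", o))
    profuse_cli(c("predict", "--config", cfgf, "--out", o))
    profuse_cli(c("evaluate", "--config", cfgf, "--out", o))
    profuse_cli(c("ablate", "--config", cfgf, "--out", o))
  }
  for (f in c("cohort.csv", "cohort_truth.csv", "partition.yaml",
              "split.json", "metrics.json", "predictions.csv",
              "ablation.json", "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     info = f)
  }
  # manifest carries the config hash and seeds
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$command, "ablate")
  expect_match(man$config_hash, "^[0-9a-f]{8}$")
  expect_equal(man$seeds$split, 2L)

  # --seed overrides every seed in the set
  profuse_cli(c("evaluate", "--config", cfgf, "--seed", "9", "--out",
                file.path(d, "run3")))
  man3 <- jsonlite::read_json(file.path(d, "run3", "manifest.json"))
  expect_equal(man3$seeds$model, 9L)

  expect_error(profuse_cli(c("evaluate")), class = "profuse_error_arg")
  expect_error(profuse_cli(c("nope", "--config", cfgf)),
               class = "profuse_error_arg")
  unlink(d, recursive = TRUE)
})
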