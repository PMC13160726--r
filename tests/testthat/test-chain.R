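# Progressive fusion chain: stage-1 equivalence, residual behaviour,
# depth/gap rules, determinism, ordering, serialization.

test_that("a 1-block chain is bitwise identical to the standalone stage-1 model", {
  g <- generate_cohort(tiny_params(n = 250), seed = 2)
  part1 <- modality_partition(list(a = c("a1", "a2", "a3")))
  ch <- fit_chain(g$table, part1, families = "gbt", seed = 17)
  pr <- predict(ch, g$table)

  dm <- encode(g$table, g$table$sample_ids, variables = c("a1", "a2", "a3"))
  solo <- fit_stage1(dm$x, g$table$outcome, "gbt",
                     seed = profuse:::seed_stream(17, "stage", 1))
  expect_identical(pr$probability,
                   unname(pmin(pmax(predict(solo, dm$x), 1e-6), 1 - 1e-6)))
})

test_that("a constant new block leaves predictions essentially unchanged", {
  run_one <- function(seed, mode) {
    p <- plant_signal(tiny_params(n = 600), "a", 1.5)
    g <- generate_cohort(p, seed = seed)
    tab <- g$table
    tab$data$b1 <- 0; tab$data$b2 <- 0  # stage-2 block carries nothing
    sp <- train_test_split(tab, 0.7, seed = seed)
    tr <- profuse:::subset_samples(tab, sp$train_ids)
    te <- profuse:::subset_samples(tab, sp$test_ids)
    ch <- fit_chain(tr, modality_partition(list(a = c("a1", "a2", "a3"),
                                                b = c("b1", "b2"))),
                    seed = seed, residual_mode = mode)
    t2 <- attr(predict(ch, te), "trace")
    c(mad = mean(abs(t2[, 2] - t2[, 1])),
      dacc = mean((t2[, 2] >= 0.5) == te$outcome) -
        mean((t2[, 1] >= 0.5) == te$outcome))
  }
  # default mode: probability drift within 0.02 MAD (averaged over seeds)
  res <- vapply(1:5, run_one, numeric(2), mode = "prob_residual")
  expect_lt(mean(res["mad", ]), 0.02)
  expect_lt(abs(mean(res["dacc", ])), 0.02)
  # alternate modes re-learn earlier blocks (label-target inflation, see
  # vignette) and only guarantee accuracy-level no-harm
  for (mode in c("logit_residual", "stacking")) {
    res <- vapply(1:3, run_one, numeric(2), mode = mode)
    expect_lt(abs(mean(res["dacc", ])), 0.02)
  }
})

test_that("an outcome-leaking stage drives training error to zero", {
  g <- generate_cohort(tiny_params(n = 300), seed = 6)
  tab <- g$table
  tab$data$b1 <- as.numeric(tab$outcome)  # stage-2 block contains the label
  ch <- fit_chain(tab, modality_partition(list(a = c("a1", "a2", "a3"),
                                               b = c("b1", "b2"))),
                  seed = 6)
  pr <- predict(ch, tab)
  expect_equal(mean(pr$label == tab$outcome), 1)
  expect_lt(mean(abs(pr$probability - tab$outcome)), 0.05)
})

test_that("a perfect prior is a fixed point of the residual stage", {
  set.seed(10)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(2 * n), n)
  prior <- ifelse(y == 1, 1 - 1e-6, 1e-6)
  st <- fit_residual_stage(x, y, prior, "gbt", seed = 1)
  p2 <- profuse:::predict_stage_probs(st, x, prior)
  expect_lt(max(abs(p2 - prior)), 0.01)
})

test_that("depth follows the longest observed prefix; gaps stop the chain", {
  g <- generate_cohort(tiny_params(n = 300, avail_b = 0.7, avail_c = 0.7),
                       seed = 8)
  ch <- fit_chain(g$table, tiny_partition(), seed = 8)

  tab <- g$table
  # sample 1: all blocks; sample 2: gap at b with c present; sample 3: only a;
  # sample 4: block a missing -> unpredictable
  tab$data[1, ] <- 0
  tab$data[2, c("b1", "b2")] <- NA; tab$data[2, "c1"] <- 0.5
  tab$data[2, c("a1", "a2", "a3")] <- 0
  tab$data[3, c("b1", "b2", "c1")] <- NA
  tab$data[3, c("a1", "a2", "a3")] <- 0
  tab$data[4, "a1"] <- NA
  pr <- predict(ch, tab)
  expect_equal(pr$depth[1:4], c(3L, 1L, 1L, 0L))
  expect_true(is.na(pr$probability[4]))
  expect_true(is.na(pr$label[4]))
  # a sample with only block 1 gets exactly the stage-1 output
  expect_equal(pr$probability[3], attr(pr, "trace")[3, 1])
  # trace stops at the reached depth
  expect_true(all(is.na(attr(pr, "trace")[2, 2:3])))

  # max_depth cap reproduces prefix evaluation
  pr1 <- predict(ch, tab, max_depth = 1)
  expect_true(all(pr1$depth <= 1))
  expect_equal(pr1$probability[1], attr(pr, "trace")[1, 1])
})

test_that("chains are deterministic and truncate on untrainable stages", {
  g <- generate_cohort(tiny_params(n = 250, avail_b = 0.6), seed = 9)
  ch1 <- fit_chain(g$table, tiny_partition(), seed = 11)
  ch2 <- fit_chain(g$table, tiny_partition(), seed = 11)
  expect_identical(predict(ch1, g$table)$probability,
                   predict(ch2, g$table)$probability)
  ch3 <- fit_chain(g$table, tiny_partition(), seed = 12)
  expect_false(identical(predict(ch1, g$table)$probability,
                         predict(ch3, g$table)$probability))

  # empty stage-3 eligible set -> truncation warning, 2-stage chain
  gz <- generate_cohort(tiny_params(n = 250, avail_c = 0), seed = 9)
  expect_warning(chz <- fit_chain(gz$table, tiny_partition(), seed = 1),
                 class = "profuse_warning_truncated")
  expect_length(chz$stages, 2L)

  # stage-1 untrainable is an error
  g1 <- generate_cohort(tiny_params(n = 50), seed = 2)
  tab <- g1$table
  tab$data$a1 <- NA_real_
  expect_error(fit_chain(tab, tiny_partition(), seed = 1),
               class = "profuse_error_empty_stage")
})

test_that("chain archives round-trip exactly", {
  g <- generate_cohort(tiny_params(n = 200), seed = 5)
  ch <- fit_chain(g$table, tiny_partition(), seed = 5)
  f <- tempfile(fileext = ".rds")
  chain_save(ch, f)
  back <- chain_load(f)
  expect_identical(predict(back, g$table)$probability,
                   predict(ch, g$table)$probability)
  unlink(f)
  suppressWarnings(expect_error(chain_load(tempfile()), "cannot open"))
})

test_that("order_modalities prefers signal, keeps ties in declaration order", {
  # informative block b (d = 1.2) vs pure-noise block c
  p <- plant_signal(plant_signal(tiny_params(n = 400), "b", 1.2), "c", 0)
  g <- generate_cohort(p, seed = 21)
  ord <- order_modalities(g$table, tiny_partition(), families = "logistic",
                          inner_folds = 3, seed = 21)
  expect_equal(names(ord$blocks), c("a", "b", "c"))
  expect_error(order_modalities(g$table, tiny_partition(), inner_folds = 1),
               class = "profuse_error_arg")

  # byte-identical duplicate candidate blocks: declaration order preserved
  tab <- g$table
  tab$data$c1 <- tab$data$b1
  part_dup <- modality_partition(list(a = c("a1", "a2", "a3"),
                                      b = "b1", c = "c1"))
  ord2 <- order_modalities(tab, part_dup, families = "logistic",
                           inner_folds = 3, seed = 3)
  expect_equal(names(ord2$blocks), c("a", "b", "c"))

  # single remaining candidate: trivially determined
  part2 <- modality_partition(list(a = c("a1", "a2", "a3"), b = c("b1", "b2")),
                              fixed_prefix = 1L)
  ord3 <- order_modalities(g$table, part2, families = "logistic",
                           inner_folds = 2, seed = 1)
  expect_equal(names(ord3$blocks), c("a", "b"))
})

test_that("two informative blocks beat one (signal split across blocks)", {
  p <- plant_signal(plant_signal(tiny_params(n = 1200), "a", 0.8), "b", 0.8)
  g <- generate_cohort(p, seed = 31)
  acc1 <- heldout_accuracy(g$table, tiny_partition(), seed = 31, max_depth = 1)
  acc2 <- heldout_accuracy(g$table, tiny_partition(), seed = 31, max_depth = 2)
  expect_gt(acc2, acc1)
})
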