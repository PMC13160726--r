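# Baselines, random-forest imputation, regimes, leakage guards.

test_that("fit_baseline rejects missing matrices and records its config", {
  x <- matrix(rnorm(40), ncol = 2)
  y <- rep(c(0, 1), 10)
  cfg <- baseline_config("knn", seed = 3)
  expect_equal(cfg$hyperparameters$k, 10L)
  xna <- x; xna[1, 1] <- NA
  expect_error(fit_baseline(cfg, xna, y), class = "profuse_error_missing")
  m <- fit_baseline(cfg, x, y)
  expect_identical(predict(m, x), predict(fit_baseline(cfg, x, y), x))
  expect_equal(m$config, cfg$hyperparameters)
})

test_that("rf_impute: identity on complete data, never alters observed cells", {
  g <- generate_cohort(tiny_params(n = 120), seed = 1)
  out <- rf_impute(g$table, seed = 1)
  expect_identical(out$data, g$table$data)
  expect_equal(attr(out, "imputer")$iterations, 0L)

  gm <- generate_cohort(tiny_params(n = 150, avail_b = 0.7, avail_c = 0.6),
                        seed = 2)
  comp <- rf_impute(gm$table, seed = 2, n_trees = 10, max_iter = 2)
  expect_false(anyNA(comp$data))
  obs <- !is.na(as.matrix(gm$table$data))
  expect_identical(as.matrix(comp$data)[obs],
                   as.matrix(gm$table$data)[obs])  # bitwise untouched
  # deterministic
  comp2 <- rf_impute(gm$table, seed = 2, n_trees = 10, max_iter = 2)
  expect_identical(comp$data, comp2$data)

  tab <- gm$table
  tab$data$c1 <- NA_real_
  expect_error(rf_impute(tab, seed = 1),
               class = "profuse_error_all_missing")
})

test_that("rf_impute reproduces an exact duplicate column", {
  set.seed(4)
  v <- rep(c(1.25, 2.5, 3.75, 5), 25)[sample(100)]
  tab <- cohort_table(data.frame(u = v, dup = v, w = rnorm(100)),
                      outcome = rep(c(0, 1), 50))
  tab$data$dup[17] <- NA
  out <- rf_impute(tab, seed = 7)
  expect_equal(out$data$dup[17], v[17], tolerance = 1e-6)
})

test_that("rf_impute beats marginal imputation on correlated MCAR data", {
  withr::with_seed(5, {
    n <- 600
    z <- rnorm(n)
    dat <- data.frame(g = z + rnorm(n, sd = 0.3),
                      h = z + rnorm(n, sd = 0.3),
                      k = rnorm(n))
    truth <- dat$g
    mask <- sample(n, n * 0.2)
    dat$g[mask] <- NA
    tab <- cohort_table(dat, outcome = rep(c(0, 1), n / 2))
    out <- rf_impute(tab, seed = 5, n_trees = 20)
    rmse <- sqrt(mean((out$data$g[mask] - truth[mask])^2))
    expect_lt(rmse, sd(truth))  # far below the marginal SD
  })
})

test_that("impute_apply fills new rows from training-fitted state only", {
  gm <- generate_cohort(tiny_params(n = 200, avail_b = 0.7), seed = 3)
  sp <- train_test_split(gm$table, 0.7, seed = 3)
  tr <- profuse:::subset_samples(gm$table, sp$train_ids)
  te <- profuse:::subset_samples(gm$table, sp$test_ids)
  fit <- rf_impute(tr, seed = 3, n_trees = 10, max_iter = 2)
  filled <- impute_apply(attr(fit, "imputer"), te)
  expect_false(anyNA(filled$data))
  obs <- !is.na(as.matrix(te$data))
  expect_identical(as.matrix(filled$data)[obs], as.matrix(te$data)[obs])
})

test_that("train/test split is stratified, seeded and reproducible", {
  g <- generate_cohort(tiny_params(n = 200, prevalence = 0.3), seed = 6)
  s1 <- train_test_split(g$table, 0.7, seed = 8)
  s2 <- train_test_split(g$table, 0.7, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$train_ids,
                         train_test_split(g$table, 0.7, seed = 9)$train_ids))
  tr <- profuse:::subset_samples(g$table, s1$train_ids)
  expect_equal(mean(tr$outcome), mean(g$table$outcome), tolerance = 0.01)
  expect_equal(length(s1$train_ids), 140)
})

test_that("regimes: row accounting and identical rows under full availability", {
  g <- generate_cohort(tiny_params(n = 240, avail_b = 0.8, avail_c = 0.8),
                       seed = 7)
  part <- tiny_partition()
  rmax <- run_regime(g$table, part, "max_sample", configs = "logistic",
                     split_seed = 5, resamples = 20)
  rcc <- run_regime(g$table, part, "complete_case", configs = "logistic",
                    split_seed = 5, resamples = 20)
  expect_gte(rmax$n_train, rcc$n_train)  # max-sample always has >= rows
  expect_gt(rmax$n_train, rcc$n_train)   # strict under availability < 1
  expect_true(all(rcc$train_ids %in% rmax$train_ids))

  gfull <- generate_cohort(tiny_params(n = 240), seed = 7)
  fmax <- run_regime(gfull$table, part, "max_sample", configs = "logistic",
                     split_seed = 5, resamples = 20)
  fcc <- run_regime(gfull$table, part, "complete_case", configs = "logistic",
                    split_seed = 5, resamples = 20)
  expect_identical(fmax$train_ids, fcc$train_ids)  # same rows, different cols
  expect_identical(fmax$test_ids, fcc$test_ids)

  # thin complete-case sets raise the typed error
  gthin <- generate_cohort(tiny_params(n = 240, avail_b = 0.05), seed = 7)
  expect_error(run_regime(gthin$table, part, "complete_case",
                          configs = "logistic", split_seed = 5),
               class = "profuse_error_complete_case")
})

test_that("complete-case beats max-sample when the signal lives in block 2", {
  p <- plant_signal(plant_signal(tiny_params(n = 900, avail_b = 0.75,
                                             avail_c = 0.75), "a", 0), "b", 2)
  g <- generate_cohort(p, seed = 12)
  part <- tiny_partition()
  rmax <- run_regime(g$table, part, "max_sample", configs = "gbt",
                     split_seed = 12, resamples = 20)
  rcc <- run_regime(g$table, part, "complete_case", configs = "gbt",
                    split_seed = 12, resamples = 20)
  expect_gt(rcc$reports$gbt$accuracy, rmax$reports$gbt$accuracy)
})

test_that("imputed regime runs leak-free and completes both folds", {
  g <- generate_cohort(tiny_params(n = 240, avail_b = 0.7, avail_c = 0.7),
                       seed = 9)
  rr <- run_regime(g$table, tiny_partition(), "imputed",
                   configs = c("logistic", "gbt"), split_seed = 9,
                   resamples = 20,
                   impute_args = list(n_trees = 10L, max_iter = 2L))
  expect_named(rr$reports, c("logistic", "gbt"))
  expect_equal(rr$n_train + rr$n_test, 240)
  expect_false(is.null(rr$imputer))
})

test_that("sentinels in test rows cannot alter training-fitted state", {
  g <- generate_cohort(tiny_params(n = 200, avail_b = 0.7), seed = 10)
  # match run_regime's internal split so the poisoned rows are exactly its
  # held-out fold
  sp <- train_test_split(g$table, 0.7, profuse:::seed_stream(10, "split"))
  poisoned <- g$table
  te_rows <- match(sp$test_ids, poisoned$sample_ids)
  poisoned$data[te_rows, c("a1", "a2")] <- 9e9  # sentinel

  # encoder state
  enc_clean <- encode(g$table, sp$train_ids, standardize = TRUE)$fit_state
  enc_dirty <- encode(poisoned, sp$train_ids, standardize = TRUE)$fit_state
  expect_identical(enc_clean, enc_dirty)

  # imputer state (fit on train rows only)
  imp_clean <- attr(rf_impute(profuse:::subset_samples(g$table, sp$train_ids),
                              seed = 1, n_trees = 5, max_iter = 1), "imputer")
  imp_dirty <- attr(rf_impute(profuse:::subset_samples(poisoned, sp$train_ids),
                              seed = 1, n_trees = 5, max_iter = 1), "imputer")
  expect_identical(imp_clean, imp_dirty)

  # end-to-end: regime fit state identical under test-row poisoning
  r_clean <- run_regime(g$table, tiny_partition(), "imputed",
                        configs = "logistic", split_seed = 10,
                        resamples = 10,
                        impute_args = list(n_trees = 5L, max_iter = 1L))
  # sentinel rows may yield degenerate predictions; only the fitted state
  # matters here
  r_dirty <- suppressWarnings(
    run_regime(poisoned, tiny_partition(), "imputed",
               configs = "logistic", split_seed = 10, resamples = 10,
               impute_args = list(n_trees = 5L, max_iter = 1L)))
  expect_identical(r_clean$imputer, r_dirty$imputer)
  expect_identical(r_clean$fit_state, r_dirty$fit_state)
})
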