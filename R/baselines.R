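# Baseline comparison arms.
#
# Three data regimes confront the fusion chain with the classical ways of
# handling modular missingness:
#   max_sample    -- block-1 features only, every sample (max rows);
#   complete_case -- all features, only fully observed samples (max cols);
#   imputed       -- all features after random-forest imputation.
# Imputation and all preprocessing are fitted on training rows only.

#' Baseline model configuration
#'
#' Resolves and freezes every hyperparameter of one of the six baseline
#' families so results are reproducible from the config alone.
#'
#' @param family family identifier (see [fit_model()]).
#' @param params overrides merged over [default_config()].
#' @param seed integer seed.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(family, params = list(), seed = 0L) {
  structure(list(family = family,
                 hyperparameters = modifyList(default_config(family), params),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Fit a baseline classifier on complete data
#'
#' @param config a [baseline_config()].
#' @param x numeric design matrix without missing entries (the regimes
#'   guarantee this; missing entries raise a typed error directing the
#'   caller to a regime).
#' @param labels 0/1 outcomes.
#' @return a `pf_model`.
#' @export
fit_baseline <- function(config, x, labels) {
  if (anyNA(x))
    pf_stop("design matrix has missing entries; use run_regime() to obtain a complete matrix",
            "profuse_error_missing")
  fit_model(config$family, x, labels, "classification",
            seed = config$seed, params = config$hyperparameters)
}

# Fixed-width numeric design for the imputer: one-hot over the spec's full
# category set so the matrix shape never depends on which rows are present.
impute_design <- function(data, specs, exclude) {
  cols <- list()
  for (v in setdiff(names(data), exclude)) {
    kind <- specs[[v]]$kind
    if (kind == "categorical") {
      k <- length(specs[[v]]$categories)
      m <- matrix(0, nrow(data), k)
      for (j in seq_len(k)) m[, j] <- as.numeric(data[[v]] == j)
      colnames(m) <- paste0(v, "=", seq_len(k))
      cols[[v]] <- m
    } else {
      cols[[v]] <- matrix(data[[v]], ncol = 1, dimnames = list(NULL, v))
    }
  }
  do.call(cbind, cols)
}

init_fill <- function(data, specs) {
  fills <- list()
  for (v in names(data)) {
    obs <- data[[v]][!is.na(data[[v]])]
    if (!length(obs))
      pf_stop(sprintf("variable '%s' is 100%% missing; cannot impute", v),
              "profuse_error_all_missing")
    fills[[v]] <- if (specs[[v]]$kind == "continuous") mean(obs) else {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])
    }
  }
  fills
}

impute_one_pass <- function(work, miss_mask, specs, forests) {
  for (v in names(forests)) {
    mis <- which(miss_mask[[v]])
    if (!length(mis)) next
    xm <- impute_design(work, specs, exclude = v)[mis, , drop = FALSE]
    fv <- forests[[v]]
    if (fv$type == "categorical") {
      scores <- vapply(fv$models, function(m) predict_forest(m, xm),
                       numeric(length(mis)))
      scores <- matrix(scores, length(mis))
      work[[v]][mis] <- fv$levels[max.col(scores, ties.method = "first")]
    } else {
      pred <- predict_forest(fv$model, xm)
      if (fv$type == "binary") pred <- as.numeric(pred >= 0.5)
      work[[v]][mis] <- pred
    }
  }
  work
}

#' Random-forest imputation of a cohort table
#'
#' Iterative chained imputation in the missForest style: starting from
#' mean/mode fills, each incomplete variable is regressed (continuous) or
#' classified (binary/categorical, via per-level one-vs-rest regression
#' forests) on all other variables, cycling in order of increasing
#' missingness until the imputed values stabilise or `max_iter` is
#' reached. Observed cells are never altered.
#'
#' @param table a [cohort_table()]; every variable needs at least one
#'   observed value.
#' @param seed integer seed for the forests.
#' @param max_iter maximum sweeps over the incomplete variables.
#' @param n_trees trees per forest.
#' @param tol relative-change convergence tolerance.
#' @return the completed [cohort_table()]; the fitted imputer (fills,
#'   variable order, final-sweep forests) is attached as attribute
#'   `"imputer"` for out-of-sample use via [impute_apply()].
#' @export
rf_impute <- function(table, seed = 0L, max_iter = 10L, n_trees = 30L,
                      tol = 1e-3, max_depth = 12L) {
  data <- table$data
  specs <- table$specs
  fills <- init_fill(data, specs)
  miss_mask <- lapply(data, is.na)
  n_miss <- vapply(miss_mask, sum, 0L)
  targets <- names(sort(n_miss[n_miss > 0L]))
  if (!length(targets)) {
    out <- table
    attr(out, "imputer") <- structure(
      list(fills = fills, targets = character(), forests = list(),
           specs = specs, iterations = 0L), class = "pf_imputer")
    return(out)
  }
  work <- data
  for (v in names(fills)) work[[v]][miss_mask[[v]]] <- fills[[v]]

  forests <- list()
  prev_change <- Inf
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    iters <- iter
    old <- work
    for (v in targets) {
      obs <- which(!miss_mask[[v]])
      mis <- which(miss_mask[[v]])
      xd <- impute_design(work, specs, exclude = v)
      fseed <- seed_stream(seed, "impute", iter, v)
      if (specs[[v]]$kind == "categorical") {
        levs <- sort(unique(data[[v]][obs]))
        models <- lapply(levs, function(l)
          fit_forest(xd[obs, , drop = FALSE],
                     as.numeric(data[[v]][obs] == l),
                     n_trees = n_trees, max_depth = max_depth,
                     mtry = ncol(xd),
                     seed = seed_stream(fseed, "level", l)))
        forests[[v]] <- list(type = "categorical", levels = levs,
                             models = models)
        scores <- vapply(models, function(m)
          predict_forest(m, xd[mis, , drop = FALSE]), numeric(length(mis)))
        scores <- matrix(scores, length(mis))
        work[[v]][mis] <- levs[max.col(scores, ties.method = "first")]
      } else {
        # bagging without feature subsampling: with few predictors a
        # sqrt-mtry tree can miss the informative column entirely, and
        # imputation needs conditional-mean fidelity more than
        # decorrelation
        model <- fit_forest(xd[obs, , drop = FALSE], data[[v]][obs],
                            n_trees = n_trees, max_depth = max_depth,
                            mtry = ncol(xd), seed = fseed)
        pred <- predict_forest(model, xd[mis, , drop = FALSE])
        if (specs[[v]]$kind == "binary") pred <- as.numeric(pred >= 0.5)
        forests[[v]] <- list(type = specs[[v]]$kind, model = model)
        work[[v]][mis] <- pred
      }
    }
    num <- den <- 0
    for (v in targets) {
      mis <- miss_mask[[v]]
      num <- num + sum((work[[v]][mis] - old[[v]][mis])^2)
      den <- den + sum(work[[v]][mis]^2)
    }
    change <- if (den > 0) num / den else 0
    if (change < tol || change > prev_change) break
    prev_change <- change
  }
  out <- cohort_table(work, table$outcome, specs = specs,
                      sample_ids = table$sample_ids)
  attr(out, "imputer") <- structure(
    list(fills = fills, targets = targets, forests = forests,
         specs = specs, iterations = iters, passes = 2L),
    class = "pf_imputer")
  out
}

#' Apply a training-fitted imputer to new rows
#'
#' Initial mean/mode fills and all forests come from the training fit;
#' the new rows are cycled through the stored forests for a fixed number
#' of passes. Observed cells are never altered.
#'
#' @param imputer the `"imputer"` attribute of an [rf_impute()] result.
#' @param table a [cohort_table()] with the same variables.
#' @return the completed table.
#' @export
impute_apply <- function(imputer, table) {
  work <- table$data
  miss_mask <- lapply(work, is.na)
  for (v in names(work)) {
    if (any(miss_mask[[v]])) {
      if (is.null(imputer$fills[[v]]))
        pf_stop(sprintf("imputer has no fill for variable '%s'", v),
                "profuse_error_arg")
      work[[v]][miss_mask[[v]]] <- imputer$fills[[v]]
    }
  }
  for (pass in seq_len(imputer$passes %||% 2L))
    work <- impute_one_pass(work, miss_mask, imputer$specs, imputer$forests)
  cohort_table(work, table$outcome, specs = table$specs,
               sample_ids = table$sample_ids)
}

#' Stratified (or simple) train/test split
#'
#' @param table a [cohort_table()].
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @param stratified preserve class balance across the split (default).
#' @return list of `train_ids` and `test_ids`.
#' @export
train_test_split <- function(table, ratio = 0.7, seed = 0L,
                             stratified = TRUE) {
  n <- length(table$sample_ids)
  with_seed(seed, {
    if (stratified) {
      tr <- integer()
      for (cl in c(0L, 1L)) {
        idx <- which(table$outcome == cl)
        tr <- c(tr, sample(idx, round(ratio * length(idx))))
      }
    } else {
      tr <- sample.int(n, round(ratio * n))
    }
    tr <- sort(tr)
    list(train_ids = table$sample_ids[tr],
         test_ids = table$sample_ids[-tr])
  })
}

#' Run one baseline data regime
#'
#' Splits 70/30 (stratified by default), prepares the regime's complete
#' design matrices with training-only fit state, fits every configured
#' family and evaluates on the held-out 30%.
#'
#' @param table a [cohort_table()].
#' @param partition a [modality_partition()].
#' @param regime `"max_sample"`, `"complete_case"` or `"imputed"`.
#' @param configs families to run: character vector or list of
#'   [baseline_config()]s (default all six).
#' @param split_seed seed controlling the split and model fits.
#' @param stratified stratify the split.
#' @param resamples bootstrap resamples for the AUC CI.
#' @param impute_whole_table sensitivity switch reproducing the
#'   impute-before-split protocol (leaks test rows into the imputer; off
#'   by default).
#' @param impute_args extra arguments passed to [rf_impute()] (forest
#'   size, iteration cap) for runtime control.
#' @return an object of class `regime_result`: per-family
#'   [metric_report()]s, sample counts, predictions, and the
#'   training-fitted preprocessing/imputer state.
#' @export
run_regime <- function(table, partition,
                       regime = c("max_sample", "complete_case", "imputed"),
                       configs = FAMILIES, split_seed = 0L,
                       stratified = TRUE, resamples = 500L,
                       impute_whole_table = FALSE, impute_args = list()) {
  regime <- match.arg(regime)
  if (is.character(configs)) {
    configs <- lapply(configs, function(f)
      baseline_config(f, seed = seed_stream(split_seed, "baseline", f)))
  }
  names(configs) <- vapply(configs, `[[`, "", "family")
  sp <- train_test_split(table, 0.7, seed_stream(split_seed, "split"),
                         stratified = stratified)
  T_ <- n_blocks(partition)
  imputer <- NULL

  if (regime == "max_sample") {
    vars <- partition$blocks[[1L]]
    tr_ids <- intersect(sp$train_ids, stage_eligible(table, partition, 1L))
    te_ids <- intersect(sp$test_ids, stage_eligible(table, partition, 1L))
    work <- table
  } else if (regime == "complete_case") {
    vars <- block_vars(partition, T_)
    full <- stage_eligible(table, partition, T_)
    tr_ids <- intersect(sp$train_ids, full)
    te_ids <- intersect(sp$test_ids, full)
    tr_cls <- subset_samples(table, tr_ids)$outcome
    cnt <- c(sum(tr_cls == 0L), sum(tr_cls == 1L))
    if (any(cnt < 10L))
      pf_stop(sprintf("complete-case training set has < 10 samples in a class (%s)",
                      paste(cnt, collapse = "/")),
              "profuse_error_complete_case")
    work <- table
  } else {
    vars <- block_vars(partition, T_)
    if (impute_whole_table) {
      work <- do.call(rf_impute,
                      c(list(table, seed = seed_stream(split_seed, "impute")),
                        impute_args))
      imputer <- attr(work, "imputer")
    } else {
      tr_tab <- do.call(rf_impute,
                        c(list(subset_samples(table, sp$train_ids),
                               seed = seed_stream(split_seed, "impute")),
                          impute_args))
      imputer <- attr(tr_tab, "imputer")
      te_tab <- impute_apply(imputer, subset_samples(table, sp$test_ids))
      merged <- rbind(tr_tab$data, te_tab$data)
      ids <- c(tr_tab$sample_ids, te_tab$sample_ids)
      work <- cohort_table(merged, c(tr_tab$outcome, te_tab$outcome),
                           specs = table$specs, sample_ids = ids)
    }
    tr_ids <- sp$train_ids
    te_ids <- sp$test_ids
  }

  te_out <- subset_samples(work, te_ids)$outcome
  tr_out <- subset_samples(work, tr_ids)$outcome
  if (length(unique(te_out)) < 2L || length(unique(tr_out)) < 2L)
    pf_stop("regime split left a single-class train or test set",
            "profuse_error_single_class")

  reports <- list(); preds <- list(); enc_states <- list()
  sub <- subset_samples(work, c(tr_ids, te_ids))
  for (fam in names(configs)) {
    dm <- encode(sub, train_ids = tr_ids,
                 standardize = standardize_required(fam), variables = vars)
    enc_states[[fam]] <- dm$fit_state
    xtr <- dm$x[match(tr_ids, sub$sample_ids), , drop = FALSE]
    xte <- dm$x[match(te_ids, sub$sample_ids), , drop = FALSE]
    model <- fit_baseline(configs[[fam]], xtr, tr_out)
    p <- predict(model, xte)
    preds[[fam]] <- data.frame(sample_id = te_ids, probability = p,
                               label = as.integer(p >= 0.5),
                               stringsAsFactors = FALSE)
    reports[[fam]] <- metric_report(p, te_out, resamples = resamples,
                                    seed = seed_stream(split_seed, "boot", fam))
  }
  structure(list(regime = regime, reports = reports, predictions = preds,
                 configs = configs,
                 n_train = length(tr_ids), n_test = length(te_ids),
                 train_ids = tr_ids, test_ids = te_ids,
                 fit_state = enc_states, imputer = imputer),
            class = "regime_result")
}

#' @export
print.regime_result <- function(x, ...) {
  cat(sprintf("regime_result '%s': %d train / %d test\n", x$regime,
              x$n_train, x$n_test))
  for (fam in names(x$reports))
    cat(sprintf("  %-22s accuracy %.4f  AUC %.4f\n", fam,
                x$reports[[fam]]$accuracy, x$reports[[fam]]$auc))
  invisible(x)
}
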