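# Progressive residual fusion.
#
# Stage 1 is an ordinary probabilistic classifier on the most widely
# available block. Each later stage t sees blocks 1..t plus the previous
# stage's prediction and refines it. Three refinement modes:
#
#   prob_residual (default): stage t regresses the probability-scale
#     residual r = y - yhat_{t-1} on [x(1:t), yhat_{t-1}]; stage output is
#     clip(yhat_{t-1} + rhat). The optimal corrector E[y|x] - yhat is
#     exactly zero when the new block carries nothing and the prior is
#     calibrated, so an uninformative stage is a fixed point.
#   logit_residual: regresses r = logit(clip(y, eps)) - logit(yhat_{t-1});
#     stage output sigmoid(logit(yhat_{t-1}) + rhat). Note the optimal
#     corrector under clipped-label targets, |logit(eps)|*(2p-1) - logit(p),
#     is non-zero even with no new information: this mode sharpens
#     probabilities toward 0/1 (kept for comparison; see vignette).
#   stacking: stage t re-classifies y directly on [x(1:t), yhat_{t-1}].
#
# Residual/stacking stages are trained against *cross-fitted* prior
# predictions: the previous stage is refit on half-splits so that no
# sample's training prior comes from a model that saw that sample.
# Without this the prior is overfit (near the label in-sample), which
# both masks the new block's signal in probability-residual mode and
# injects spurious corrections in the other modes. Inference always uses
# the actual full previous-stage model.
#
# Stage t trains only on samples observed for blocks 1..t, with
# minority-class oversampling applied per stage; at inference each sample
# is pushed to the deepest stage its observed prefix of blocks allows.

reg_analogue <- function(family) {
  if (family == "naive_bayes_gaussian") "logistic" else family
}

#' Fit the first-stage (baseline) model of a fusion chain
#'
#' Oversamples the minority class, then fits a probabilistic classifier on
#' block-1 features only.
#'
#' @param x numeric design matrix restricted to block-1 columns.
#' @param labels 0/1 outcome vector.
#' @param family model family identifier.
#' @param seed integer seed; oversampling and model fitting derive
#'   independent sub-seeds from it.
#' @param params hyperparameter overrides for the family.
#' @return a `pf_model`.
#' @export
fit_stage1 <- function(x, labels, family = "gbt", seed = 0L, params = list()) {
  os <- oversample(x, labels, seed_stream(seed, "oversample"))
  fit_model(family, os$x, os$labels, "classification",
            seed = seed_stream(seed, "fit"), params = params)
}

#' Fit a residual-correction stage
#'
#' @param x design matrix over blocks `1..t` for the stage-eligible rows.
#' @param labels 0/1 outcomes for those rows.
#' @param prior previous-stage probabilities for the same rows.
#' @param family model family (regression analogue used in
#'   `logit_residual` mode; Gaussian naive Bayes falls back to a ridge
#'   linear model there).
#' @param seed integer seed.
#' @param residual_mode `"prob_residual"`, `"logit_residual"` or
#'   `"stacking"`.
#' @param eps probability-clipping constant (keeps logits finite and
#'   outputs inside `(0, 1)`).
#' @param params hyperparameter overrides.
#' @return list holding the fitted `model` and the stage's residual mode.
#' @export
fit_residual_stage <- function(x, labels, prior, family = "gbt", seed = 0L,
                               residual_mode = c("prob_residual",
                                                 "logit_residual",
                                                 "stacking"),
                               eps = 1e-6, params = list()) {
  residual_mode <- match.arg(residual_mode)
  feat <- cbind(x, .prior = prior)
  os <- oversample(feat, labels, seed_stream(seed, "oversample"))
  if (residual_mode == "stacking") {
    model <- fit_model(family, os$x, os$labels, "classification",
                       seed = seed_stream(seed, "fit"), params = params)
  } else {
    r <- if (residual_mode == "prob_residual") labels - prior
         else logit(clip_prob(labels, eps)) - logit(clip_prob(prior, eps))
    if (any(!is.finite(r)))
      pf_stop("non-finite residual target despite clipping",
              "profuse_error_internal")
    regfam <- reg_analogue(family)
    none <- FALSE
    if (regfam == "gbt" && is.null(params$n_trees)) {
      # early-stop the residual ensemble by 1-SE staged validation MSE so
      # an uninformative block cannot inject noise corrections; "none"
      # means even the intercept is unsupported and the stage is the
      # identity correction
      cfg <- default_config("gbt", "regression")
      sel <- gbt_select_ntrees(feat, r, labels, cfg,
                               seed_stream(seed, "select"))
      params$n_trees <- sel$n_trees
      none <- sel$none
    }
    model <- fit_model(regfam, os$x, r[os$index], "regression",
                       seed = seed_stream(seed, "fit"), params = params)
    if (none) model$fit$f0 <- 0
  }
  list(model = model, residual_mode = residual_mode, eps = eps)
}

predict_stage_probs <- function(stage, x, prior) {
  feat <- cbind(x, .prior = prior)
  raw <- predict(stage$model, feat)
  p <- switch(stage$residual_mode,
    prob_residual = prior + raw,
    logit_residual = plogis(logit(clip_prob(prior, stage$eps)) + raw),
    raw)
  clip_prob(p, stage$eps)
}

#' Fit a progressive fusion chain
#'
#' Trains stages `1..T` over the block order of `partition`. Stage `t` is
#' trained only on [stage_eligible()] samples; its encoder
#' (one-hot/standardization state) is refit on those rows since eligible
#' sets shrink with depth. A stage whose eligible set is empty or
#' single-class truncates the chain with a warning.
#'
#' @param table a [cohort_table()].
#' @param partition a [modality_partition()] in the fusion order.
#' @param families one family for all stages or a vector of length `T`.
#' @param residual_mode `"prob_residual"` (additive probability-scale
#'   correction, default), `"logit_residual"` (additive logit correction)
#'   or `"stacking"` (re-classification with the prior prediction as a
#'   feature).
#' @param seed integer seed controlling all stage-level randomness.
#' @param eps probability clipping constant.
#' @param rule block-completeness rule (see [stage_eligible()]).
#' @param params per-family hyperparameter overrides.
#' @param honest_folds cross-fitting folds used to compute the prior
#'   predictions that residual stages train against (2 = half-split
#'   refits of the previous stage; 0 disables cross-fitting and feeds
#'   in-sample priors).
#' @return an object of class `fused_chain`.
#' @export
fit_chain <- function(table, partition, families = "gbt",
                      residual_mode = c("prob_residual", "logit_residual",
                                        "stacking"),
                      seed = 0L, eps = 1e-6,
                      rule = c("all_variables", "any_variable"),
                      params = list(), honest_folds = 2L) {
  residual_mode <- match.arg(residual_mode)
  rule <- match.arg(rule)
  T_ <- n_blocks(partition)
  families <- rep_len(families, T_)
  fill <- rule == "any_variable"
  stages <- vector("list", T_)

  for (t in seq_len(T_)) {
    elig <- stage_eligible(table, partition, t, rule)
    fam <- families[t]
    truncate <- FALSE
    if (length(elig) == 0L) {
      truncate <- TRUE
    } else {
      sub <- subset_samples(table, elig)
      if (length(unique(sub$outcome)) < 2L) truncate <- TRUE
    }
    if (truncate) {
      if (t == 1L)
        pf_stop(sprintf("stage 1 untrainable: block '%s' has no eligible two-class sample set",
                        names(partition$blocks)[1]),
                "profuse_error_empty_stage")
      pf_warn(sprintf("stage %d ('%s') has no trainable eligible set; chain truncated at depth %d",
                      t, names(partition$blocks)[t], t - 1L),
              "profuse_warning_truncated")
      stages <- stages[seq_len(t - 1L)]
      partition$blocks <- partition$blocks[seq_len(t - 1L)]
      partition$fixed_prefix <- min(partition$fixed_prefix, t - 1L)
      break
    }
    stage_seed <- seed_stream(seed, "stage", t)
    dm <- encode(sub, train_ids = elig,
                 standardize = standardize_required(fam),
                 variables = block_vars(partition, t), fill = fill)
    stage <- list(t = t, family = fam, enc_state = dm$fit_state,
                  train_ids = elig, n_train = length(elig))
    if (t == 1L) {
      stage$model <- fit_stage1(dm$x, sub$outcome, fam, seed = stage_seed,
                                params = params[[fam]] %||% list())
      stage$residual_mode <- "stage1"
    } else {
      partial <- structure(list(partition = partition, stages = stages[1:(t - 1L)],
                                residual_mode = residual_mode, eps = eps,
                                rule = rule),
                           class = "fused_chain")
      prior <- if (honest_folds >= 2L)
        honest_prior(table, partial, sub, t, fill, seed, params,
                     honest_folds)
      else chain_probs_at_depth(partial, sub, t - 1L)
      rs <- fit_residual_stage(dm$x, sub$outcome, prior, fam,
                               seed = stage_seed,
                               residual_mode = residual_mode, eps = eps,
                               params = params[[reg_analogue(fam)]] %||% list())
      stage$model <- rs$model
      stage$residual_mode <- residual_mode
      stage$eps <- eps
    }
    stages[[t]] <- stage
  }
  structure(list(partition = partition, stages = stages,
                 residual_mode = residual_mode, eps = eps, rule = rule,
                 families = vapply(stages, `[[`, "", "family"),
                 seed = as.integer(seed)),
            class = "fused_chain")
}

#' @export
print.fused_chain <- function(x, ...) {
  cat(sprintf("fused_chain: %d stages, mode=%s\n", length(x$stages),
              x$residual_mode))
  for (s in x$stages)
    cat(sprintf("  stage %d: %s on '%s' (n=%d eligible)\n", s$t, s$family,
                names(x$partition$blocks)[s$t], s$n_train))
  invisible(x)
}

# Cross-fitted prior predictions for the rows of `sub` (the stage-t
# training set). The previous stage is refit on k half-splits of its own
# eligible set so that no row's prior comes from a model that saw it; the
# refits consume the in-sample prefix below stage t-1 (a documented
# second-order approximation). Inference never uses these refits.
honest_prior <- function(table, chain, sub, t, fill, seed, params, k) {
  tm1 <- t - 1L
  st_prev <- chain$stages[[tm1]]
  prev_ids <- st_prev$train_ids
  prev_tab <- subset_samples(table, prev_ids)
  fam <- st_prev$family
  folds <- stratified_folds(prev_tab$outcome, k,
                            seed_stream(seed, "honest", t))
  prior_out <- stats::setNames(rep(NA_real_, length(sub$sample_ids)),
                               sub$sample_ids)
  prev_prior_all <- if (tm1 >= 2L) {
    pc <- chain
    pc$stages <- chain$stages[seq_len(tm1 - 1L)]
    chain_probs_at_depth(pc, prev_tab, tm1 - 1L)
  } else NULL
  for (f in seq_len(k)) {
    tr_ids <- prev_ids[folds != f]
    ho_ids <- intersect(prev_ids[folds == f], sub$sample_ids)
    if (!length(ho_ids)) next
    tr_tab <- subset_samples(table, tr_ids)
    ho_tab <- subset_samples(table, ho_ids)
    if (length(unique(tr_tab$outcome)) < 2L) {
      prior_out[ho_ids] <- chain_probs_at_depth(chain, ho_tab, tm1)
      next
    }
    dm <- encode(tr_tab, tr_ids, standardize = standardize_required(fam),
                 variables = block_vars(chain$partition, tm1), fill = fill)
    hseed <- seed_stream(seed, "honest_fit", t, f)
    xho <- encode_apply(dm$fit_state, ho_tab)
    if (tm1 == 1L) {
      m <- fit_stage1(dm$x, tr_tab$outcome, fam, seed = hseed,
                      params = params[[fam]] %||% list())
      prior_out[ho_ids] <- clip_prob(predict(m, xho), chain$eps)
    } else {
      pr_tr <- prev_prior_all[match(tr_ids, prev_ids)]
      # reuse the tree count the actual stage selected: the refit only
      # supplies priors, so re-running early stopping would double cost
      # for no benefit
      hp <- params[[reg_analogue(fam)]] %||% list()
      pc_cfg <- st_prev$model$config
      if (is.null(hp$n_trees) && st_prev$model$family == "gbt" &&
          st_prev$model$task == "regression" && !is.null(pc_cfg$n_trees))
        hp$n_trees <- pc_cfg$n_trees
      rs <- fit_residual_stage(dm$x, tr_tab$outcome, pr_tr, fam,
                               seed = hseed,
                               residual_mode = chain$residual_mode,
                               eps = chain$eps, params = hp)
      pr_ho <- prev_prior_all[match(ho_ids, prev_ids)]
      prior_out[ho_ids] <- predict_stage_probs(rs, xho, pr_ho)
    }
  }
  unname(prior_out[sub$sample_ids])
}

# Probabilities at exactly depth d for every row of `table` (rows must be
# eligible through depth d).
chain_probs_at_depth <- function(chain, table, d) {
  p <- NULL
  for (t in seq_len(d)) {
    st <- chain$stages[[t]]
    x <- encode_apply(st$enc_state, table)
    p <- if (t == 1L) clip_prob(predict(st$model, x), chain$eps)
         else predict_stage_probs(st, x, p)
  }
  p
}

#' Predict from a fusion chain at each sample's achievable depth
#'
#' Each sample is evaluated to depth `d`, the longest *prefix* of blocks it
#' has observed (a gap stops the chain: stage `t` consumes blocks `1..t`,
#' so a sample missing block `t` cannot use block `t+1` even if present).
#' Samples missing block 1 are flagged unpredictable (`depth = 0`,
#' probability `NA`); no imputation is attempted.
#'
#' @param object a [fit_chain()] result.
#' @param table a [cohort_table()] covering at least block 1's variables.
#' @param max_depth optional cap on the evaluation depth (ablation use).
#' @param ... unused.
#' @return a `chain_prediction`: data.frame with `sample_id`, `depth`,
#'   `probability`, `label` (threshold 0.5), plus a `trace` attribute
#'   holding the per-stage probability matrix.
#' @export
predict.fused_chain <- function(object, table, max_depth = NULL, ...) {
  T_ <- length(object$stages)
  cap <- min(max_depth %||% T_, T_)
  n <- nrow(table$data)
  # depth = longest observed prefix of blocks, capped
  present <- matrix(FALSE, n, T_)
  for (t in seq_len(T_)) {
    vars <- object$partition$blocks[[t]]
    have <- intersect(vars, names(table$data))
    if (length(have) < length(vars) && object$rule == "all_variables") {
      present[, t] <- FALSE
      next
    }
    if (!length(have)) { present[, t] <- FALSE; next }
    obs <- !is.na(as.matrix(table$data[, have, drop = FALSE]))
    present[, t] <- if (object$rule == "all_variables") apply(obs, 1, all)
                    else apply(obs, 1, any)
  }
  if (!any(present[, 1]))
    pf_warn("no sample has block 1 observed; all rows unpredictable",
            "profuse_warning_unpredictable")
  depth <- apply(present, 1, function(r) {
    d <- 0L
    for (t in seq_along(r)) { if (!r[t]) break; d <- t }
    d
  })
  depth <- pmin(depth, cap)

  trace <- matrix(NA_real_, n, T_,
                  dimnames = list(table$sample_ids,
                                  paste0("stage", seq_len(T_))))
  p_prev <- rep(NA_real_, n)
  for (t in seq_len(cap)) {
    rows <- which(depth >= t)
    if (!length(rows)) break
    st <- object$stages[[t]]
    sub <- subset_samples(table, table$sample_ids[rows])
    x <- encode_apply(st$enc_state, sub)
    p <- if (t == 1L) clip_prob(predict(st$model, x), object$eps)
         else predict_stage_probs(st, x, p_prev[rows])
    trace[rows, t] <- p
    p_prev[rows] <- p
  }
  prob <- ifelse(depth >= 1L, p_prev, NA_real_)
  out <- data.frame(sample_id = table$sample_ids, depth = depth,
                    probability = prob,
                    label = ifelse(is.na(prob), NA_integer_,
                                   as.integer(prob >= 0.5)),
                    stringsAsFactors = FALSE)
  attr(out, "trace") <- trace
  class(out) <- c("chain_prediction", "data.frame")
  out
}

#' Order the searchable modality blocks by inner validation
#'
#' Keeps the first `fixed_prefix` blocks pinned, then greedily appends the
#' remaining blocks: at each position every candidate is tried, a chain of
#' that depth is scored by stratified k-fold accuracy *within the supplied
#' (training) table*, and the best candidate is fixed. Ties keep
#' declaration order. No other data ever enters the search.
#'
#' @inheritParams fit_chain
#' @param inner_folds number of stratified folds (at least 2).
#' @return the reordered [modality_partition()], with per-position scores
#'   in attribute `"scores"`.
#' @export
order_modalities <- function(table, partition, families = "gbt",
                             inner_folds = 5L, seed = 0L,
                             residual_mode = "prob_residual",
                             rule = "all_variables", params = list()) {
  if (inner_folds < 2L)
    pf_stop("inner_folds must be >= 2", "profuse_error_arg")
  T_ <- n_blocks(partition)
  fixed <- partition$fixed_prefix
  selected <- names(partition$blocks)[seq_len(fixed)]
  remaining <- setdiff(names(partition$blocks), selected)
  folds <- stratified_folds(table$outcome, inner_folds,
                            seed_stream(seed, "order_folds"))
  scores <- list()
  while (length(remaining)) {
    pos <- length(selected) + 1L
    sc <- vapply(remaining, function(cand) {
      blocks <- partition$blocks[c(selected, cand)]
      part <- modality_partition(blocks, fixed_prefix = 1L,
                                 outcome = partition$outcome)
      accs <- vapply(seq_len(inner_folds), function(f) {
        tr_ids <- table$sample_ids[folds != f]
        te_ids <- table$sample_ids[folds == f]
        ch <- fit_chain(subset_samples(table, tr_ids), part,
                        families = families, residual_mode = residual_mode,
                        seed = seed_stream(seed, "order_fit", pos, f),
                        rule = rule, params = params)
        pr <- predict(ch, subset_samples(table, te_ids))
        ok <- !is.na(pr$label)
        if (!any(ok)) return(NA_real_)
        mean(pr$label[ok] == subset_samples(table, te_ids)$outcome[ok])
      }, 0)
      mean(accs, na.rm = TRUE)
    }, 0)
    best <- remaining[which.max(sc)]  # first max: declaration-order ties
    scores[[pos]] <- sc
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out <- modality_partition(partition$blocks[selected],
                            fixed_prefix = fixed,
                            outcome = partition$outcome)
  attr(out, "scores") <- scores
  out
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Save / load a fitted chain archive
#'
#' The archive holds the partition, residual mode, clipping constant and
#' every stage's family, fitted state and preprocessing state; loading
#' reproduces predictions exactly.
#'
#' @param chain a `fused_chain`.
#' @param path file path.
#' @return `chain_load` returns the chain; `chain_save` its path,
#'   invisibly.
#' @export
chain_save <- function(chain, path) {
  saveRDS(chain, path, version = 2)
  invisible(path)
}

#' @rdname chain_save
#' @export
chain_load <- function(path) {
  ch <- readRDS(path)
  if (!inherits(ch, "fused_chain"))
    pf_stop("file is not a fused_chain archive", "profuse_error_arg")
  ch
}
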