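# Gradient-boosted tree ensemble on the C++ regression tree.
#
# Classification uses the logistic loss with Friedman's per-leaf Newton
# step: each tree is fit to the gradient (y - p) and its leaf values are
# replaced by sum(g)/sum(p(1-p)) within the leaf. Regression boosts the
# squared loss, so leaf means are used as-is. 100 trees at learning rate
# 0.1 is the default, matching the strongest baseline's configuration;
# depth-3 trees keep stage fits fast at cohort scale (n ~ 10^3).

fit_gbt <- function(x, y, task = c("classification", "regression"),
                    n_trees = 100L, learning_rate = 0.1, max_depth = 3L,
                    min_split = 10L, min_leaf = 5L, seed = 0L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) pf_stop("gbt: missing values in design matrix",
                        "profuse_error_missing")
  n <- nrow(x)
  trees <- vector("list", n_trees)
  leaf_values <- vector("list", n_trees)
  if (task == "classification") {
    y <- as.numeric(y)
    f0 <- logit(clip_prob(mean(y)))
    f <- rep(f0, n)
    for (m in seq_len(n_trees)) {
      p <- plogis(f)
      g <- y - p
      tr <- .fit_tree_cpp(x, g, max_depth, min_split, min_leaf, -1L,
                          seed_stream(seed, "gbt", m))
      leaf <- .predict_tree_leaf_cpp(tr, x) + 1L
      h <- pmax(p * (1 - p), 1e-12)
      num <- tapply(g, leaf, sum)
      den <- tapply(h, leaf, sum)
      gamma <- rep(0, length(tr$feature))
      gamma[as.integer(names(num))] <- pmin(pmax(num / den, -4), 4)
      trees[[m]] <- tr
      leaf_values[[m]] <- gamma
      f <- f + learning_rate * gamma[leaf]
    }
  } else {
    y <- as.numeric(y)
    f0 <- mean(y)
    f <- rep(f0, n)
    for (m in seq_len(n_trees)) {
      r <- y - f
      tr <- .fit_tree_cpp(x, r, max_depth, min_split, min_leaf, -1L,
                          seed_stream(seed, "gbt", m))
      trees[[m]] <- tr
      leaf_values[[m]] <- tr$value
      f <- f + learning_rate * .predict_tree_cpp(tr, x)
    }
  }
  structure(list(task = task, f0 = f0, trees = trees,
                 leaf_values = leaf_values,
                 learning_rate = learning_rate),
            class = "pf_gbt")
}

predict_gbt <- function(object, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  f <- rep(object$f0, nrow(x))
  for (m in seq_along(object$trees)) {
    leaf <- .predict_tree_leaf_cpp(object$trees[[m]], x) + 1L
    f <- f + object$learning_rate * object$leaf_values[[m]][leaf]
  }
  if (object$task == "classification") plogis(f) else f
}

# Early stopping for residual-stage regressions: choose the tree count by
# k-fold staged validation MSE under the one-standard-error rule (the
# smallest ensemble whose validation MSE is within one between-fold SE of
# the minimum). An uninformative stage then selects ~0 trees -- the
# correction degenerates to the mean residual, approximately zero -- which
# is what makes a no-signal block a fixed point of the chain; a block with
# real evidence clears the 1-SE bar and keeps its trees.
gbt_select_ntrees <- function(x, y, strata, cfg, seed, k = 2L) {
  folds <- stratified_folds(strata, k, seed_stream(seed, "earlystop"))
  err <- matrix(0, k, cfg$n_trees + 1L)
  err_none <- numeric(k)  # validation MSE of applying no correction at all
  for (f in seq_len(k)) {
    tr <- folds != f
    if (sum(tr) < 2L * cfg$min_leaf || all(tr) || !any(tr))
      return(list(n_trees = cfg$n_trees, none = FALSE))
    m <- fit_gbt(x[tr, , drop = FALSE], y[tr], "regression",
                 n_trees = cfg$n_trees, learning_rate = cfg$learning_rate,
                 max_depth = cfg$max_depth, min_split = cfg$min_split,
                 min_leaf = cfg$min_leaf, seed = seed_stream(seed, "es", f))
    xh <- x[!tr, , drop = FALSE]
    storage.mode(xh) <- "double"
    yh <- y[!tr]
    err_none[f] <- mean(yh^2)
    fh <- rep(m$f0, nrow(xh))
    err[f, 1L] <- mean((yh - fh)^2)
    for (t in seq_along(m$trees)) {
      leaf <- .predict_tree_leaf_cpp(m$trees[[t]], xh) + 1L
      fh <- fh + m$learning_rate * m$leaf_values[[t]][leaf]
      err[f, t + 1L] <- mean((yh - fh)^2)
    }
  }
  m <- colMeans(err)
  se <- apply(err, 2, sd) / sqrt(k)
  best <- which.min(m)
  bar <- m[best] + se[best]
  if (mean(err_none) <= bar) return(list(n_trees = 0L, none = TRUE))
  list(n_trees = (which(m <= bar)[1]) - 1L, none = FALSE)
}

# Random forest (bagged trees + feature subsampling). Used by the
# imputation engine; leaves of size 1 so that deterministic relationships
# in the data can be reproduced exactly.
fit_forest <- function(x, y, task = c("regression", "classification"),
                       n_trees = 30L, mtry = NULL, max_depth = 20L,
                       min_split = 2L, min_leaf = 1L, seed = 0L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  mtry <- mtry %||% max(1L, as.integer(floor(sqrt(p))))
  y <- as.numeric(y)
  trees <- vector("list", n_trees)
  boots <- vector("list", n_trees)
  for (m in seq_len(n_trees)) {
    idx <- with_seed(seed_stream(seed, "forest_boot", m),
                     sample.int(n, n, replace = TRUE))
    trees[[m]] <- .fit_tree_cpp(x[idx, , drop = FALSE], y[idx],
                                max_depth, min_split, min_leaf, mtry,
                                seed_stream(seed, "forest_tree", m))
  }
  structure(list(task = task, trees = trees), class = "pf_forest")
}

predict_forest <- function(object, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  preds <- vapply(object$trees, function(tr) .predict_tree_cpp(tr, x),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) mean(preds) else rowMeans(matrix(preds, nrow(x)))
}
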