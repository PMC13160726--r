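# The six baseline classifier families and their regression analogues.
#
# No external learner packages are assumed: trees and forests run on the
# package's C++ tree, the margin family is a polynomial-kernel ridge
# classifier with Platt-scaled probabilities, logistic is ridge-penalised
# IRLS. Every resolved hyperparameter lands in the fitted object's
# $config, so a result can be reproduced from its config alone.

FAMILIES <- c("gbt", "logistic", "decision_tree", "knn",
              "naive_bayes_gaussian", "svm_poly")

#' Resolved default hyperparameters for a model family
#'
#' @param family family identifier (see `FAMILIES`).
#' @param task `"classification"` or `"regression"`.
#' @return named list of every hyperparameter that affects results.
#' @export
default_config <- function(family, task = "classification") {
  switch(family,
    gbt = list(n_trees = 100L, learning_rate = 0.1, max_depth = 3L,
               min_split = 10L, min_leaf = 5L),
    decision_tree = list(max_depth = 30L, min_split = 2L, min_leaf = 1L),
    knn = list(k = 10L),
    naive_bayes_gaussian = list(var_smoothing = 1e-9),
    logistic = list(lambda = 1.0, max_iter = 100L, tol = 1e-10),
    svm_poly = list(degree = 3L, coef0 = 1.0, lambda = 1.0),
    pf_stop(paste("unknown family:", family), "profuse_error_arg"))
}

standardize_required <- function(family) {
  family %in% c("knn", "svm_poly", "logistic", "naive_bayes_gaussian")
}

# Ridge-penalised IRLS for logistic / linear models. Intercept unpenalised.
fit_ridge <- function(x, y, lambda, binomial = TRUE, max_iter = 100L,
                      tol = 1e-10) {
  x1 <- cbind(`(Intercept)` = 1, x)
  p <- ncol(x1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  if (!binomial) {
    beta <- solve(crossprod(x1) + pen, crossprod(x1, y))
    return(drop(beta))
  }
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xw <- x1 * w
    new <- drop(solve(crossprod(x1, xw) + pen, crossprod(xw, z)))
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  beta
}

poly_kernel <- function(a, b, degree, coef0, gamma) {
  (gamma * tcrossprod(a, b) + coef0)^degree
}

#' Fit one model family
#'
#' Dispatches to the requested family. Classification fits return
#' probability-emitting models; regression fits (used by logit-residual
#' stages and imputation) return conditional-mean models.
#'
#' @param family family identifier, one of `gbt`, `logistic`,
#'   `decision_tree`, `knn`, `naive_bayes_gaussian`, `svm_poly`.
#' @param x numeric design matrix without missing values.
#' @param y 0/1 labels (classification) or numeric response (regression).
#' @param task model task.
#' @param seed integer seed (tree ensembles; other families are exact).
#' @param params overrides merged over [default_config()].
#' @return an object of class `pf_model` with `$config` holding every
#'   resolved hyperparameter.
#' @export
fit_model <- function(family, x, y, task = c("classification", "regression"),
                      seed = 0L, params = list()) {
  task <- match.arg(task)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x))
    pf_stop("missing values in design matrix; restrict to eligible rows or use a regime",
            "profuse_error_missing")
  cfg <- modifyList(default_config(family, task), params)
  y <- as.numeric(y)
  if (task == "classification" && length(unique(y)) < 2L)
    pf_stop("classification fit needs both classes", "profuse_error_single_class")

  fit <- switch(family,
    gbt = fit_gbt(x, y, task, n_trees = cfg$n_trees,
                  learning_rate = cfg$learning_rate,
                  max_depth = cfg$max_depth, min_split = cfg$min_split,
                  min_leaf = cfg$min_leaf, seed = seed),
    decision_tree = .fit_tree_cpp(x, y, cfg$max_depth, cfg$min_split,
                                  cfg$min_leaf, -1L, seed),
    knn = list(x = x, y = y, k = cfg$k),
    naive_bayes_gaussian = {
      if (task == "regression")
        pf_stop("naive_bayes_gaussian has no regression analogue",
                "profuse_error_arg")
      cls <- sort(unique(y))
      eps <- cfg$var_smoothing * max(apply(x, 2, var), 1e-12)
      list(classes = cls,
           prior = vapply(cls, function(c) mean(y == c), 0),
           mu = lapply(cls, function(c) colMeans(x[y == c, , drop = FALSE])),
           s2 = lapply(cls, function(c) {
             v <- apply(x[y == c, , drop = FALSE], 2, var)
             v[!is.finite(v)] <- 0
             v + eps
           }))
    },
    logistic = fit_ridge(x, y, cfg$lambda, binomial = task == "classification",
                         max_iter = cfg$max_iter, tol = cfg$tol),
    svm_poly = {
      gamma <- 1 / ncol(x)
      K <- poly_kernel(x, x, cfg$degree, cfg$coef0, gamma)
      tgt <- if (task == "classification") 2 * y - 1 else y
      alpha <- solve(K + cfg$lambda * diag(nrow(x)), tgt)
      platt <- NULL
      if (task == "classification") {
        s <- drop(K %*% alpha)
        platt <- coef(suppressWarnings(
          glm(y ~ s, family = binomial())))
      }
      list(sv = x, alpha = alpha, gamma = gamma, platt = platt)
    },
    pf_stop(paste("unknown family:", family), "profuse_error_arg"))

  structure(list(family = family, task = task, config = cfg, fit = fit,
                 columns = colnames(x), seed = as.integer(seed)),
            class = "pf_model")
}

#' Predict from a fitted `pf_model`
#'
#' @param object a `pf_model`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return probabilities of class 1 (classification) or numeric
#'   predictions (regression).
#' @export
predict.pf_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (anyNA(x)) pf_stop("missing values at prediction time",
                        "profuse_error_missing")
  cfg <- object$config
  fit <- object$fit
  switch(object$family,
    gbt = predict_gbt(fit, x),
    decision_tree = .predict_tree_cpp(fit, x),
    knn = {
      tr <- fit$x
      k <- min(cfg$k, nrow(tr))
      d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * tcrossprod(x, tr)
      apply(d2, 1, function(d) {
        nb <- order(d, seq_along(d))[seq_len(k)]  # distance, then row index
        mean(fit$y[nb])
      })
    },
    naive_bayes_gaussian = {
      lp <- vapply(seq_along(fit$classes), function(ci) {
        mu <- fit$mu[[ci]]; s2 <- fit$s2[[ci]]
        log(fit$prior[ci]) + colSums(-0.5 * (log(2 * pi * s2) +
          (t(x) - mu)^2 / s2))
      }, numeric(nrow(x)))
      lp <- matrix(lp, nrow(x))
      m <- apply(lp, 1, max)
      post <- exp(lp - m)
      post <- post / rowSums(post)
      post[, match(1, fit$classes)]
    },
    logistic = {
      eta <- drop(cbind(1, x) %*% fit)
      if (object$task == "classification") plogis(eta) else eta
    },
    svm_poly = {
      s <- drop(poly_kernel(x, fit$sv, cfg$degree, cfg$coef0, fit$gamma) %*%
                  fit$alpha)
      if (object$task == "classification")
        plogis(fit$platt[1] + fit$platt[2] * s)
      else s
    })
}
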