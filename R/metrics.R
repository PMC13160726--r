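# Clinical evaluation suite: discrimination (confusion metrics, AUC with
# percentile-bootstrap CI), calibration (Brier, ECE) and decision-curve
# net benefit.

check_prob_labels <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    pf_stop("probabilities and labels must align", "profuse_error_arg")
  if (anyNA(probabilities) || anyNA(labels))
    pf_stop("missing values in probabilities or labels", "profuse_error_arg")
  if (any(probabilities < 0 | probabilities > 1))
    pf_stop("probabilities must lie in [0,1]", "profuse_error_arg")
  if (!all(labels %in% c(0, 1)))
    pf_stop("labels must be 0/1", "profuse_error_arg")
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predicted positive iff probability >= `threshold` (ties positive).
#' With no predicted positives precision is undefined and reported as 0
#' with `precision_undefined = TRUE`.
#'
#' @param probabilities predicted class-1 probabilities.
#' @param labels 0/1 outcomes.
#' @param threshold decision threshold (default 0.5).
#' @return list: `accuracy`, `precision`, `recall`, `f1`, the confusion
#'   counts, and the `precision_undefined` flag.
#' @export
classification_metrics <- function(probabilities, labels, threshold = 0.5) {
  check_prob_labels(probabilities, labels)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  undef <- (tp + fp) == 0
  if (undef)
    pf_warn("no predicted positives; precision reported as 0",
            "profuse_warning_precision")
  precision <- if (undef) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn,
       precision_undefined = undef)
}

auc_point <- function(probabilities, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    pf_stop("AUC needs both classes present", "profuse_error_single_class")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a stratified percentile-bootstrap confidence interval
#'
#' AUC is the probability that a random positive outranks a random
#' negative, ties counting one half (the rank / Mann-Whitney statistic).
#' The CI resamples positives and negatives separately (so every resample
#' keeps both classes), then takes percentile quantiles.
#'
#' @inheritParams classification_metrics
#' @param resamples bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list: `auc`, `lower`, `upper`, `level`, `resamples`.
#' @export
auc_with_ci <- function(probabilities, labels, resamples = 2000L,
                        level = 0.95, seed = 0L) {
  check_prob_labels(probabilities, labels)
  est <- auc_point(probabilities, labels)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  boots <- with_seed(seed, vapply(seq_len(resamples), function(b) {
    j1 <- sample(i1, length(i1), replace = TRUE)
    j0 <- sample(i0, length(i0), replace = TRUE)
    auc_point(c(probabilities[j1], probabilities[j0]),
              c(rep(1, length(j1)), rep(0, length(j0))))
  }, 0))
  a <- (1 - level) / 2
  q <- unname(quantile(boots, c(a, 1 - a), type = 7))
  list(auc = est, lower = q[1], upper = q[2], level = level,
       resamples = as.integer(resamples))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @inheritParams classification_metrics
#' @return the score in `[0, 1]`.
#' @export
brier_score <- function(probabilities, labels) {
  check_prob_labels(probabilities, labels)
  mean((probabilities - labels)^2)
}

#' Expected calibration error
#'
#' Equal-width, right-closed bins on `[0,1]`; ECE is the bin-count-weighted
#' mean absolute gap between mean predicted probability and observed event
#' rate. Empty bins contribute zero.
#'
#' @inheritParams classification_metrics
#' @param n_bins number of bins (default 10).
#' @return list: `ece` and `bins` (per-bin edges, count, mean confidence,
#'   event rate, gap).
#' @export
ece <- function(probabilities, labels, n_bins = 10L) {
  check_prob_labels(probabilities, labels)
  if (n_bins < 1L) pf_stop("n_bins must be >= 1", "profuse_error_arg")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(probabilities, edges, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  n <- length(labels)
  tab <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (!length(idx))
      return(data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
                        count = 0L, confidence = NA_real_, rate = NA_real_,
                        gap = 0))
    conf <- mean(probabilities[idx]); rate <- mean(labels[idx])
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               count = length(idx), confidence = conf, rate = rate,
               gap = abs(conf - rate))
  })
  tab <- do.call(rbind, tab)
  list(ece = sum(tab$count / n * tab$gap), bins = tab)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at each threshold probability
#' `p_t`: `NB = TP/n - (FP/n) * p_t / (1 - p_t)` with the positive call
#' rule probability >= `p_t`; compared against treat-all
#' (`pi - (1 - pi) * p_t / (1 - p_t)`) and treat-none (0).
#'
#' @inheritParams classification_metrics
#' @param thresholds vector of threshold probabilities in `(0, 1)`
#'   (default 0.01 to 0.50 step 0.01).
#' @return data.frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  check_prob_labels(probabilities, labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    pf_stop("thresholds must lie strictly inside (0,1)", "profuse_error_arg")
  n <- length(labels); prev <- mean(labels)
  out <- lapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    w <- pt / (1 - pt)
    data.frame(threshold = pt,
               nb_model = tp / n - fp / n * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  })
  do.call(rbind, out)
}

#' Full metric report
#'
#' Bundles discrimination, calibration and decision-curve results for one
#' probability vector.
#'
#' @inheritParams auc_with_ci
#' @param threshold classification threshold.
#' @param n_bins ECE bins.
#' @param thresholds decision-curve grid.
#' @return an object of class `metric_report` (a named list), JSON-ready
#'   via [report_to_json()].
#' @export
metric_report <- function(probabilities, labels, threshold = 0.5,
                          resamples = 2000L, level = 0.95, seed = 0L,
                          n_bins = 10L,
                          thresholds = seq(0.01, 0.50, by = 0.01)) {
  cm <- classification_metrics(probabilities, labels, threshold)
  auc <- auc_with_ci(probabilities, labels, resamples, level, seed)
  cal <- ece(probabilities, labels, n_bins)
  structure(list(n = length(labels), threshold = threshold,
                 accuracy = cm$accuracy, precision = cm$precision,
                 recall = cm$recall, f1 = cm$f1,
                 auc = auc$auc, auc_lower = auc$lower,
                 auc_upper = auc$upper, auc_level = level,
                 brier = brier_score(probabilities, labels),
                 ece = cal$ece, calibration = cal$bins,
                 decision_curve = decision_curve(probabilities, labels,
                                                 thresholds)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("metric_report (n=%d): accuracy %.4f, precision %.4f, ",
                     "recall %.4f, F1 %.4f\n  AUC %.4f (%d%% CI %.4f-%.4f), ",
                     "Brier %.4f, ECE %.4f\n"),
              x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc,
              round(100 * x$auc_level), x$auc_lower, x$auc_upper,
              x$brier, x$ece))
  invisible(x)
}

#' Serialise a metric report to JSON
#'
#' @param report a [metric_report()].
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
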