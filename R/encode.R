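# Variable encoding: binary -> one 0/1 column, categorical -> one-hot
# indicator group over the levels seen in training rows, continuous ->
# pass-through with optional train-statistics standardization. All fit
# state (levels, means, SDs, fill values) comes from training rows only;
# test rows can never influence it.

encode_fit <- function(table, train_ids, variables = NULL,
                       standardize = FALSE, fill = FALSE) {
  variables <- variables %||% names(table$data)
  tr <- match(train_ids, table$sample_ids)
  if (anyNA(tr)) pf_stop("train_ids must be a subset of sample_ids",
                         "profuse_error_spec")
  state <- list(variables = variables, standardize = standardize,
                fill = fill, per_var = list())
  for (v in variables) {
    spec <- table$specs[[v]]
    xs <- table$data[[v]][tr]
    obs <- xs[!is.na(xs)]
    st <- list(kind = spec$kind)
    if (spec$kind == "categorical") {
      st$levels <- sort(unique(obs))
      st$labels <- spec$categories
      # train-frequency fill for permissive mode: modal level
      st$fill_value <- if (length(obs)) {
        tab <- base::table(obs)
        as.numeric(names(tab)[which.max(tab)])
      } else NA_real_
    } else {
      st$center <- if (length(obs)) mean(obs) else 0
      st$scale <- if (length(obs) > 1) sd(obs) else 1
      if (!is.finite(st$scale) || st$scale == 0) st$scale <- 1
      st$fill_value <- st$center
    }
    state$per_var[[v]] <- st
  }
  state
}

encode_apply <- function(state, table) {
  n <- nrow(table$data)
  cols <- list()
  unseen <- character()
  for (v in state$variables) {
    st <- state$per_var[[v]]
    xs <- table$data[[v]]
    if (st$kind == "categorical") {
      lv <- st$levels
      if (length(lv) == 0L) next
      m <- matrix(0, n, length(lv))
      labs <- if (!is.null(st$labels) && all(lv == round(lv)) &&
                  max(lv) <= length(st$labels)) st$labels[lv]
              else as.character(lv)
      colnames(m) <- paste0(v, "=", labs)
      na_rows <- is.na(xs)
      if (state$fill) xs[na_rows] <- st$fill_value
      for (j in seq_along(lv)) m[, j] <- as.numeric(!is.na(xs) & xs == lv[j])
      if (!state$fill && any(na_rows)) m[na_rows, ] <- NA
      new <- !is.na(xs) & !(xs %in% lv)
      if (any(new)) unseen <- c(unseen, v)  # all-zero indicator group
      cols[[v]] <- m
    } else {
      out <- xs
      if (state$fill) out[is.na(out)] <- st$fill_value
      if (state$standardize && st$kind == "continuous")
        out <- (out - st$center) / st$scale
      m <- matrix(out, n, 1)
      colnames(m) <- v
      cols[[v]] <- m
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- table$sample_ids
  if (length(unseen))
    pf_log(paste("categories unseen in training encoded as all-zero:",
                 paste(unique(unseen), collapse = ", ")),
           "profuse_log_unseen_category")
  x
}

#' Build a design matrix from a cohort table
#'
#' Encodes variables into a numeric model matrix. Binary variables map to a
#' single 0/1 column; categorical variables to a one-hot group over the
#' levels observed in the training rows (a test-row category unseen in
#' training encodes as an all-zero group, with a warning); continuous
#' variables pass through, optionally centred and scaled by training-row
#' statistics. Missing source values propagate to `NA` across all derived
#' columns unless `fill = TRUE`, in which case they are filled with the
#' training mean (continuous) or training mode (categorical).
#'
#' @param table a [cohort_table()].
#' @param train_ids sample ids whose rows supply all fit statistics.
#' @param standardize centre/scale continuous columns (used by
#'   distance/margin/linear model families, never by tree ensembles).
#' @param variables optional subset of variables to encode, in order.
#' @param fill mean/mode-fill missing entries (permissive block rule).
#' @return an object of class `design_matrix`: list with the numeric
#'   matrix `x` (rows aligned to `table$sample_ids`), `columns`, and the
#'   training-fitted `fit_state`.
#' @export
encode <- function(table, train_ids, standardize = FALSE, variables = NULL,
                   fill = FALSE) {
  state <- encode_fit(table, train_ids, variables = variables,
                      standardize = standardize, fill = fill)
  x <- encode_apply(state, table)
  structure(list(x = x, columns = colnames(x), fit_state = state,
                 sample_ids = table$sample_ids),
            class = "design_matrix")
}

#' Recover categories from a one-hot group
#'
#' Inverse of the categorical part of [encode()]: for each sample the
#' active indicator within a variable's one-hot group names its category.
#' All-zero groups (missing or unseen) decode to `NA`.
#'
#' @param dm a `design_matrix`.
#' @param variable name of a categorical variable in the matrix.
#' @return numeric vector of decoded level codes.
#' @export
decode_onehot <- function(dm, variable) {
  st <- dm$fit_state$per_var[[variable]]
  if (is.null(st) || st$kind != "categorical")
    pf_stop(sprintf("'%s' is not an encoded categorical variable", variable),
            "profuse_error_arg")
  pref <- paste0(variable, "=")
  grp <- dm$x[, startsWith(colnames(dm$x), pref), drop = FALSE]
  lv <- st$levels
  unname(apply(grp, 1, function(r) {
    if (anyNA(r) || sum(r) == 0) NA_real_ else lv[which.max(r)]
  }))
}
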