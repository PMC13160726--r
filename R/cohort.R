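#' Variable specification
#'
#' Describes one clinical variable: its measurement kind and, for
#' categorical variables, the full label set. Values are stored numerically
#' in a [cohort_table()]: binary as 0/1, categorical as the 1-based index
#' into `categories`, continuous as-is.
#'
#' @param name variable name (unique within a table).
#' @param kind one of `"binary"`, `"categorical"`, `"continuous"`.
#' @param categories character vector of category labels (categorical only,
#'   at least two).
#' @param unit free-text unit annotation.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                          categories = NULL, unit = "") {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (length(categories) < 2L || anyDuplicated(categories))
      pf_stop(sprintf("variable '%s': categorical needs >= 2 distinct categories", name),
              "profuse_error_spec")
  } else if (!is.null(categories)) {
    pf_stop(sprintf("variable '%s': categories only allowed for categorical kind", name),
            "profuse_error_spec")
  }
  structure(list(name = name, kind = kind,
                 categories = categories, unit = unit),
            class = "variable_spec")
}

infer_spec <- function(name, values) {
  v <- values[!is.na(values)]
  if (length(v) && all(v %in% c(0, 1))) {
    variable_spec(name, "binary")
  } else if (length(v) && all(v == round(v)) && length(unique(v)) <= 13 &&
             min(v) >= 1) {
    variable_spec(name, "categorical",
                  categories = as.character(seq_len(max(v))))
  } else {
    variable_spec(name, "continuous")
  }
}

#' Modality partition
#'
#' An ordered grouping of variables into modality blocks. Block order is the
#' fusion-chain order: stage `t` consumes blocks `1..t`. The first
#' `fixed_prefix` blocks are pinned and never reordered by
#' [order_modalities()].
#'
#' @param blocks named list; each element is a character vector of variable
#'   names. Element order is the chain order.
#' @param fixed_prefix number of leading blocks whose position is not
#'   searchable (at least 1).
#' @param outcome name of the outcome column in CSV representations.
#' @return an object of class `modality_partition`.
#' @export
modality_partition <- function(blocks, fixed_prefix = 1L, outcome = "outcome") {
  if (is.null(names(blocks)) || any(names(blocks) == "") ||
      anyDuplicated(names(blocks)))
    pf_stop("blocks must be a uniquely named list", "profuse_error_spec")
  vars <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(vars))
    pf_stop("each variable must appear in exactly one block", "profuse_error_spec")
  fixed_prefix <- as.integer(fixed_prefix)
  if (fixed_prefix < 1L || fixed_prefix > length(blocks))
    pf_stop("fixed_prefix must be in 1..number of blocks", "profuse_error_spec")
  structure(list(blocks = blocks, fixed_prefix = fixed_prefix,
                 outcome = outcome),
            class = "modality_partition")
}

#' @export
print.modality_partition <- function(x, ...) {
  cat(sprintf("modality_partition: %d blocks (fixed prefix %d)\n",
              length(x$blocks), x$fixed_prefix))
  for (i in seq_along(x$blocks))
    cat(sprintf("  %d. %s [%d vars]%s\n", i, names(x$blocks)[i],
                length(x$blocks[[i]]),
                if (i <= x$fixed_prefix) " (fixed)" else ""))
  invisible(x)
}

n_blocks <- function(partition) length(partition$blocks)

block_vars <- function(partition, t) {
  unlist(partition$blocks[seq_len(t)], use.names = FALSE)
}

#' Cohort table
#'
#' The central data container: a samples-by-variables numeric grid with
#' missing entries, a binary outcome per sample, per-variable specs and an
#' optional long-format store of repeated measurements awaiting
#' aggregation.
#'
#' @param data data.frame of numeric columns (binary 0/1, categorical
#'   coded 1..k, continuous); `NA` marks a missing entry.
#' @param outcome 0/1 vector, one per row, never missing.
#' @param specs optional named list of [variable_spec()]; inferred from the
#'   data when omitted.
#' @param sample_ids optional character ids; defaults to row numbers.
#' @param repeats optional data.frame with columns `sample_id`, `variable`,
#'   `value` holding repeated measurements (see [aggregate_repeats()]).
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(data, outcome, specs = NULL, sample_ids = NULL,
                         repeats = NULL) {
  data <- as.data.frame(data)
  if (anyDuplicated(names(data)))
    pf_stop("variable names must be unique", "profuse_error_spec")
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(data))
    pf_stop("outcome length must match rows", "profuse_error_spec")
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L)))
    pf_stop("outcome must be 0/1 and never missing", "profuse_error_spec")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(data)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    pf_stop("sample ids must be unique", "profuse_error_spec")
  if (is.null(specs)) {
    specs <- lapply(names(data), function(v) infer_spec(v, data[[v]]))
    names(specs) <- names(data)
  } else {
    if (!setequal(names(specs), names(data)))
      pf_stop("specs must cover exactly the data columns", "profuse_error_spec")
    specs <- specs[names(data)]
  }
  structure(list(data = data, outcome = outcome, specs = specs,
                 sample_ids = sample_ids, repeats = repeats),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d samples x %d variables, prevalence %.3f, %.1f%% cells missing\n",
              nrow(x$data), ncol(x$data), mean(x$outcome),
              100 * mean(is.na(as.matrix(x$data)))))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

#' Subset a cohort table by sample ids or variable names
#'
#' @param table a [cohort_table()].
#' @param ids sample ids to keep (order preserved).
#' @return the restricted [cohort_table()].
#' @export
subset_samples <- function(table, ids) {
  keep <- match(ids, table$sample_ids)
  if (anyNA(keep)) pf_stop("unknown sample ids", "profuse_error_spec")
  cohort_table(table$data[keep, , drop = FALSE], table$outcome[keep],
               specs = table$specs, sample_ids = table$sample_ids[keep],
               repeats = table$repeats)
}

#' @rdname subset_samples
#' @param vars variable names to keep.
#' @export
subset_variables <- function(table, vars) {
  miss <- setdiff(vars, names(table$data))
  if (length(miss))
    pf_stop(paste("unknown variables:", paste(miss, collapse = ", ")),
            "profuse_error_spec")
  cohort_table(table$data[, vars, drop = FALSE], table$outcome,
               specs = table$specs[vars], sample_ids = table$sample_ids)
}

#' Collapse repeated measurements to their median
#'
#' Clinical indicators measured more than once per patient are summarised
#' by the per-entry median before modelling, damping the influence of
#' extreme single readings. Entries without repeats are untouched; the
#' operation is idempotent.
#'
#' @param table a [cohort_table()] whose `repeats` slot may hold a
#'   long-format data.frame (`sample_id`, `variable`, `value`).
#' @return the table with medians folded into the grid and `repeats`
#'   cleared.
#' @export
aggregate_repeats <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  rp <- table$repeats
  if (is.null(rp) || nrow(rp) == 0L) {
    table$repeats <- NULL
    return(table)
  }
  need <- c("sample_id", "variable", "value")
  if (!all(need %in% names(rp)))
    pf_stop("repeats needs columns sample_id, variable, value",
            "profuse_error_spec")
  val <- rp$value
  if (!is.numeric(val)) {
    conv <- suppressWarnings(as.numeric(val))
    bad <- is.na(conv) & !is.na(val)
    if (any(bad)) {
      v <- unique(rp$variable[bad])
      pf_stop(paste("non-numeric repeat values for:", paste(v, collapse = ", ")),
              "profuse_error_value")
    }
    val <- conv
  }
  key <- paste(as.character(rp$sample_id), as.character(rp$variable),
               sep = "\r")
  med <- tapply(val, key, median, na.rm = TRUE)
  ks <- strsplit(names(med), "\r", fixed = TRUE)
  for (i in seq_along(med)) {
    sid <- ks[[i]][1]; var <- ks[[i]][2]
    r <- match(sid, table$sample_ids)
    if (is.na(r) || !var %in% names(table$data))
      pf_stop(sprintf("repeat entry refers to unknown (%s, %s)", sid, var),
              "profuse_error_spec")
    table$data[[var]][r] <- unname(med[i])
  }
  table$repeats <- NULL
  table
}

#' Samples eligible for a fusion stage
#'
#' Stage `t` of the chain is trained only on samples observed for modality
#' blocks `1..t`. Under the default `"all_variables"` rule a block counts
#' as present only when every one of its variables is non-missing; the
#' permissive `"any_variable"` rule accepts a block with at least one
#' observed variable (remaining gaps are mean-filled at encoding time).
#'
#' @param table a [cohort_table()].
#' @param partition a [modality_partition()].
#' @param t stage index in `1..T`.
#' @param rule block-completeness rule.
#' @return character vector of eligible sample ids (chain order preserved).
#' @export
stage_eligible <- function(table, partition, t,
                           rule = c("all_variables", "any_variable")) {
  rule <- match.arg(rule)
  t <- as.integer(t)
  if (t < 1L || t > n_blocks(partition))
    pf_stop(sprintf("stage index t=%d out of 1..%d", t, n_blocks(partition)),
            "profuse_error_arg")
  ok <- rep(TRUE, nrow(table$data))
  for (b in seq_len(t)) {
    vars <- partition$blocks[[b]]
    obs <- !is.na(as.matrix(table$data[, vars, drop = FALSE]))
    ok <- ok & if (rule == "all_variables") apply(obs, 1, all)
               else apply(obs, 1, any)
  }
  table$sample_ids[ok]
}

#' Balance classes by random duplication of the minority class
#'
#' Training rows of the minority class are duplicated uniformly at random
#' with replacement until both classes have the majority count. Majority
#' rows are untouched and appear exactly once.
#'
#' @param x numeric matrix of training rows.
#' @param labels 0/1 vector aligned with `x`.
#' @param seed integer seed; fixes the duplication draw.
#' @return list with `x`, `labels` and `index` (row indices into the
#'   input, majority + original minority first).
#' @export
oversample <- function(x, labels, seed) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    pf_stop("oversample needs both classes present", "profuse_error_single_class")
  if (n1 == n0) {
    idx <- seq_along(labels)
  } else {
    minority <- if (n1 < n0) 1L else 0L
    need <- abs(n0 - n1)
    min_idx <- which(labels == minority)
    extra <- with_seed(seed, sample(min_idx, need, replace = TRUE))
    idx <- c(seq_along(labels), extra)
  }
  list(x = x[idx, , drop = FALSE], labels = labels[idx], index = idx)
}
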