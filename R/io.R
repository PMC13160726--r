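# Plain-text interchange: cohort CSV (header = variable names, missing
# cell = empty or NA, outcome column named in the partition config),
# optional long-format repeats CSV, and YAML/JSON partition and
# experiment configs.

#' Read a cohort table from CSV
#'
#' @param path CSV with one header row of variable names; empty cells or
#'   `NA` mark missing entries.
#' @param outcome name of the 0/1 outcome column.
#' @param id_column optional sample-id column name; row numbers otherwise.
#' @param specs optional named list of [variable_spec()]s; inferred
#'   otherwise.
#' @param repeats_path optional long-format CSV (`sample_id`, `variable`,
#'   `value`) of repeated measurements.
#' @return a [cohort_table()].
#' @export
read_cohort_csv <- function(path, outcome = "outcome", id_column = NULL,
                            specs = NULL, repeats_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), check.names = FALSE)
  if (!outcome %in% names(df))
    pf_stop(sprintf("outcome column '%s' not found", outcome),
            "profuse_error_spec")
  ids <- if (!is.null(id_column)) {
    v <- as.character(df[[id_column]]); df[[id_column]] <- NULL; v
  } else NULL
  y <- df[[outcome]]
  df[[outcome]] <- NULL
  rp <- if (!is.null(repeats_path))
    read.csv(repeats_path, stringsAsFactors = FALSE) else NULL
  cohort_table(df, y, specs = specs, sample_ids = ids, repeats = rp)
}

#' Write a cohort table (and optional truth sidecar) to CSV
#'
#' @param table a [cohort_table()].
#' @param path output CSV path.
#' @param outcome outcome column name to emit.
#' @param truth optional truth data.frame (latent class, observed flags)
#'   from [generate_cohort()].
#' @param truth_path sidecar path (default `<path>` with `_truth` suffix).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path, outcome = "outcome",
                             truth = NULL, truth_path = NULL) {
  df <- cbind(data.frame(sample_id = table$sample_ids,
                         stringsAsFactors = FALSE),
              table$data)
  df[[outcome]] <- table$outcome
  write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    truth_path <- truth_path %||% sub("(\\.csv)?$", "_truth.csv", path)
    write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a modality-partition config (YAML or JSON)
#'
#' Expected keys: ordered `blocks:` mapping block name to variable list,
#' `fixed_prefix:`, `outcome:`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [modality_partition()].
#' @export
read_partition <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$blocks))
    pf_stop("partition config needs a 'blocks' mapping", "profuse_error_spec")
  blocks <- lapply(cfg$blocks, function(b) as.character(unlist(b)))
  modality_partition(blocks,
                     fixed_prefix = cfg$fixed_prefix %||% 1L,
                     outcome = cfg$outcome %||% "outcome")
}

#' Write a modality-partition config
#'
#' @param partition a [modality_partition()].
#' @param path output path; extension selects YAML or JSON.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  obj <- list(blocks = partition$blocks,
              fixed_prefix = partition$fixed_prefix,
              outcome = partition$outcome)
  write_config_file(obj, path)
  invisible(path)
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

write_config_file <- function(obj, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(obj, path)
  else
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' Write chain predictions to CSV
#'
#' One row per sample: id, reached depth, probability, hard label at 0.5,
#' and one trace column per stage.
#'
#' @param prediction a `chain_prediction` from [predict.fused_chain()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(prediction, path) {
  df <- cbind(as.data.frame(prediction), attr(prediction, "trace"))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
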