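#' @useDynLib profuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate binomial coef glm median plogis pnorm predict
#'   qlogis quantile rbinom rnorm runif sd var
#' @importFrom utils modifyList read.csv write.csv
NULL

# Typed condition helpers -----------------------------------------------------

pf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "profuse_error"), call = call))
}

pf_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "profuse_warning")))
}

# routine, logged events (e.g. unseen categories at prediction time):
# classed messages, so callers can catch them without warning noise
pf_log <- function(msg, class) {
  message(structure(
    class = c(class, "profuse_message", "message", "condition"),
    list(message = paste0(msg, "\n"), call = NULL)))
}

# Deterministic seed derivation -----------------------------------------------

#' Derive a reproducible sub-seed from a base seed and a label
#'
#' Every stochastic component (splits, oversampling, tree fitting, bootstrap)
#' draws its own seed from the run seed through this function, so components
#' are independently reproducible and adding one stochastic step never
#' perturbs the draws of another.
#'
#' @param seed integer base seed.
#' @param ... labels (strings or integers) identifying the consumer.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
seed_stream <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(x) else as.integer(x)
  }))
  h <- as.double(seed %% 2147483647L)
  for (v in parts) {
    h <- (h * 31 + as.double(v) + 7) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Probability helpers ---------------------------------------------------------

clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a
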