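# Synthetic cohort generator.
#
# Emulates the statistical structure the fusion method assumes: a latent
# binary class, class-conditional variables grouped into six modality
# blocks (demographics, BMD, bone turnover markers, biochemical panel,
# hemoglobin, HbA1c), and block-level availability masks applied per
# sample. Continuous variables are independent Gaussians within class
# (only marginal means/SDs are published for the source cohort); an
# optional within-block equicorrelation is available for stress tests.

#' Generator parameters for a synthetic cohort
#'
#' @param variables named list; each element a list with `block`, `kind`
#'   (`binary`/`categorical`/`continuous`) and class-conditional
#'   parameters: continuous `mean`/`sd` (length-2, control then case),
#'   binary `prob` (length-2), categorical `probs` (list of 2 vectors)
#'   plus `categories`.
#' @param blocks character vector giving block order.
#' @param availability named list: per block, length-2 probability of the
#'   block being observed for (control, case). Block 1 defaults to fully
#'   observed.
#' @param n_samples cohort size.
#' @param prevalence case probability.
#' @param block_correlation within-block equicorrelation of continuous
#'   variables (default 0, matching the marginal-only specification).
#' @param truncate_positive truncate physically positive variables at 0.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(variables, blocks, availability,
                             n_samples = 1287L, prevalence = 0.4996,
                             block_correlation = 0,
                             truncate_positive = FALSE) {
  for (v in names(variables)) {
    vv <- variables[[v]]
    if (!vv$block %in% blocks)
      pf_stop(sprintf("variable '%s' assigned to unknown block '%s'", v, vv$block),
              "profuse_error_spec")
    if (vv$kind == "continuous" && any(vv$sd <= 0))
      pf_stop(sprintf("variable '%s': SDs must be > 0", v), "profuse_error_spec")
    if (vv$kind == "binary" && any(vv$prob < 0 | vv$prob > 1))
      pf_stop(sprintf("variable '%s': probabilities in [0,1]", v),
              "profuse_error_spec")
  }
  if (!setequal(names(availability), blocks))
    pf_stop("availability must name every block", "profuse_error_spec")
  av <- lapply(availability, function(a) rep_len(a, 2L))
  if (any(unlist(av) < 0 | unlist(av) > 1))
    pf_stop("availabilities must lie in [0,1]", "profuse_error_spec")
  if (prevalence <= 0 || prevalence >= 1)
    pf_stop("prevalence must lie in (0,1)", "profuse_error_spec")
  structure(list(variables = variables, blocks = blocks,
                 availability = av[blocks],
                 n_samples = as.integer(n_samples),
                 prevalence = prevalence,
                 block_correlation = block_correlation,
                 truncate_positive = truncate_positive),
            class = "generator_params")
}

cv_cont <- function(block, mean_ctrl, sd_ctrl, mean_case, sd_case,
                    positive = FALSE) {
  list(block = block, kind = "continuous",
       mean = c(mean_ctrl, mean_case), sd = c(sd_ctrl, sd_case),
       positive = positive)
}

cv_bin <- function(block, p_ctrl, p_case) {
  list(block = block, kind = "binary", prob = c(p_ctrl, p_case))
}

cv_cat <- function(block, probs_ctrl, probs_case, categories) {
  list(block = block, kind = "categorical",
       probs = list(probs_ctrl, probs_case), categories = categories)
}

#' Default parameters transcribed from the source cohort's baseline table
#'
#' Class-conditional means/SDs and event proportions for 31 variables in
#' six modality blocks, as published for a hip-fracture case/control
#' cohort of 1,287 records (case class = fracture). Marital-status and
#' ethnicity category frequencies are not published; plausible values for
#' an elderly urban Chinese cohort are used, identical in both classes
#' (so they carry no signal). Block availabilities default to the
#' published per-block totals (class-independent); with
#' `class_dependent = TRUE` the per-class observed counts are used
#' instead.
#'
#' @param class_dependent use per-class availability (the published
#'   per-class block counts) rather than the pooled totals.
#' @return a [generator_params()] object.
#' @export
table1_default_params <- function(class_dependent = FALSE) {
  vars <- list(
    # demographics ------------------------------------------------- block 1
    gender_male = cv_bin("demographics", 492 / 644, 134 / 643),
    age = cv_cont("demographics", 84.38, 6.807, 76.98, 8.747),
    marital_status = cv_cat("demographics",
                            c(0.03, 0.52, 0.05, 0.40), c(0.03, 0.52, 0.05, 0.40),
                            c("unmarried", "married", "divorced", "widowed")),
    ethnicity = cv_cat("demographics",
                       c(0.90, rep(0.10 / 12, 12)), c(0.90, rep(0.10 / 12, 12)),
                       c("Han", "Hui", "Manchu", "Mongolian", "Miao", "Tujia",
                         "Uighur", "Xibe", "Kazakh", "Korean", "Daur",
                         "Gelao", "Zhuang")),
    fracture_history = cv_bin("demographics", 0.1273, 0.2193),
    smoking_history = cv_bin("demographics", 0.2733, 0.05288),
    smoking_duration = cv_cont("demographics", 31.06, 15.94, 35.76, 8.982),
    alcohol_history = cv_bin("demographics", 0.1040, 0.04199),
    alcohol_duration = cv_cont("demographics", 32.63, 11.08, 27.59, 6.957),
    # BMD ----------------------------------------------------------- block 2
    femoral_neck_bmd = cv_cont("bmd", 0.8008, 0.1535, 0.6292, 0.1136, TRUE),
    femoral_neck_tscore = cv_cont("bmd", -1.322, 1.224, -2.551, 1.007),
    total_hip_bmd = cv_cont("bmd", 0.8902, 0.1691, 0.6675, 0.1300, TRUE),
    total_hip_tscore = cv_cont("bmd", 0.7553, 1.310, -2.391, 1.110),
    lumbar_spine_tscore = cv_cont("bmd", 0.7577, 2.062, -2.060, 1.623),
    mechanical_index = cv_cont("bmd", 1.378, 0.6540, 1.236, 0.5271, TRUE),
    curvature_ratio = cv_cont("bmd", 8.348, 6.950, 9.310, 9.528, TRUE),
    section_modulus = cv_cont("bmd", 581.3, 246.8, 401.3, 145.9, TRUE),
    # bone turnover markers ------------------------------------------ block 3
    ipth = cv_cont("bone_turnover", 47.92, 28.28, 49.03, 24.78, TRUE),
    vitamin_d_25oh = cv_cont("bone_turnover", 18.29, 10.11, 16.62, 8.891, TRUE),
    tpinp = cv_cont("bone_turnover", 42.52, 26.45, 48.81, 34.93, TRUE),
    beta_ctx = cv_cont("bone_turnover", 0.4070, 0.2375, 0.4940, 0.3226, TRUE),
    n_mid = cv_cont("bone_turnover", 13.68, 6.078, 14.21, 7.749, TRUE),
    # biochemical examination ---------------------------------------- block 4
    albumin_globulin = cv_cont("biochemical", 1.974, 4.643, 1.954, 3.025),
    calcium = cv_cont("biochemical", 2.270, 0.1331, 2.283, 0.1174, TRUE),
    alkaline_phosphatase = cv_cont("biochemical", 56.75, 27.55, 63.34, 25.78, TRUE),
    creatinine = cv_cont("biochemical", 91.13, 47.05, 67.45, 23.68, TRUE),
    total_cholesterol = cv_cont("biochemical", 4.049, 0.9931, 4.468, 1.131, TRUE),
    ldl_c = cv_cont("biochemical", 2.138, 0.7664, 2.452, 0.9122, TRUE),
    hdl_c = cv_cont("biochemical", 1.284, 0.3271, 1.432, 0.3801, TRUE),
    triglycerides = cv_cont("biochemical", 1.412, 1.091, 1.327, 0.7557, TRUE),
    # hemoglobin ------------------------------------------------------ block 5
    hemoglobin = cv_cont("hemoglobin", 121.4, 23.53, 106.3, 30.81, TRUE),
    # HbA1c ----------------------------------------------------------- block 6
    hba1c = cv_cont("hba1c", 6.460, 1.328, 6.719, 1.477, TRUE)
  )
  blocks <- c("demographics", "bmd", "bone_turnover", "biochemical",
              "hemoglobin", "hba1c")
  availability <- if (class_dependent) {
    list(demographics = c(1, 1),
         bmd = c(513 / 644, 171 / 643),
         bone_turnover = c(511 / 644, 258 / 643),
         biochemical = c(508 / 644, 176 / 643),
         hemoglobin = c(425 / 644, 206 / 643),
         hba1c = c(520 / 644, 145 / 643))
  } else {
    list(demographics = c(1, 1),
         bmd = rep(684 / 1287, 2),
         bone_turnover = rep(769 / 1287, 2),
         biochemical = rep(684 / 1287, 2),
         hemoglobin = rep(751 / 1287, 2),
         hba1c = rep(665 / 1287, 2))
  }
  generator_params(vars, blocks, availability,
                   n_samples = 1287L, prevalence = 643 / 1287)
}

#' Default modality partition matching [table1_default_params()]
#'
#' Demographics and BMD are pinned as the first two stages (the most
#' available block and the strongest clinical predictor respectively).
#'
#' @param params a [generator_params()].
#' @return a [modality_partition()].
#' @export
default_partition <- function(params = table1_default_params()) {
  blocks <- lapply(params$blocks, function(b) {
    names(Filter(function(v) v$block == b, params$variables))
  })
  names(blocks) <- params$blocks
  modality_partition(blocks, fixed_prefix = min(2L, length(blocks)))
}

#' Plant (or remove) discriminative signal in one block
#'
#' Rewrites the block's continuous variables to unit-SD Gaussians whose
#' class means are separated by `d` standard deviations, and equalises the
#' block's binary/categorical class proportions, so the block's signal is
#' exactly the planted `d` (with `d = 0` the block is pure noise).
#'
#' @param params a [generator_params()].
#' @param block_name block to rewrite.
#' @param effect standardized mean difference `d`.
#' @return modified [generator_params()].
#' @export
plant_signal <- function(params, block_name, effect) {
  if (!block_name %in% params$blocks)
    pf_stop(paste("unknown block:", block_name), "profuse_error_arg")
  in_block <- names(Filter(function(v) v$block == block_name,
                           params$variables))
  kinds <- vapply(params$variables[in_block], `[[`, "", "kind")
  if (!any(kinds == "continuous"))
    pf_stop(sprintf("block '%s' has no continuous variables", block_name),
            "profuse_error_arg")
  for (v in in_block) {
    vv <- params$variables[[v]]
    if (vv$kind == "continuous") {
      vv$mean <- c(0, effect); vv$sd <- c(1, 1); vv$positive <- FALSE
    } else if (vv$kind == "binary") {
      vv$prob <- rep(mean(vv$prob), 2L)
    } else {
      pr <- (vv$probs[[1]] + vv$probs[[2]]) / 2
      vv$probs <- list(pr, pr)
    }
    params$variables[[v]] <- vv
  }
  params
}

#' Generate a synthetic cohort
#'
#' Draws a latent class per sample, class-conditional variable values, and
#' class-dependent block-level availability masks. Fully reproducible for
#' a fixed seed.
#'
#' @param params a [generator_params()].
#' @param seed integer seed.
#' @return list with `table` (a [cohort_table()]) and `truth`
#'   (data.frame of latent class and per-block observed flags).
#' @export
generate_cohort <- function(params, seed = 0L) {
  n <- params$n_samples
  with_seed(seed, {
    cls <- rbinom(n, 1L, params$prevalence)
    data <- list()
    specs <- list()
    for (v in names(params$variables)) {
      vv <- params$variables[[v]]
      if (vv$kind == "continuous") {
        x <- rnorm(n, vv$mean[cls + 1L], vv$sd[cls + 1L])
        if (params$truncate_positive && isTRUE(vv$positive)) x <- pmax(x, 0)
        specs[[v]] <- variable_spec(v, "continuous")
      } else if (vv$kind == "binary") {
        x <- rbinom(n, 1L, vv$prob[cls + 1L])
        specs[[v]] <- variable_spec(v, "binary")
      } else {
        k <- length(vv$categories)
        x <- integer(n)
        for (c0 in 0:1) {
          idx <- which(cls == c0)
          if (length(idx))
            x[idx] <- sample.int(k, length(idx), replace = TRUE,
                                 prob = vv$probs[[c0 + 1L]])
        }
        specs[[v]] <- variable_spec(v, "categorical",
                                    categories = vv$categories)
      }
      data[[v]] <- as.numeric(x)
    }
    # optional within-block equicorrelation of continuous variables
    if (params$block_correlation > 0) {
      rho <- params$block_correlation
      for (b in params$blocks) {
        cont <- names(Filter(function(vv) vv$block == b &&
                               vv$kind == "continuous", params$variables))
        if (length(cont) < 2L) next
        z <- rnorm(n)
        for (v in cont) {
          vv <- params$variables[[v]]
          mu <- vv$mean[cls + 1L]; sdv <- vv$sd[cls + 1L]
          e <- (data[[v]] - mu) / sdv
          data[[v]] <- mu + sdv * (sqrt(rho) * z + sqrt(1 - rho) * e)
        }
      }
    }
    observed <- matrix(TRUE, n, length(params$blocks),
                       dimnames = list(NULL, params$blocks))
    for (b in params$blocks) {
      a <- params$availability[[b]][cls + 1L]
      observed[, b] <- runif(n) < a
      if (!all(observed[, b])) {
        vars <- names(Filter(function(vv) vv$block == b, params$variables))
        for (v in vars) data[[v]][!observed[, b]] <- NA_real_
      }
    }
    tab <- cohort_table(as.data.frame(data), cls, specs = specs)
    truth <- data.frame(sample_id = tab$sample_ids, class = cls,
                        observed, stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}
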