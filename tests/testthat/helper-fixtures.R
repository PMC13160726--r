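# In-code fixtures shared across test files. Everything is generated at
# test time; no stored data.

# A 3-block generator: block "a" (2 continuous + 1 binary), block "b"
# (2 continuous), block "c" (1 continuous). Signal is whatever the caller
# plants; raw defaults are pure noise in the continuous variables and a
# mild binary effect that plant_signal() can flatten.
tiny_params <- function(n = 300L, avail_b = 1, avail_c = 1,
                        prevalence = 0.5) {
  vars <- list(
    a1 = list(block = "a", kind = "continuous", mean = c(0, 0), sd = c(1, 1)),
    a2 = list(block = "a", kind = "continuous", mean = c(0, 0), sd = c(1, 1)),
    a3 = list(block = "a", kind = "binary", prob = c(0.3, 0.6)),
    b1 = list(block = "b", kind = "continuous", mean = c(0, 0), sd = c(1, 1)),
    b2 = list(block = "b", kind = "continuous", mean = c(0, 0), sd = c(1, 1)),
    c1 = list(block = "c", kind = "continuous", mean = c(0, 0), sd = c(1, 1))
  )
  generator_params(vars, c("a", "b", "c"),
                   list(a = 1, b = avail_b, c = avail_c),
                   n_samples = n, prevalence = prevalence)
}

tiny_partition <- function() {
  modality_partition(list(a = c("a1", "a2", "a3"),
                          b = c("b1", "b2"),
                          c = "c1"),
                     fixed_prefix = 1L)
}

# A fully deterministic 6-sample table with hand-set missingness.
hand_table <- function() {
  cohort_table(
    data.frame(
      x1 = c(1.0, 2.0, NA, 4.0, 5.0, 6.0),
      x2 = c(0, 1, 1, 0, NA, 1),
      y1 = c(10, NA, 30, 40, 50, 60),
      z1 = c(0.1, 0.2, 0.3, NA, 0.5, 0.6)
    ),
    outcome = c(0, 1, 0, 1, 0, 1),
    sample_ids = paste0("s", 1:6)
  )
}

hand_partition <- function() {
  modality_partition(list(one = c("x1", "x2"), two = "y1", three = "z1"),
                     fixed_prefix = 1L)
}

# Held-out accuracy of a chain fit on 70% of `tab`.
heldout_accuracy <- function(tab, part, seed, families = "gbt",
                             residual_mode = "prob_residual",
                             max_depth = NULL) {
  sp <- train_test_split(tab, 0.7, seed)
  ch <- fit_chain(profuse:::subset_samples(tab, sp$train_ids), part,
                  families = families, residual_mode = residual_mode,
                  seed = seed)
  te <- profuse:::subset_samples(tab, sp$test_ids)
  pr <- predict(ch, te, max_depth = max_depth)
  ok <- !is.na(pr$label)
  mean(pr$label[ok] == te$outcome[ok])
}
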