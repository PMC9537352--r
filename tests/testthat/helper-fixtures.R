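# Shared fixtures: all inputs are built in code at test time.

write_cost_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random multilinear scoring function with interactions, plus an input and a
# small background set; used as a generic nonlinear model for Shapley tests.
random_small_model <- function(m, seed) {
  set.seed(seed)
  w <- round(stats::rnorm(m), 3)
  pairs <- if (m >= 2) utils::combn(m, 2L) else matrix(integer(0), 2, 0)
  u <- round(stats::rnorm(ncol(pairs), sd = 0.5), 3)
  fn <- function(X) {
    out <- drop(X %*% w)
    for (p in seq_len(ncol(pairs))) {
      out <- out + u[p] * X[, pairs[1, p]] * X[, pairs[2, p]]
    }
    out
  }
  list(fn = fn, x = round(stats::rnorm(m), 3),
       bg = matrix(round(stats::rnorm(3 * m), 3), 3, m))
}

# Generate, preprocess and cost-expand a synthetic cohort in one call.
make_cohort <- function(spec, seed) {
  coh <- generate_cohort(spec, seed = seed)
  data <- preprocess_data(coh$data, "label", seed = seed)
  list(data = data,
       costs = expand_cost_table(coh$costs, data),
       raw = coh,
       X_test = data$X[data$split == "test", , drop = FALSE],
       y_test = data$y[data$split == "test"])
}
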