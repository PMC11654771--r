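# Independent oracles used across tests. Each one reaches the target
# quantity by a different route than the implementation under test.

# JZS Bayes factor via the noncentral-t route: marginal likelihood under H1
# as the integral of the noncentral-t density against the Cauchy prior on
# effect size (the implementation integrates over the g-mixture instead).
jzs_bf_oracle <- function(t, n, rscale) {
  df <- n - 1
  num <- suppressWarnings(stats::integrate(
    function(d) stats::dt(t, df, ncp = d * sqrt(n)) *
      stats::dcauchy(d, 0, rscale),
    -Inf, Inf, rel.tol = 1e-12, subdivisions = 2000L))$value
  num / stats::dt(t, df)
}

# OLS slope/intercept by the textbook closed form (the implementation uses
# stats::lm).
ols_line <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

fig12_sizes <- c(21, 28, 35, 42)

# A minimal noise-free design: responses are exactly k*s + overshoot.
noise_free_design <- function(k = 0.7, overshoot = 18, n_subjects = 4,
                              reps = 5, conditions = c("A", "B")) {
  params <- lapply(conditions, function(cd)
    two_stage_params(k = k, overshoot = overshoot, sigma_impl = 0,
                     weber_v = 0))
  names(params) <- conditions
  experiment_design(sizes = fig12_sizes, conditions = params,
                    reps_per_size = reps, n_subjects = n_subjects)
}

# Hand-built single-cell trial table.
make_cell <- function(responses, subject = 1L, condition = "A",
                      size = 35, block = 1L) {
  tibble::tibble(
    subject = subject, group = NA_character_, condition = condition,
    block = block, size_mm = size,
    repetition = seq_along(responses), response_mm = responses)
}
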