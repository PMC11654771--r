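test_that("generated tables have the full factorial size and schema", {
  des <- experiment_design(fig12_sizes,
                           list(MGA = fig12_params("MGA"),
                                MSE = fig12_params("MSE")),
                           reps_per_size = 20, n_subjects = 20)
  tab <- generate_experiment(des, seed = 3)
  expect_equal(nrow(tab), 4 * 2 * 20 * 20)
  expect_named(tab, c("subject", "group", "condition", "block", "size_mm",
                      "repetition", "response_mm"))
  counts <- dplyr::count(tab, subject, condition, size_mm)
  expect_true(all(counts$n == 20))
  # repetition indices dense 1..reps within each cell
  reps <- tab |>
    dplyr::group_by(subject, condition, size_mm) |>
    dplyr::summarise(ok = identical(sort(repetition), 1:20),
                     .groups = "drop")
  expect_true(all(reps$ok))
})

test_that("design and drift constructors reject invalid structure", {
  expect_error(experiment_design(numeric(0), list(A = fig12_params("MGA")),
                                 1, 1), "positive")
  expect_error(experiment_design(21, list(fig12_params("MGA")), 1, 1),
               "unique")
  expect_error(experiment_design(21, list(A = fig12_params("MGA"),
                                          A = fig12_params("MSE")), 1, 1),
               "unique")
  expect_error(drift_spec(rate = 0.5), "targets")
  expect_error(drift_spec(list(A = fig12_params("MGA")), rate = 1.5),
               "\\[0, 1\\]")
})

test_that("with all noise off every response equals k*s + overshoot", {
  des <- noise_free_design(k = 0.7, overshoot = 18)
  tab <- generate_experiment(des, between_subject_sd = 0, seed = 1)
  expect_identical(tab$response_mm, 0.7 * tab$size_mm + 18)
})

test_that("the same seed reproduces the table bit-identically", {
  des <- noise_free_design()
  t1 <- generate_experiment(des, between_subject_sd = 2, seed = 99)
  t2 <- generate_experiment(des, between_subject_sd = 2, seed = 99)
  expect_identical(t1, t2)
})

test_that("the reference cohort wrapper matches its stated layout", {
  tab <- generate_fig12_cohort(seed = 4)
  expect_equal(nrow(tab), 3200)
  expect_setequal(unique(tab$condition), c("MGA", "MSE"))
  expect_setequal(unique(tab$size_mm), fig12_sizes)

  # large-reps variant: per-size SD converges on the closed form
  big <- generate_fig12_cohort(seed = 5, n_subjects = 1,
                               reps_per_size = 20000)
  mse42 <- big$response_mm[big$condition == "MSE" & big$size_mm == 42]
  expect_equal(sd(mse42), sqrt((0.06 * 42)^2 + 4), tolerance = 0.01)
})

test_that("between-subject heterogeneity inflates across-subject variance", {
  des <- experiment_design(fig12_sizes,
                           list(A = fig12_params("MSE")),
                           reps_per_size = 200, n_subjects = 40)
  subj_means <- function(tab) {
    tapply(tab$response_mm, tab$subject, mean)
  }
  v0 <- var(subj_means(generate_experiment(des, between_subject_sd = 0,
                                           seed = 21)))
  v5 <- var(subj_means(generate_experiment(des, between_subject_sd = 5,
                                           seed = 21)))
  # sampling-only variance of a subject mean is sd^2/800 << 25
  expect_gt(v5, v0 + 10)
})

test_that("trial tables round-trip through CSV bit-identically", {
  tab <- generate_fig12_cohort(seed = 8, n_subjects = 3, reps_per_size = 4)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trial_table(tab, f1, seed = 8)
  back <- read_trial_table(f1)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  write_trial_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  meta <- jsonlite::fromJSON(paste0(f1, ".meta.json"))
  expect_equal(meta$seed, 8)
})

test_that("schema validation names the offending column", {
  tab <- generate_fig12_cohort(seed = 1, n_subjects = 1, reps_per_size = 2)
  expect_error(validate_trial_table(tab[-which(names(tab) == "size_mm")]),
               "size_mm")
  bad <- tab
  bad$response_mm <- as.character(bad$response_mm)
  expect_error(validate_trial_table(bad), "response_mm")
})

test_that("drift interpolates parameters exponentially along the trial sequence", {
  sizes <- c(21, 42)
  base <- two_stage_params(k = 0.7, overshoot = 18, sigma_impl = 0,
                           weber_v = 0)
  target <- two_stage_params(k = 1.0, overshoot = 4, sigma_impl = 0,
                             weber_v = 0)
  des <- experiment_design(sizes, list(A = base), reps_per_size = 6,
                           n_subjects = 1)

  # rate 0: indistinguishable from the non-drift generator
  t0 <- generate_experiment(des, drift = drift_spec(list(A = target), 0),
                            seed = 2)
  expect_identical(t0$response_mm,
                   generate_experiment(des, seed = 2)$response_mm)

  # rate 1: every trial after the first sits at the target parameters
  t1 <- generate_experiment(des, drift = drift_spec(list(A = target), 1),
                            seed = 2)
  expect_identical(t1$response_mm[1], 0.7 * t1$size_mm[1] + 18)
  expect_identical(t1$response_mm[-1], 1.0 * t1$size_mm[-1] + 4)

  # rate 0.5, noise-free: per-trial k follows the direct recursion
  # k_t = k_{t-1} + rate * (k_target - k_{t-1})
  th <- generate_experiment(des, drift = drift_spec(list(A = target), 0.5),
                            seed = 2)
  n_trials <- nrow(th)
  k_rec <- numeric(n_trials); ov_rec <- numeric(n_trials)
  k_rec[1] <- 0.7; ov_rec[1] <- 18
  for (t in 2:n_trials) {
    k_rec[t] <- k_rec[t - 1] + 0.5 * (1.0 - k_rec[t - 1])
    ov_rec[t] <- ov_rec[t - 1] + 0.5 * (4 - ov_rec[t - 1])
  }
  expect_equal(th$response_mm, k_rec * th$size_mm + ov_rec)
})

test_that("adaptation carries across blocks according to retention", {
  sizes <- c(21, 42)
  base <- two_stage_params(0.7, 18, 0, 0)
  target <- two_stage_params(1.0, 4, 0, 0)
  des <- experiment_design(sizes, list(FB = base, WASH = base),
                           reps_per_size = 50, n_subjects = 1)
  dr_full <- drift_spec(list(FB = target), rate = 1, retention = 1)
  dr_none <- drift_spec(list(FB = target), rate = 1, retention = 0)
  tf <- generate_experiment(des, drift = dr_full, seed = 1)
  tn <- generate_experiment(des, drift = dr_none, seed = 1)
  wash_f <- tf[tf$condition == "WASH", ]
  wash_n <- tn[tn$condition == "WASH", ]
  # full retention: washout starts (and, with no further target, stays) at
  # the adapted parameters; zero retention: washout is pure baseline
  expect_equal(wash_f$response_mm, 1.0 * wash_f$size_mm + 4)
  expect_equal(wash_n$response_mm, 0.7 * wash_n$size_mm + 18)
})
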