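#!/usr/bin/env Rscript

# Step 1: simulate the study's trial tables.
#
# Generates (a) the reference two-condition cohort comparing the grasping
# response (MGA) and the manual size estimate (MSE) driven by the same
# Weber-scaled visual input, and (b) a three-block blocked design with
# trial-by-trial adaptation drift, illustrating the optional drift
# generator. Tables are written as canonical trial CSVs under results/.

suppressMessages(library(webergrasp))

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

cohort <- generate_fig12_cohort(seed = seed)
write_trial_table(cohort, "results/trials_fig12_cohort.csv", seed = seed)
cat(sprintf("reference cohort: %d trials (%d subjects x 2 conditions x 4 sizes x 20 reps)\n",
            nrow(cohort), length(unique(cohort$subject))))

# blocked design with adaptation: a feedback block drifts the mapping from
# the grasp-like parameters toward veridical, then a washout block retains
# 60% of the adaptation
base <- two_stage_params(k = 0.7, overshoot = 18, sigma_impl = 2,
                         weber_v = 0.06)
veridical <- two_stage_params(k = 1.0, overshoot = 4, sigma_impl = 2,
                              weber_v = 0.06)
des <- experiment_design(
  sizes = c(21, 28, 35, 42),
  conditions = list(baseline = base, feedback = base, washout = base),
  reps_per_size = 20, n_subjects = 10, group = "BLOCKED")
drift <- drift_spec(targets = list(feedback = veridical), rate = 0.1,
                    retention = 0.6)
adapt <- generate_experiment(des, between_subject_sd = 2, drift = drift,
                             seed = seed + 1L)
write_trial_table(adapt, "results/trials_adaptation.csv", seed = seed + 1L)
cat(sprintf("adaptation table: %d trials across %d blocks\n",
            nrow(adapt), length(unique(adapt$block))))
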