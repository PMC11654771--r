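#' Define an experiment design for simulation
#'
#' Describes the factorial structure of a simulated session: the object
#' sizes, the per-condition generative parameters, repetitions per size, and
#' the number of subjects. Conditions are run in blocks in the order given
#' (`block = 1, 2, ...`) unless `blocked = FALSE`, in which case all trials
#' share block 1 (an intermixed session).
#'
#' @param sizes Numeric vector of object sizes in mm (> 0, at least 2
#'   distinct values for any slope fit downstream).
#' @param conditions Named list of [two_stage_params()], one per condition;
#'   names are the condition labels and must be unique.
#' @param reps_per_size Repetitions of each size within each condition
#'   (>= 1).
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param group Optional group label (e.g. "BLOCKED"), recorded in the trial
#'   table.
#' @param blocked If `TRUE` (default) each condition occupies its own block
#'   in list order; if `FALSE` all conditions share block 1.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' des <- experiment_design(
#'   sizes = c(21, 28, 35, 42),
#'   conditions = list(MGA = fig12_params("MGA"), MSE = fig12_params("MSE")),
#'   reps_per_size = 20, n_subjects = 20)
#' @export
experiment_design <- function(sizes, conditions, reps_per_size, n_subjects,
                              group = NA_character_, blocked = TRUE) {
  if (!is.numeric(sizes) || length(sizes) == 0 || any(!is.finite(sizes)) ||
      any(sizes <= 0))
    stop("`sizes` must be positive finite numbers", call. = FALSE)
  if (!is.list(conditions) || length(conditions) == 0)
    stop("`conditions` must be a non-empty named list of two_stage_params",
         call. = FALSE)
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)) ||
      any(names(conditions) == ""))
    stop("condition labels must be unique and non-empty", call. = FALSE)
  ok <- vapply(conditions, inherits, logical(1), "two_stage_params")
  if (!all(ok))
    stop("every condition must be a two_stage_params object", call. = FALSE)
  if (reps_per_size < 1) stop("`reps_per_size` must be >= 1", call. = FALSE)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  structure(
    list(sizes = as.numeric(sizes), conditions = conditions,
         reps_per_size = as.integer(reps_per_size),
         n_subjects = as.integer(n_subjects),
         group = group, blocked = isTRUE(blocked)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Experiment design: %d subjects x %d conditions (%s) x %d sizes x %d reps\n",
    x$n_subjects, length(x$conditions),
    paste(names(x$conditions), collapse = ", "),
    length(x$sizes), x$reps_per_size))
  invisible(x)
}

#' Specify trial-by-trial adaptation drift
#'
#' An explicitly synthetic add-on: generative parameters relax exponentially
#' from each condition's nominal values toward per-condition targets, one
#' step per trial, emulating rapid trial-by-trial correction under feedback.
#' This is plumbing for robustness studies, not a fitted model of any
#' empirical adaptation curve.
#'
#' At trial `t = 0, 1, ...` within a subject-by-condition sequence, each
#' parameter follows `p_t = target + (start - target) * (1 - rate)^t`. When a
#' block ends, a fraction `retention` of the accumulated adaptation
#' (deviation from the next block's nominal parameters' baseline) carries
#' into the next block; `retention = 1` carries it fully, `0` resets.
#'
#' @param targets Named list of [two_stage_params()], one per condition to
#'   drift (conditions not listed keep fixed parameters).
#' @param rate Per-trial convergence rate in \[0, 1\].
#' @param retention Fraction of adaptation retained across block boundaries,
#'   in \[0, 1\].
#' @return An object of class `drift_spec`.
#' @export
drift_spec <- function(targets, rate, retention = 1) {
  if (missing(targets) || !is.list(targets) || length(targets) == 0 ||
      is.null(names(targets)))
    stop("drift enabled without named `targets`", call. = FALSE)
  ok <- vapply(targets, inherits, logical(1), "two_stage_params")
  if (!all(ok))
    stop("every drift target must be a two_stage_params object", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1)
    stop("`rate` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(retention) || length(retention) != 1L ||
      retention < 0 || retention > 1)
    stop("`retention` must be in [0, 1]", call. = FALSE)
  structure(list(targets = targets, rate = rate, retention = retention),
            class = "drift_spec")
}

# Per-trial exponential interpolation used by the drift generator:
# p_t = target + (start - target) * (1 - rate)^t, t = 0 .. n_trials - 1.
drift_param_path <- function(start, target, rate, n_trials) {
  t <- seq_len(n_trials) - 1
  target + (start - target) * (1 - rate)^t
}

param_fields <- c("k", "overshoot", "sigma_impl", "weber_v")

#' Simulate a trial table from an experiment design
#'
#' Draws every trial of the design through the two-stage model. Subject
#' heterogeneity enters as an additive Gaussian offset on the overshoot
#' (a by-subject random intercept, drawn independently per subject and
#' condition) and, optionally, multiplicative jitter on the mapping slope.
#' Trials within a subject-by-condition cell proceed in sweeps across the
#' size list; the repetition index records the sweep.
#'
#' @param design An [experiment_design()].
#' @param between_subject_sd SD (mm) of the additive by-subject offset on
#'   overshoot; 0 disables heterogeneity.
#' @param slope_jitter_sd SD of multiplicative jitter on `k` (per subject and
#'   condition, `k * (1 + N(0, sd))`); 0 (default) disables it.
#' @param drift Optional [drift_spec()] enabling trial-by-trial parameter
#'   drift; `NULL` (default) keeps parameters fixed.
#' @param seed Optional integer seed; when given, the table is a
#'   deterministic function of (design, arguments, seed).
#'
#' @return A tibble with columns
#'   `subject, group, condition, block, size_mm, repetition, response_mm`
#'   and `n_subjects * n_conditions * n_sizes * reps_per_size` rows.
#' @examples
#' des <- experiment_design(c(21, 28, 35, 42),
#'   list(MGA = fig12_params("MGA"), MSE = fig12_params("MSE")),
#'   reps_per_size = 20, n_subjects = 20)
#' tab <- generate_experiment(des, seed = 1)
#' nrow(tab)  # 3200
#' @export
generate_experiment <- function(design, between_subject_sd = 0,
                                slope_jitter_sd = 0, drift = NULL,
                                seed = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(drift) && !inherits(drift, "drift_spec"))
    stop("`drift` must be NULL or a drift_spec", call. = FALSE)
  if (between_subject_sd < 0 || slope_jitter_sd < 0)
    stop("heterogeneity SDs must be >= 0", call. = FALSE)
  if (!is.null(drift)) {
    unknown <- setdiff(names(drift$targets), names(design$conditions))
    if (length(unknown) > 0)
      stop("drift targets for unknown condition(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  sizes <- design$sizes
  n_sizes <- length(sizes)
  reps <- design$reps_per_size
  n_trials <- n_sizes * reps
  cond_names <- names(design$conditions)
  # one sweep over all sizes per repetition; sweep r occupies trials
  # (r-1)*n_sizes .. r*n_sizes - 1 in design size order
  trial_size <- rep(sizes, times = reps)
  trial_rep <- rep(seq_len(reps), each = n_sizes)

  out <- vector("list", design$n_subjects * length(cond_names))
  idx <- 0L
  for (subj in seq_len(design$n_subjects)) {
    carry <- NULL  # adaptation displacement carried across blocks
    for (ci in seq_along(cond_names)) {
      cond <- cond_names[ci]
      base <- design$conditions[[cond]]
      offset <- if (between_subject_sd > 0)
        stats::rnorm(1, 0, between_subject_sd) else 0
      jitter <- if (slope_jitter_sd > 0)
        stats::rnorm(1, 0, slope_jitter_sd) else 0

      start <- c(k = base$k, overshoot = base$overshoot,
                 sigma_impl = base$sigma_impl, weber_v = base$weber_v)
      if (!is.null(drift) && !is.null(carry) && design$blocked)
        start <- start + drift$retention * carry

      if (!is.null(drift) && cond %in% names(drift$targets)) {
        tg <- drift$targets[[cond]]
        target <- c(k = tg$k, overshoot = tg$overshoot,
                    sigma_impl = tg$sigma_impl, weber_v = tg$weber_v)
      } else {
        target <- start
      }
      rate <- if (is.null(drift)) 0 else drift$rate
      path <- vapply(param_fields, function(f)
        drift_param_path(start[[f]], target[[f]], rate, n_trials),
        numeric(n_trials))

      k_t <- path[, "k"] * (1 + jitter)
      ov_t <- path[, "overshoot"] + offset
      si_t <- pmax(path[, "sigma_impl"], 0)
      wv_t <- pmax(path[, "weber_v"], 0)

      s_hat <- trial_size + stats::rnorm(n_trials, 0, wv_t * trial_size)
      resp <- k_t * s_hat + ov_t + stats::rnorm(n_trials, 0, si_t)

      if (!is.null(drift))
        carry <- path[n_trials, param_fields] -
          c(k = base$k, overshoot = base$overshoot,
            sigma_impl = base$sigma_impl, weber_v = base$weber_v)

      idx <- idx + 1L
      out[[idx]] <- tibble::tibble(
        subject = subj,
        group = design$group,
        condition = cond,
        block = if (design$blocked) ci else 1L,
        size_mm = trial_size,
        repetition = trial_rep,
        response_mm = resp
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Generative parameters of the grasping-vs-estimation simulation
#'
#' The two reference parameterizations of the simulation study: the maximum
#' grip aperture (MGA) response with a compressed mapping slope of 0.7, an
#' 18 mm overshoot, and 6 mm implementation noise; and the manual size
#' estimate (MSE) response with unity slope, 4 mm overshoot, and 2 mm
#' implementation noise. Both share a visual Weber fraction of 0.06.
#'
#' @param condition `"MGA"` or `"MSE"`.
#' @param weber_v Visual Weber fraction shared by both stages' conditions.
#' @return A [two_stage_params()] object.
#' @export
fig12_params <- function(condition = c("MGA", "MSE"), weber_v = 0.06) {
  condition <- match.arg(condition)
  switch(condition,
    MGA = two_stage_params(k = 0.7, overshoot = 18, sigma_impl = 6,
                           weber_v = weber_v),
    MSE = two_stage_params(k = 1.0, overshoot = 4, sigma_impl = 2,
                           weber_v = weber_v))
}

#' Simulate one cohort of the grasping-vs-estimation comparison
#'
#' Convenience wrapper for the reference simulation: sizes 21/28/35/42 mm,
#' 20 subjects, 20 repetitions per size, two conditions (MGA and MSE, see
#' [fig12_params()]) driven by the same visual-noise level, and no
#' between-subject heterogeneity by default.
#'
#' @param seed Optional integer seed.
#' @param n_subjects,reps_per_size Cohort dimensions (defaults 20 and 20).
#' @param between_subject_sd SD (mm) of by-subject overshoot offsets
#'   (default 0).
#' @param weber_v Shared visual Weber fraction (default 0.06).
#' @return A trial tibble with `n_subjects * 2 * 4 * reps_per_size` rows.
#' @export
generate_fig12_cohort <- function(seed = NULL, n_subjects = 20,
                                  reps_per_size = 20,
                                  between_subject_sd = 0, weber_v = 0.06) {
  des <- experiment_design(
    sizes = c(21, 28, 35, 42),
    conditions = list(MGA = fig12_params("MGA", weber_v),
                      MSE = fig12_params("MSE", weber_v)),
    reps_per_size = reps_per_size, n_subjects = n_subjects)
  generate_experiment(des, between_subject_sd = between_subject_sd,
                      seed = seed)
}

trial_table_cols <- c("subject", "group", "condition", "block",
                      "size_mm", "repetition", "response_mm")

#' Validate a trial table's schema
#'
#' Checks that the table carries exactly the canonical columns
#' `subject, group, condition, block, size_mm, repetition, response_mm`
#' with numeric sizes and responses. Errors name the offending column.
#'
#' @param table A data frame to validate.
#' @return The table, invisibly, if valid.
#' @export
validate_trial_table <- function(table) {
  if (!is.data.frame(table)) stop("trial table must be a data frame",
                                  call. = FALSE)
  missing <- setdiff(trial_table_cols, names(table))
  if (length(missing) > 0)
    stop("trial table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("size_mm", "repetition", "response_mm")) {
    if (!is.numeric(table[[col]]))
      stop("trial table column `", col, "` must be numeric", call. = FALSE)
  }
  invisible(table)
}

#' Read and write trial tables as CSV
#'
#' The on-disk format is UTF-8 CSV with header exactly
#' `subject,group,condition,block,size_mm,repetition,response_mm` and "."
#' as decimal separator. `write_trial_table()` can record the generating
#' seed in an adjacent `<path>.meta.json`.
#'
#' @param table A trial tibble (see [generate_experiment()]).
#' @param path CSV file path.
#' @param seed Optional seed to record in the metadata JSON.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the trial tibble.
#' @export
write_trial_table <- function(table, path, seed = NULL) {
  validate_trial_table(table)
  readr::write_csv(table[trial_table_cols], path)
  if (!is.null(seed)) {
    jsonlite::write_json(
      list(seed = seed, n_rows = nrow(table)),
      paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_integer(),
      group = readr::col_character(),
      condition = readr::col_character(),
      block = readr::col_integer(),
      size_mm = readr::col_character(),
      repetition = readr::col_integer(),
      response_mm = readr::col_character()
    ))
  # parse doubles with base strtod: correctly rounded, so written tables
  # round-trip to the exact same binary values
  tab$size_mm <- as.numeric(tab$size_mm)
  tab$response_mm <- as.numeric(tab$response_mm)
  validate_trial_table(tab)
  tab
}
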