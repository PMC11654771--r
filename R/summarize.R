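#' Exclude outlier trials within subject-by-condition-by-size cells
#'
#' Removes trials whose response deviates from its cell mean by at least
#' `z` sample standard deviations (n - 1 denominator). Cells with fewer than
#' 3 trials are passed through untouched and flagged. The criterion is
#' evaluated once on the original cell statistics, not iterated.
#'
#' @param table A trial tibble (see [generate_experiment()]).
#' @param z Deviation threshold in cell SDs (default 2.5).
#' @return A list with `table` (the filtered trial tibble) and `report`
#'   (a tibble of per-cell trial counts, removals, and small-cell flags).
#' @examples
#' tab <- generate_fig12_cohort(seed = 1, n_subjects = 2, reps_per_size = 5)
#' filt <- exclude_outlier_trials(tab)
#' sum(filt$report$n_removed)
#' @export
exclude_outlier_trials <- function(table, z = 2.5) {
  validate_trial_table(table)
  if (nrow(table) == 0) stop("trial table is empty", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z <= 0)
    stop("`z` must be a positive number", call. = FALSE)

  aug <- table |>
    dplyr::group_by(.data$subject, .data$condition, .data$size_mm) |>
    dplyr::mutate(
      .n = dplyr::n(),
      .mean = mean(.data$response_mm),
      .sd = stats::sd(.data$response_mm),
      .keep_trial = .data$.n < 3 | is.na(.data$.sd) | .data$.sd == 0 |
        abs(.data$response_mm - .data$.mean) < z * .data$.sd
    ) |>
    dplyr::ungroup()

  report <- aug |>
    dplyr::group_by(.data$subject, .data$condition, .data$size_mm) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_removed = sum(!.data$.keep_trial),
      small_cell = dplyr::first(.data$.n) < 3,
      .groups = "drop")

  list(
    table = aug |>
      dplyr::filter(.data$.keep_trial) |>
      dplyr::select(dplyr::all_of(trial_table_cols)),
    report = report
  )
}

#' Drop the first repetitions of each block
#'
#' Removes repetitions `1..n_drop` within each subject-by-condition-by-
#' block-by-size cell, the prescreen applied when responses change abruptly
#' at block transitions (e.g. sudden introduction or withdrawal of a cue).
#'
#' @param table A trial tibble.
#' @param n_drop Number of initial repetitions to remove (default 2).
#' @return The filtered trial tibble.
#' @export
drop_initial_repetitions <- function(table, n_drop = 2L) {
  validate_trial_table(table)
  if (!is.numeric(n_drop) || length(n_drop) != 1L || n_drop < 0)
    stop("`n_drop` must be a single number >= 0", call. = FALSE)
  if (n_drop == 0) return(table)
  max_rep <- table |>
    dplyr::group_by(.data$subject, .data$condition, .data$block,
                    .data$size_mm) |>
    dplyr::summarise(mx = max(.data$repetition), .groups = "drop")
  if (any(max_rep$mx <= n_drop))
    stop("`n_drop` >= available repetitions in at least one cell",
         call. = FALSE)
  dplyr::filter(table, .data$repetition > n_drop)
}

#' Per-subject mean and SD of the response at each size
#'
#' Collapses a (filtered) trial table to one row per subject, condition, and
#' size, carrying the sample mean and sample SD (n - 1 denominator) of the
#' response. Cells with a single trial have an undefined SD and are flagged.
#'
#' @param table A trial tibble.
#' @return A tibble with columns `subject, condition, size_mm,
#'   mean_response, sd_response, n_trials, sd_defined`.
#' @export
summarize_subjects <- function(table) {
  validate_trial_table(table)
  table |>
    dplyr::group_by(.data$subject, .data$condition, .data$size_mm) |>
    dplyr::summarise(
      mean_response = mean(.data$response_mm),
      sd_response = stats::sd(.data$response_mm),
      n_trials = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(sd_defined = .data$n_trials >= 2)
}

#' Response slope and apparent Weber fraction per subject and condition
#'
#' For each subject-by-condition set of per-size summaries, fits two
#' ordinary least-squares lines against object size: the mean response
#' (slope = response slope `k_resp`, the recovered motor-mapping slope) and
#' the response SD (slope = `weber_fraction`, the apparent Weber fraction —
#' the operational read-out of Weber's law in the response).
#'
#' @param summaries Output of [summarize_subjects()] (any subset of
#'   subjects/conditions; each subject-by-condition group needs >= 2
#'   distinct sizes).
#' @return A tibble with one row per subject and condition:
#'   `k_resp, intercept_resp, weber_fraction, intercept_sd, n_sizes`.
#' @examples
#' tab <- generate_fig12_cohort(seed = 1, n_subjects = 3)
#' fit_slopes(summarize_subjects(tab))
#' @export
fit_slopes <- function(summaries) {
  required <- c("subject", "condition", "size_mm", "mean_response",
                "sd_response")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0)
    stop("summaries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  fit_one <- function(d) {
    if (length(unique(d$size_mm)) < 2)
      stop("slope undefined: fewer than 2 distinct sizes for subject ",
           d$subject[1], ", condition ", d$condition[1], call. = FALSE)
    cm <- stats::coef(stats::lm(mean_response ~ size_mm, data = d))
    cs <- stats::coef(stats::lm(sd_response ~ size_mm, data = d))
    tibble::tibble(
      k_resp = unname(cm["size_mm"]),
      intercept_resp = unname(cm["(Intercept)"]),
      weber_fraction = unname(cs["size_mm"]),
      intercept_sd = unname(cs["(Intercept)"]),
      n_sizes = length(unique(d$size_mm)))
  }
  summaries |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::group_modify(~ fit_one(.x |>
      dplyr::mutate(subject = .y$subject, condition = .y$condition))) |>
    dplyr::ungroup()
}

#' Exclude outlier subjects from a summary table
#'
#' A subject is removed if, in any condition-by-size cell, either its mean
#' response or its response SD deviates from the across-subject mean of that
#' cell by at least `z` across-subject SDs. The criterion is evaluated once
#' on the original summaries (no iterative re-exclusion); cells whose
#' across-subject SD is zero are skipped.
#'
#' @param summaries Output of [summarize_subjects()], covering >= 3 subjects.
#' @param z Deviation threshold in across-subject SDs (default 2.5).
#' @return A list with `summaries` (rows for retained subjects only),
#'   `retained` and `excluded` (subject ids), and `report` (per-subject
#'   flag counts).
#' @export
exclude_outlier_subjects <- function(summaries, z = 2.5) {
  required <- c("subject", "condition", "size_mm", "mean_response",
                "sd_response")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0)
    stop("summaries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(unique(summaries$subject)) < 3)
    stop("subject exclusion needs >= 3 subjects", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z <= 0)
    stop("`z` must be a positive number", call. = FALSE)

  long <- summaries |>
    tidyr::pivot_longer(c("mean_response", "sd_response"),
                        names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$condition, .data$size_mm, .data$measure) |>
    dplyr::mutate(
      grand_mean = mean(.data$value),
      grand_sd = stats::sd(.data$value),
      flagged = .data$grand_sd > 0 &
        abs(.data$value - .data$grand_mean) >= z * .data$grand_sd
    ) |>
    dplyr::ungroup()

  report <- long |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_flagged = sum(.data$flagged), .groups = "drop") |>
    dplyr::mutate(excluded = .data$n_flagged > 0)

  excluded <- report$subject[report$excluded]
  list(
    summaries = dplyr::filter(summaries, !(.data$subject %in% excluded)),
    retained = setdiff(unique(summaries$subject), excluded),
    excluded = excluded,
    report = report
  )
}
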