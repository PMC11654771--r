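#' Per-size response moments
#'
#' Collapses raw draws to one row per object size with the sample mean, SD
#' (n - 1), and count — the moments every recovery estimator below works
#' from.
#'
#' @param size_mm Object size per draw (mm).
#' @param response_mm Response per draw (mm).
#' @return A tibble with columns `size_mm, mean_response, sd_response, n`.
#' @export
per_size_moments <- function(size_mm, response_mm) {
  stopifnot(length(size_mm) == length(response_mm))
  tibble::tibble(size_mm = size_mm, response_mm = response_mm) |>
    dplyr::group_by(.data$size_mm) |>
    dplyr::summarise(mean_response = mean(.data$response_mm),
                     sd_response = stats::sd(.data$response_mm),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$size_mm)
}

#' Recover two-stage model parameters from simulated draws
#'
#' Moment-based parameter recovery for one condition:
#' \itemize{
#'   \item the mapping slope `k` and `overshoot` are the OLS line of the
#'     per-size mean response on size;
#'   \item the apparent Weber fraction `weber_fraction` is the OLS slope of
#'     the per-size response SD on size;
#'   \item the implementation noise `sigma_impl` comes from a variance
#'     decomposition: each per-size response variance minus the squared
#'     visual contribution \eqn{(\hat{k} \, W_V \, s)^2} (clamped at zero),
#'     square-rooted and averaged over sizes. This requires the visual
#'     Weber fraction `weber_v` to be known (as it is in simulation
#'     studies).
#' }
#'
#' @param size_mm,response_mm Raw draws (see [per_size_moments()]), or pass
#'   a precomputed moments table via `moments`.
#' @param weber_v Known visual Weber fraction used in the variance
#'   decomposition; `NA` skips the `sigma_impl` estimate.
#' @param moments Optional precomputed [per_size_moments()] table
#'   (overrides the raw draws).
#' @return A list: `k`, `overshoot`, `weber_fraction`, `intercept_sd`,
#'   `sigma_impl` (NA when `weber_v` is), and the `moments` table.
#' @examples
#' set.seed(1)
#' resp <- simulate_responses(rep(c(21, 28, 35, 42), each = 2000),
#'                            fig12_params("MGA"))
#' recover_two_stage(rep(c(21, 28, 35, 42), each = 2000), resp,
#'                   weber_v = 0.06)[c("k", "overshoot", "sigma_impl")]
#' @export
recover_two_stage <- function(size_mm = NULL, response_mm = NULL,
                              weber_v = NA_real_, moments = NULL) {
  if (is.null(moments)) moments <- per_size_moments(size_mm, response_mm)
  if (nrow(moments) < 2)
    stop("parameter recovery needs >= 2 distinct sizes", call. = FALSE)
  cm <- stats::coef(stats::lm(mean_response ~ size_mm, data = moments))
  cs <- stats::coef(stats::lm(sd_response ~ size_mm, data = moments))
  k_hat <- unname(cm["size_mm"])
  sigma_impl <- NA_real_
  if (!is.na(weber_v)) {
    resid_var <- moments$sd_response^2 -
      (k_hat * weber_v * moments$size_mm)^2
    sigma_impl <- mean(sqrt(pmax(resid_var, 0)))
  }
  list(k = k_hat, overshoot = unname(cm["(Intercept)"]),
       weber_fraction = unname(cs["size_mm"]),
       intercept_sd = unname(cs["(Intercept)"]),
       sigma_impl = sigma_impl, moments = moments)
}
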