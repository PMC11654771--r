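#' Parameters of the two-stage visuomotor model
#'
#' Bundles the generative parameters of one feedback condition: the slope and
#' intercept of the linear motor mapping, the implementation (motor-execution)
#' noise added after the mapping, and the Weber fraction of the visual stage.
#' Under this model a response to object size \eqn{s} is
#' \deqn{GA^* = k \hat{s} + \mathrm{overshoot} + \epsilon,\qquad
#'       \hat{s} = s + \epsilon_V,}
#' with \eqn{\epsilon_V \sim N(0, (W_V s)^2)} and
#' \eqn{\epsilon \sim N(0, \sigma_{impl}^2)} independent.
#'
#' @param k Dimensionless slope of the motor mapping; must be finite.
#' @param overshoot Intercept of the mapping in mm (for grasps, the safety
#'   margin by which the aperture exceeds the object).
#' @param sigma_impl Standard deviation of the implementation noise in mm;
#'   must be >= 0.
#' @param weber_v Visual Weber fraction: the SD of the visual estimate is
#'   `weber_v * size`; must be >= 0.
#'
#' @return An object of class `two_stage_params` (a named list).
#' @examples
#' p <- two_stage_params(k = 0.7, overshoot = 18, sigma_impl = 6, weber_v = 0.06)
#' predicted_mean(35, p)
#' predicted_sd(35, p)
#' @export
two_stage_params <- function(k, overshoot, sigma_impl, weber_v) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    stop("`k` must be a single finite number", call. = FALSE)
  if (!is.numeric(overshoot) || length(overshoot) != 1L || !is.finite(overshoot))
    stop("`overshoot` must be a single finite number", call. = FALSE)
  if (!is.numeric(sigma_impl) || length(sigma_impl) != 1L ||
      !is.finite(sigma_impl) || sigma_impl < 0)
    stop("`sigma_impl` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(weber_v) || length(weber_v) != 1L ||
      !is.finite(weber_v) || weber_v < 0)
    stop("`weber_v` must be a single finite number >= 0", call. = FALSE)
  structure(
    list(k = k, overshoot = overshoot, sigma_impl = sigma_impl,
         weber_v = weber_v),
    class = "two_stage_params"
  )
}

#' @export
print.two_stage_params <- function(x, ...) {
  cat(sprintf(
    "Two-stage model parameters:\n  k = %g, overshoot = %g mm, sigma_impl = %g mm, weber_v = %g\n",
    x$k, x$overshoot, x$sigma_impl, x$weber_v))
  invisible(x)
}

#' Serialize two-stage parameters to / from JSON
#'
#' The flat JSON layout is `{k, overshoot_mm, sigma_impl_mm, weber_v}`.
#'
#' @param params A [two_stage_params()] object.
#' @return `params_to_json()` returns a JSON string; `params_from_json()`
#'   returns a `two_stage_params` object.
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "two_stage_params"))
  jsonlite::toJSON(
    list(k = params$k, overshoot_mm = params$overshoot,
         sigma_impl_mm = params$sigma_impl, weber_v = params$weber_v),
    auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  required <- c("k", "overshoot_mm", "sigma_impl_mm", "weber_v")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("JSON params missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  two_stage_params(k = x$k, overshoot = x$overshoot_mm,
                   sigma_impl = x$sigma_impl_mm, weber_v = x$weber_v)
}

#' Draw noisy visual size estimates
#'
#' First stage of the model: the visual estimate of an object of size `s` is
#' unbiased with SD proportional to size (Weber's law),
#' \eqn{\hat{s} = s + \epsilon_V}, \eqn{\epsilon_V \sim N(0, (W_V s)^2)}.
#'
#' Draws consume the current R RNG stream; seed the caller (e.g.
#' `set.seed()`) for reproducibility.
#'
#' @param s Object size(s) in mm; non-negative and finite.
#' @param weber_v Visual Weber fraction (>= 0).
#' @param n Number of draws per element of `s` (draws are vectorized over
#'   `s` when `n = 1`).
#' @return Visual estimates in mm, length `length(s) * n`.
#' @export
visual_estimate <- function(s, weber_v, n = 1L) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("`s` must be finite and >= 0", call. = FALSE)
  if (!is.numeric(weber_v) || length(weber_v) != 1L ||
      !is.finite(weber_v) || weber_v < 0)
    stop("`weber_v` must be a single finite number >= 0", call. = FALSE)
  s_rep <- rep(s, each = n)
  s_rep + stats::rnorm(length(s_rep), mean = 0, sd = weber_v * s_rep)
}

#' Map visual estimates to motor responses
#'
#' Second stage of the model: a linear motor mapping plus implementation
#' noise, \eqn{GA^* = k \hat{s} + \mathrm{overshoot} + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma_{impl}^2)}.
#'
#' @param s_hat Visual estimate(s) in mm (finite).
#' @param params A [two_stage_params()] object.
#' @return Motor responses in mm, same length as `s_hat`.
#' @export
motor_response <- function(s_hat, params) {
  stopifnot(inherits(params, "two_stage_params"))
  if (!is.numeric(s_hat) || any(!is.finite(s_hat)))
    stop("`s_hat` must be finite", call. = FALSE)
  params$k * s_hat + params$overshoot +
    stats::rnorm(length(s_hat), mean = 0, sd = params$sigma_impl)
}

#' Closed-form mean and SD of the two-stage response
#'
#' With independent Gaussian visual and implementation noise, the response at
#' object size `s` has mean \eqn{k s + \mathrm{overshoot}} and standard
#' deviation \eqn{\sqrt{(k W_V s)^2 + \sigma_{impl}^2}}.
#'
#' @param s Object size(s) in mm (>= 0).
#' @param params A [two_stage_params()] object.
#' @return Predicted mean (mm) or SD (mm), vectorized over `s`.
#' @export
predicted_mean <- function(s, params) {
  stopifnot(inherits(params, "two_stage_params"))
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("`s` must be finite", call. = FALSE)
  params$k * s + params$overshoot
}

#' @rdname predicted_mean
#' @export
predicted_sd <- function(s, params) {
  stopifnot(inherits(params, "two_stage_params"))
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("`s` must be finite and >= 0", call. = FALSE)
  sqrt((params$k * params$weber_v * s)^2 + params$sigma_impl^2)
}

#' Simulate full two-stage responses
#'
#' Convenience composition of [visual_estimate()] and [motor_response()]:
#' draws `n` responses at each size in `s`.
#'
#' @inheritParams visual_estimate
#' @param params A [two_stage_params()] object.
#' @return Responses in mm, length `length(s) * n`, grouped by size
#'   (all draws for `s[1]` first, then `s[2]`, ...).
#' @export
simulate_responses <- function(s, params, n = 1L) {
  motor_response(visual_estimate(s, params$weber_v, n = n), params)
}
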