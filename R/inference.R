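#' Paired contrast between two within-subject measures
#'
#' Paired t-test on the within-subject differences `a - b`, with Cohen's d
#' computed as `mean(diff) / sd(diff)`. Identical vectors are the degenerate
#' no-effect case and return a zero contrast; a constant non-zero shift has
#' zero variance of differences and raises an error, since t and d are
#' undefined.
#'
#' @param a,b Numeric vectors of equal length >= 2, paired by subject.
#' @return An object of class `contrast_result`: estimate (mean difference),
#'   se, t, df, p, cohen_d, n.
#' @examples
#' paired_contrast(c(0.10, 0.25, 0.30), c(0.05, 0.10, 0.20))
#' @export
paired_contrast <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  if (length(a) < 2) stop("paired contrast needs n >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) != 0)
      stop("degenerate contrast: differences are a non-zero constant",
           call. = FALSE)
    res <- list(estimate = 0, se = 0, t = 0, df = length(d) - 1L, p = 1,
                cohen_d = 0, n = length(d))
    return(structure(res, class = "contrast_result"))
  }
  tt <- stats::t.test(d)
  structure(
    list(estimate = mean(d), se = stats::sd(d) / sqrt(length(d)),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohen_d = mean(d) / stats::sd(d), n = length(d)),
    class = "contrast_result")
}

#' Independent-groups contrast (Welch t)
#'
#' Welch two-sample t-test on the difference in group means, with Cohen's d
#' standardized by the pooled SD.
#'
#' @param g1,g2 Numeric vectors (each length >= 2) from independent groups.
#' @return A `contrast_result` (estimate = mean(g1) - mean(g2)).
#' @export
group_contrast <- function(g1, g2) {
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  n1 <- length(g1); n2 <- length(g2)
  pooled_var <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
    (n1 + n2 - 2)
  if (pooled_var == 0)
    stop("degenerate contrast: zero pooled variance", call. = FALSE)
  tt <- stats::t.test(g1, g2)
  structure(
    list(estimate = mean(g1) - mean(g2),
         se = sqrt(stats::var(g1) / n1 + stats::var(g2) / n2),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         cohen_d = (mean(g1) - mean(g2)) / sqrt(pooled_var),
         n = c(n1 = n1, n2 = n2)),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "Contrast: estimate = %.4g, t(%.3g) = %.4g, p = %.4g, Cohen's d = %.4g\n",
    x$estimate, mean(x$df), x$t, x$p, x$cohen_d))
  invisible(x)
}

#' Condition effect via a random-intercept model
#'
#' Fits `measure ~ condition + (1 | subject)` with lme4 and reports the
#' type-III Wald chi-square for the condition main effect, per-level
#' coefficients against the reference (first) level, and an eta-squared
#' effect size defined as the condition sum of squares over the total sum of
#' squares of the measure. Subjects with incomplete condition sets are
#' dropped listwise with a warning (recorded in the result).
#'
#' For two balanced conditions the Wald chi-square equals the squared paired
#' t statistic whenever the subject-variance estimate is interior (not on
#' the zero boundary).
#'
#' @param data A data frame with columns `subject`, `condition`, and `value`
#'   (one row per subject and condition).
#' @return An object of class `anova_result`: coefficients (tibble of
#'   level, estimate, se), chisq, df, p, eta_squared, n_subjects,
#'   dropped_subjects.
#' @export
condition_anova <- function(data) {
  required <- c("subject", "condition", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0)
    stop("data missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  conds <- unique(data$condition)
  if (length(conds) < 2) stop("need >= 2 conditions", call. = FALSE)

  counts <- table(data$subject, data$condition)
  complete <- rownames(counts)[apply(counts == 1, 1, all)]
  dropped <- setdiff(unique(as.character(data$subject)), complete)
  if (length(dropped) > 0) {
    warning("dropping subject(s) with incomplete condition sets: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    data <- data[as.character(data$subject) %in% complete, ]
  }
  data$condition <- factor(data$condition)
  data$subject <- factor(data$subject)

  # degenerate no-effect case: every subject identical across conditions
  # (zero residual variance; the mixed model is unfittable, the condition
  # effect is exactly null)
  rng <- tapply(data$value, data$subject,
                function(v) diff(range(v)))
  if (all(rng == 0)) {
    lev <- levels(data$condition)
    return(structure(
      list(coefficients = tibble::tibble(level = lev[-1],
                                         estimate = 0, se = 0),
           reference = lev[1], chisq = 0, df = length(lev) - 1L, p = 1,
           eta_squared = 0,
           n_subjects = length(unique(data$subject)),
           dropped_subjects = dropped),
      class = "anova_result"))
  }

  fit <- lme4::lmer(value ~ condition + (1 | subject), data = data,
                    REML = TRUE)
  aov_tab <- car::Anova(fit, type = "III", test.statistic = "Chisq")
  row <- grep("^condition$", rownames(aov_tab))
  chisq <- aov_tab[row, "Chisq"]
  df <- aov_tab[row, "Df"]
  p <- aov_tab[row, grep("^Pr", colnames(aov_tab))]

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  lev_idx <- grep("^condition", names(fe))
  coefs <- tibble::tibble(
    level = sub("^condition", "", names(fe)[lev_idx]),
    estimate = unname(fe[lev_idx]),
    se = unname(se[lev_idx]))

  grand <- mean(data$value)
  cell <- tapply(data$value, data$condition, mean)
  ncell <- tapply(data$value, data$condition, length)
  ss_cond <- sum(ncell * (cell - grand)^2)
  ss_tot <- sum((data$value - grand)^2)
  eta_sq <- if (ss_tot > 0) ss_cond / ss_tot else 0

  structure(
    list(coefficients = coefs, reference = levels(data$condition)[1],
         chisq = unname(chisq), df = unname(df), p = unname(p),
         eta_squared = eta_sq,
         n_subjects = length(unique(data$subject)),
         dropped_subjects = dropped),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "Condition effect (random-intercept model): Wald chisq(%d) = %.4g, p = %.4g, eta^2 = %.3f\n",
    x$df, x$chisq, x$p, x$eta_squared))
  invisible(x)
}

# log marginal-likelihood ratio integrand of the JZS one-sample test, in the
# g-mixture representation: effect-size prior Cauchy(0, r) is equivalent to
# delta | g ~ N(0, g) with g ~ InvGamma(1/2, r^2/2). The integral over
# g in (0, Inf) is mapped to u in (0, 1) via g = u / (1 - u).
jzs_integrand <- function(u, t, n, df, rscale) {
  g <- u / (1 - u)
  log_h1 <- -0.5 * log1p(n * g) -
    ((df + 1) / 2) * log1p(t^2 / ((1 + n * g) * df)) +
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    rscale^2 / (2 * g)
  log_h0 <- -((df + 1) / 2) * log1p(t^2 / df)
  exp(log_h1 - log_h0) / (1 - u)^2  # Jacobian dg/du
}

#' JZS Bayes factor from a t statistic
#'
#' One-sample Jeffreys-Zellner-Siow Bayes factor for a non-zero mean against
#' the point null, with a zero-centered Cauchy prior (scale `rscale`) on the
#' standardized effect size. Computed by adaptive quadrature on the
#' g-mixture representation of the Cauchy prior, with the half-line mapped
#' to the unit interval; absolute tolerance 1e-8 on the marginal-likelihood
#' ratio.
#'
#' @param t Observed one-sample t statistic.
#' @param n Sample size (>= 2).
#' @param rscale Cauchy prior scale on effect size (default `sqrt(2)/2`).
#' @return An object of class `bayes_result`: bf10, rscale, n, t, and the
#'   quadrature's absolute error estimate.
#' @examples
#' jzs_bf_from_t(t = 3, n = 20)
#' @export
jzs_bf_from_t <- function(t, n, rscale = sqrt(2) / 2) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a single finite number", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (!is.numeric(rscale) || length(rscale) != 1L || rscale <= 0)
    stop("`rscale` must be a single positive number", call. = FALSE)
  df <- n - 1
  quad <- tryCatch(
    stats::integrate(jzs_integrand, 0, 1, t = t, n = n, df = df,
                     rscale = rscale, rel.tol = 1e-10, abs.tol = 1e-10,
                     subdivisions = 1000L),
    error = function(e)
      stop("JZS quadrature failed to converge (t = ", t, ", n = ", n,
           ", rscale = ", rscale, "): ", conditionMessage(e), call. = FALSE))
  structure(
    list(bf10 = quad$value, rscale = rscale, n = n, t = t,
         quad_abs_error = quad$abs.error),
    class = "bayes_result")
}

#' JZS Bayes factor for a sample of per-subject measures
#'
#' Computes the one-sample t statistic of `values` against `null_value` and
#' the corresponding JZS Bayes factor (see [jzs_bf_from_t()]). Used to
#' decide adherence to Weber's law from subjects' apparent Weber fractions.
#'
#' @param values Numeric vector of per-subject measures (n >= 2, non-zero
#'   variance).
#' @param null_value Point null for the mean (default 0).
#' @inheritParams jzs_bf_from_t
#' @return A `bayes_result`.
#' @examples
#' w <- c(0.05, 0.03, 0.06, 0.04, 0.05, 0.07)
#' jzs_bayes_factor(w)
#' @export
jzs_bayes_factor <- function(values, null_value = 0, rscale = sqrt(2) / 2) {
  if (length(values) < 2) stop("`values` needs n >= 2", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("`values` has zero variance; t undefined", call. = FALSE)
  n <- length(values)
  t <- (mean(values) - null_value) / (stats::sd(values) / sqrt(n))
  jzs_bf_from_t(t, n, rscale)
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor: BF10 = %.4g (t = %.4g, n = %d, rscale = %.3f)\n",
              x$bf10, x$t, as.integer(x$n), x$rscale))
  invisible(x)
}

#' Sensitivity of the Bayes factor to the prior scale
#'
#' Recomputes [jzs_bayes_factor()] on the same data across a set of Cauchy
#' prior scales (the conventional sensitivity analysis accompanying a
#' default-prior Bayes factor).
#'
#' @inheritParams jzs_bayes_factor
#' @param rscales Numeric vector of prior scales (non-empty, all > 0).
#' @return A named list of `bayes_result`, one per rscale.
#' @export
rscale_sensitivity <- function(values, null_value = 0,
                               rscales = c(0.5, sqrt(2) / 2, 1.0)) {
  if (length(rscales) == 0)
    stop("`rscales` must be non-empty", call. = FALSE)
  if (any(rscales <= 0)) stop("all rscales must be > 0", call. = FALSE)
  out <- lapply(rscales, function(r)
    jzs_bayes_factor(values, null_value = null_value, rscale = r))
  names(out) <- formatC(rscales, format = "g")
  out
}

#' Classify evidence for or against an effect
#'
#' Maps a Bayes factor onto the conventional three-way evidence label:
#' `present` when bf10 is at least the upper cutoff, `absent` when at most
#' the lower cutoff, `anecdotal` in between (defaults 3 and 1/3).
#'
#' @param bayes A `bayes_result` (or a bare bf10 number).
#' @param lower,upper Evidence cutoffs, `lower < upper`.
#' @return One of `"present"`, `"absent"`, `"anecdotal"`.
#' @export
adherence_decision <- function(bayes, lower = 1 / 3, upper = 3) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper)
    stop("cutoffs must satisfy lower < upper", call. = FALSE)
  bf <- if (inherits(bayes, "bayes_result")) bayes$bf10 else bayes
  if (!is.numeric(bf) || length(bf) != 1L || !is.finite(bf) || bf <= 0)
    stop("bf10 must be a single positive number", call. = FALSE)
  if (bf >= upper) "present" else if (bf <= lower) "absent" else "anecdotal"
}

#' Quadratic curvature of the response-vs-size relation
#'
#' Exploratory metric for nonlinearity of the motor mapping: an OLS
#' quadratic fit of per-size mean response on size, per subject and
#' condition. The sign of the quadratic coefficient labels the mapping
#' convex, concave, or linear within a tolerance around zero.
#'
#' @param summaries Output of [summarize_subjects()]; each subject-by-
#'   condition group needs >= 3 distinct sizes.
#' @param tol Absolute tolerance within which the coefficient is labelled
#'   `linear` (default 1e-8, i.e. only numerically exact linearity).
#' @return A tibble with one row per subject and condition:
#'   `quad_coef` (mm^-1) and `label` in {convex, linear, concave}.
#' @export
convexity_index <- function(summaries, tol = 1e-8) {
  required <- c("subject", "condition", "size_mm", "mean_response")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0)
    stop("summaries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  fit_one <- function(d) {
    if (length(unique(d$size_mm)) < 3)
      stop("convexity undefined: fewer than 3 distinct sizes", call. = FALSE)
    co <- stats::coef(stats::lm(mean_response ~ size_mm + I(size_mm^2),
                                data = d))
    q <- unname(co["I(size_mm^2)"])
    tibble::tibble(
      quad_coef = q,
      label = if (abs(q) <= tol) "linear" else if (q > 0) "convex"
              else "concave")
  }
  summaries |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
}

#' Serialize an inference result to JSON
#'
#' Flattens a `contrast_result`, `anova_result`, or `bayes_result` (or a
#' named list of them) to a JSON string, optionally tagged with provenance
#' fields (input file, filter chain, seed).
#'
#' @param x A result object or named list of result objects.
#' @param provenance Optional named list recorded alongside the statistics.
#' @return A JSON string.
#' @export
result_to_json <- function(x, provenance = NULL) {
  strip <- function(r) {
    if (inherits(r, c("contrast_result", "anova_result", "bayes_result"))) {
      out <- unclass(r)
      out$type <- class(r)[1]
      out
    } else if (is.list(r)) lapply(r, strip) else r
  }
  payload <- strip(x)
  if (!is.null(provenance)) payload <- list(provenance = provenance,
                                            results = payload)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
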