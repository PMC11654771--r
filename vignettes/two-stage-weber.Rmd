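---
title: "A two-stage noise model for visually guided responses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage noise model for visually guided responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webergrasp)
```

## The model and its assumptions

`webergrasp` treats a visually guided response (a maximum grip aperture,
MGA, or a manual size estimate, MSE) as the output of two stages. The
visual stage produces an unbiased estimate of object size whose noise obeys
Weber's law — SD proportional to size, with proportionality constant
`weber_v`, the visual Weber fraction. The motor stage maps the estimate
through a linear function with slope `k` and intercept `overshoot` (for
grasps, the safety margin), then adds implementation noise with constant SD
`sigma_impl`.

The assumptions, all deliberate simplifications:

* both noise sources are Gaussian and independent of one another;
* the mapping is linear (curved mappings are *measured* by
  `convexity_index()`, never generated);
* responses are untruncated — no biomechanical ceiling on aperture and no
  floor at zero. At the sizes and noise levels used here the probability
  mass below zero is negligible, so the Gaussian tails are harmless;
* trial order carries no information except through the optional drift
  generator; the repetition index is bookkeeping, not a serial model.

Under these assumptions the response mean is `k*s + overshoot` and the
response SD is `sqrt((k*weber_v*s)^2 + sigma_impl^2)` (independent noise
adds in quadrature). Those closed forms, exposed as `predicted_mean()` and
`predicted_sd()`, are the oracles against which the Monte-Carlo generator
is tested.

The consequence that motivates the package: the *apparent* Weber fraction —
the OLS slope of response SD on size, the operational test for Weber's law
in this literature — is not `weber_v`. It is attenuated by `k` and diluted
by `sigma_impl`. A useful reference point: for the grasp-like
parameterization (`k = 0.7`, `sigma_impl = 6`) the closed-form SD line over
sizes 21–42 mm has slope 0.0090; for the estimate-like parameterization
(`k = 1`, `sigma_impl = 2`) it is 0.0407 — a four-fold difference from an
identical visual front end.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `weber_v` | — | 0.06 | a typical visual Weber fraction for size estimation |
| `k` (MGA / MSE) | — | 0.7 / 1.0 | compressed grasp mapping vs veridical report |
| `overshoot` (MGA / MSE) | mm | 18 / 4 | grasp safety margin vs small report bias |
| `sigma_impl` (MGA / MSE) | mm | 6 / 2 | motor execution noise, larger for transport-coupled grasps |
| sizes | mm | 21, 28, 35, 42 | four equally spaced graspable heights |
| reps per size, subjects | — | 20, 20 | the reference cohort of the simulation study |
| `between_subject_sd` | mm | 0 | the reference simulation specifies no subject-level variance; set > 0 for realism studies |
| trial / subject exclusion `z` | SD | 2.5 | the conventional screening threshold |
| `rscale` | — | `sqrt(2)/2` | the default Cauchy prior scale for JZS tests |

The defaults *are* the reference study conditions; they are not tuning
knobs, and the acceptance checks run at exactly these values.

## What the generator emulates — and what it does not

`generate_experiment()` reproduces the statistical structure of a
blocked-feedback session: a full factorial of subjects, conditions, sizes
and repetitions; by-subject random intercepts on overshoot (additive,
drawn per subject and condition — mirroring the random-intercept structure
of the analysis models); optional multiplicative slope jitter (off by
default); and an optional, explicitly synthetic drift generator in which
parameters relax exponentially toward per-condition targets
(`p_t = target + (start - target)(1 - rate)^t`) with a `retention` fraction
of the accumulated adaptation carried across block boundaries. The drift
component is an invented stand-in for qualitative trial-by-trial correction
effects; no published equations exist for it and it is disabled by default.

What it does not emulate: reach trajectories, movement time, misses,
apparatus logistics, serial dependencies other than drift, non-Gaussian
heavy tails from tracking artifacts, and ceiling compression at large
apertures. Passing tests therefore certify the pipeline's arithmetic and
its behavior under the model's own assumptions — not that real kinematic
data meet those assumptions.

## Initial processing: choices where the convention is underdetermined

* **Trial exclusion cell.** The 2.5 SD trial rule operates within
  subject × condition × size. Pooling across sizes would systematically
  flag large-object trials (their mean is higher), so the per-cell reading
  is adopted. Cells with fewer than 3 trials are passed through and
  flagged; zero-SD cells remove nothing.
* **Subject exclusion** is a single pass on the original summaries: a
  subject is dropped if *any* of its per-cell means or SDs deviates by at
  least 2.5 across-subject SDs from that cell's across-subject mean.
  Zero-variance cells are skipped. No iterative re-exclusion. Note that on
  perfectly Gaussian simulated cohorts of 20 subjects this rule still
  excludes a couple of subjects per cohort — a base rate inherent to
  applying a fixed-z screen to ~32 cells per subject, worth remembering
  when counting expected output rows (`subject_z = Inf` disables the rule).
* **SDs** use the n − 1 denominator throughout.
* **Slope fits** are plain OLS of mean and SD on size: with four size
  levels, robust alternatives have nothing to work with, and OLS matches
  standard practice.
* The block-transition prescreen (`drop_initial_repetitions()`) removes
  repetitions 1..n within each subject × block × size; the default in
  `run_config()` is 0 because only designs with abrupt feedback changes
  need it (there, 2 is the conventional choice).

## Inference layer

`paired_contrast()` and `group_contrast()` wrap the classical t-tests with
Cohen's d (paired: mean over SD of differences; independent: pooled-SD
standardization). Identical paired vectors return a zero contrast rather
than an error; a constant non-zero shift (zero-variance differences) is a
degenerate error, since t is undefined.

`condition_anova()` fits `value ~ condition + (1 | subject)` with lme4 and
reports the type-III Wald chi-square (via `car::Anova`). Eta-squared is
defined as the condition sum of squares over the total sum of squares of
the measure — a fixed-effects decomposition chosen for comparability
across implementations. For two balanced conditions the Wald chi-square
equals the squared paired-t statistic whenever the subject-variance
estimate is interior; the degenerate all-conditions-identical case is
short-circuited to a null result before lme4 sees it (zero residual
variance is unfittable). Wald chi-square tests are mildly anticonservative
at small n (the chi-square reference ignores the t-distribution's tails);
the calibration test uses a 30-subject null cohort — the size of the
larger empirical samples this design targets — where the empirical
rejection rate at α = 0.05 sits near 0.06.

### The JZS Bayes factor

The one-sample Jeffreys–Zellner–Siow Bayes factor uses a zero-centered
Cauchy prior with scale `rscale` on the standardized effect size. The
implementation integrates the g-mixture representation (Cauchy = scale
mixture of normals with inverse-gamma mixing): the marginal likelihood
ratio is a one-dimensional integral over g ∈ (0, ∞), mapped to the unit
interval by `g = u/(1 − u)` and evaluated with adaptive quadrature
(`stats::integrate`, absolute tolerance 1e−10 on the ratio, i.e. well
inside the 1e−8 target on the marginals; the integrand is computed in log
space and exponentiated against the null likelihood for stability). The
test suite verifies it against an independent route — integrating the
noncentral-t density against the Cauchy prior on effect size — to 1e−6
relative error over a grid of n ∈ {5, 20, 50}, t ∈ [−5, 5], and all three
conventional prior scales.

The default `rscale` is `sqrt(2)/2` ≈ 0.707, the conventional default;
0.717 (a value that appears in parts of this literature, most plausibly as
a typo for `sqrt(2)/2`) is selectable and never silently corrected.
`rscale_sensitivity()` sweeps {0.5, 0.707, 1.0}. `adherence_decision()`
maps BF₁₀ to present / anecdotal / absent at cutoffs 3 and 1/3 (boundary
values inclusive).

## Numerical and I/O details

* All randomness flows through R's global RNG; every stochastic entry
  point takes a `seed` argument, so any output is a deterministic function
  of (arguments, seed).
* Trial CSVs are written by readr at full (shortest round-trippable)
  precision. On reading, the double columns are parsed with base R's
  strtod, which is correctly rounded — written tables round-trip to
  bit-identical files.
* The variance-decomposition recovery of `sigma_impl`
  (`recover_two_stage()`) clamps negative per-size residual variances at
  zero before the square root; at the simulation sizes used this clamp is
  inactive, but it keeps the estimator defined at small n.
* Problem sizes: the test suite uses 10⁵ draws per size for closed-form
  agreement (Monte-Carlo SE of an SD ≈ 0.22% there, against a 1% band),
  100 replicate cohorts for the dissociation study, and 1,000 null
  simulations for test calibration — large enough that the checked bands
  are statistically comfortable, small enough to run routinely.

## Known limitations

* The mixed-model layer covers exactly the balanced random-intercept
  design the analyses need; there is no Satterthwaite machinery, no random
  slopes, and unbalanced data are handled by listwise deletion with a
  warning.
* The drift generator is a synthetic device for robustness studies; its
  rate and retention parameters have no empirical calibration.
* Nothing here analyzes raw trajectories; the package starts at the trial
  table (one landmark response per trial).
* The model's Gaussian, untruncated noise means extreme parameter choices
  (e.g. `weber_v` > ~0.3 at small sizes) can generate physically
  implausible negative responses; the screening rules do not guard against
  deliberately absurd parameterizations.
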