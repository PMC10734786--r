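#' Normal model of test-minus-reference PWV differences
#'
#' Constructs the normative probability model used for device grading: the
#' per-participant mean differences between a device under test and a
#' reference device are modelled as Normal(`mean_diff`, `sd_diff`^2), in m/s.
#' The tolerable-error criterion is two-sided and symmetric, so the sign of
#' `mean_diff` never affects a grade.
#'
#' @param mean_diff Signed mean difference (test minus reference), m/s.
#' @param sd_diff Standard deviation of per-participant mean differences,
#'   m/s; must be non-negative.
#' @return An object of class `difference_model`.
#' @examples
#' difference_model(0.36, 0.44)
#' @export
difference_model <- function(mean_diff, sd_diff) {
  if (!is.numeric(mean_diff) || length(mean_diff) != 1L || !is.finite(mean_diff))
    stop("`mean_diff` must be a single finite number (m/s)", call. = FALSE)
  if (!is.numeric(sd_diff) || length(sd_diff) != 1L || !is.finite(sd_diff) ||
      sd_diff < 0)
    stop("`sd_diff` must be a single non-negative number (m/s)", call. = FALSE)
  structure(list(mean_diff = as.numeric(mean_diff),
                 sd_diff = as.numeric(sd_diff)),
            class = "difference_model")
}

#' @export
print.difference_model <- function(x, ...) {
  cat(sprintf("Difference model: Normal(mean = %.3f, SD = %.3f) m/s\n",
              x$mean_diff, x$sd_diff))
  invisible(x)
}

as_difference_model <- function(x, sd_diff = NULL) {
  if (inherits(x, "difference_model")) return(x)
  difference_model(x, sd_diff)
}

## P(|D| <= E) for D ~ Normal(mu, sd^2)
abs_coverage <- function(E, mu, sd) {
  stats::pnorm((E - mu) / sd) - stats::pnorm((-E - mu) / sd)
}

#' Symmetric error bound containing a given probability mass
#'
#' Solves for the error magnitude `E` such that `P(|D| <= E) = probability`
#' when differences D follow the normal model. This is the "tolerable error"
#' calculus: at the default probability 0.85, a device is expected to read
#' within +/- E m/s of the reference in 85% of validation measurements.
#'
#' The root is found by bracketing bisection on `[0, |mean| + 10 sd]` to an
#' absolute tolerance of 1e-6 m/s; the bound is symmetric in the sign of the
#' mean. With `sd_diff = 0` the distribution is degenerate at the mean and the
#' bound collapses to `|mean_diff|` (the degenerate limit).
#'
#' @param model A [difference_model()], or a numeric mean (with `sd_diff`).
#' @param probability Target probability mass, strictly inside (0, 1).
#' @param sd_diff SD, only used when `model` is given as a bare mean.
#' @param tol Absolute bisection tolerance, m/s.
#' @return Error bound E >= 0, m/s.
#' @examples
#' error_at_probability(difference_model(0.40, 0.45), 0.85) # ~0.871
#' @export
error_at_probability <- function(model, probability = 0.85, sd_diff = NULL,
                                 tol = 1e-6) {
  model <- as_difference_model(model, sd_diff)
  if (!is.numeric(probability) || length(probability) != 1L ||
      !is.finite(probability) || probability <= 0 || probability >= 1)
    stop("`probability` must lie strictly within (0, 1)", call. = FALSE)
  mu <- model$mean_diff
  sd <- model$sd_diff
  if (sd == 0) return(abs(mu))  # degenerate limit: all mass at mu
  lo <- 0
  hi <- abs(mu) + 10 * sd
  while (abs_coverage(hi, mu, sd) < probability) hi <- hi * 2  # safety bracket
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (abs_coverage(mid, mu, sd) < probability) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Largest acceptable SD of the difference for a given error bound
#'
#' Inverse of [error_at_probability()] in the SD argument: the largest
#' `sd_diff` such that the symmetric bound containing `probability` mass does
#' not exceed `error_max`. This is the quantity tabulated against the mean
#' difference in acceptable-SD cutoff tables.
#'
#' @param mean_diff Mean difference, m/s; must satisfy
#'   `|mean_diff| < error_max` (otherwise no positive SD can satisfy the
#'   bound and an infeasible-mean error is signalled).
#' @param error_max Error bound to respect, m/s (1.0 for good, 1.5 for
#'   acceptable performance).
#' @param probability Probability mass, default 0.85.
#' @param tol Absolute bisection tolerance, m/s.
#' @return Maximal SD, m/s.
#' @examples
#' max_sd_for_error(0, 1.0)     # 1 / qnorm(0.925) ~ 0.695
#' max_sd_for_error(0.40, 0.88) # ~0.455 (inverse of the worked example)
#' @export
max_sd_for_error <- function(mean_diff, error_max, probability = 0.85,
                             tol = 1e-6) {
  if (!is.numeric(mean_diff) || length(mean_diff) != 1L || !is.finite(mean_diff))
    stop("`mean_diff` must be a single finite number", call. = FALSE)
  if (!is.numeric(error_max) || length(error_max) != 1L || error_max <= 0)
    stop("`error_max` must be a single positive number", call. = FALSE)
  if (abs(mean_diff) >= error_max)
    stop(sprintf(
      "infeasible mean: |mean_diff| = %.3f m/s >= error bound %.3f m/s; no SD can satisfy the criterion",
      abs(mean_diff), error_max), call. = FALSE)
  mu <- mean_diff
  ## coverage of [-error_max, error_max] decreases monotonically in sd
  lo <- 0
  hi <- error_max
  while (abs_coverage(error_max, mu, hi) > probability) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (abs_coverage(error_max, mu, mid) > probability) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Round a non-negative value up to a grid
#'
#' Conservative rounding used before grading and table lookup: the smallest
#' integer multiple of `grid` that is greater than or equal to `value`.
#' Exact multiples (to numerical tolerance) are returned unchanged, e.g.
#' 0.41 -> 0.45, 0.47 -> 0.50, 0.45 -> 0.45 on the default 0.05 m/s grid.
#'
#' @param value Non-negative value, m/s. Take the absolute value upstream for
#'   signed means; negative input is a domain error.
#' @param grid Grid spacing, m/s; default 0.05.
#' @return Rounded value, m/s.
#' @export
round_up_to_grid <- function(value, grid = 0.05) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0))
    stop("`value` must be non-negative; take abs() of a signed mean first",
         call. = FALSE)
  if (!is.numeric(grid) || length(grid) != 1L || grid <= 0)
    stop("`grid` must be a single positive number", call. = FALSE)
  ## tolerance so that exact multiples stored in binary stay unchanged
  grid * ceiling(value / grid - 1e-9)
}

## conservative 2-decimal display rounding (ceiling at 0.01), the convention
## used for tabulated error values: the printed bound never understates the
## error actually containing 85% of differences
ceil2 <- function(x) ceiling(x * 100 - 1e-9) / 100

#' Grade a PWV device from its difference model
#'
#' Applies the full grading convention: the absolute mean difference and the
#' SD are each rounded up to 0.05 m/s precision, the symmetric 85% error
#' bound (`error85`) is computed for the rounded model, and the grade is
#' assigned by the tolerable-error thresholds: "good" if `error85 <= 1.0`
#' m/s, "acceptable" if `1.0 < error85 <= 1.5` m/s, otherwise "fail".
#'
#' Grading uses the full-precision bound; `error85_display` carries the
#' conservatively rounded 2-decimal value used in reports and tables (for the
#' worked example mean 0.36, SD 0.44 this is 0.88 m/s).
#'
#' @param model A [difference_model()], or a numeric mean (with `sd_diff`).
#' @param sd_diff SD, only used when `model` is a bare mean.
#' @param probability Probability mass defining the bound, default 0.85.
#' @param grid Rounding grid, m/s.
#' @param thresholds Numeric of length 2: good / acceptable error bounds, m/s.
#' @return An object of class `grading_result`: a list with `rounded_mean`,
#'   `rounded_sd`, `error85` (full precision), `error85_display`, `grade`.
#' @examples
#' grade_device(difference_model(0.36, 0.44))
#' @export
grade_device <- function(model, sd_diff = NULL, probability = 0.85,
                         grid = 0.05, thresholds = c(good = 1.0, acceptable = 1.5)) {
  model <- as_difference_model(model, sd_diff)
  rounded_mean <- round_up_to_grid(abs(model$mean_diff), grid)
  rounded_sd <- round_up_to_grid(model$sd_diff, grid)
  rounded <- difference_model(rounded_mean, rounded_sd)
  error85 <- error_at_probability(rounded, probability)
  grade <- if (error85 <= thresholds[[1L]]) "good"
           else if (error85 <= thresholds[[2L]]) "acceptable"
           else "fail"
  structure(list(rounded_mean = rounded_mean,
                 rounded_sd = rounded_sd,
                 error85 = error85,
                 error85_display = ceil2(error85),
                 grade = grade,
                 probability = probability),
            class = "grading_result")
}

#' @export
print.grading_result <- function(x, ...) {
  cat(sprintf(
    "Device grading (%.0f%% tolerable-error criterion)\n", 100 * x$probability))
  cat(sprintf("  rounded |mean difference|: %.2f m/s\n", x$rounded_mean))
  cat(sprintf("  rounded SD of difference:  %.2f m/s\n", x$rounded_sd))
  cat(sprintf("  error85: %.2f m/s\n", x$error85_display))
  cat(sprintf("  grade:   %s\n", x$grade))
  invisible(x)
}

#' Acceptable-SD cutoff table
#'
#' For a grid of mean differences, tabulates the largest SD of the difference
#' compatible with each error bound (1.0 m/s "good" and 1.5 m/s "acceptable"
#' by default). Means at or beyond a bound are infeasible for that bound: the
#' cell is `NA` and flagged in the corresponding `*_feasible` column rather
#' than dropped.
#'
#' @param mean_grid Non-negative mean differences, m/s.
#' @param error_maxes Error bounds, m/s; default `c(1.0, 1.5)`.
#' @param probability Probability mass, default 0.85.
#' @return Data frame with columns `mean_diff`, `max_sd_good`,
#'   `max_sd_acceptable` (for the default bounds) and logical feasibility
#'   flags.
#' @examples
#' head(generate_cutoff_table(seq(0, 0.95, by = 0.05)))
#' @export
generate_cutoff_table <- function(mean_grid = seq(0, 0.95, by = 0.05),
                                  error_maxes = c(good = 1.0, acceptable = 1.5),
                                  probability = 0.85) {
  if (any(mean_grid < 0)) stop("`mean_grid` must be non-negative", call. = FALSE)
  nm <- names(error_maxes)
  if (is.null(nm)) nm <- paste0("bound", seq_along(error_maxes))
  out <- data.frame(mean_diff = mean_grid)
  for (j in seq_along(error_maxes)) {
    e <- error_maxes[[j]]
    sds <- vapply(mean_grid, function(m) {
      if (m >= e) NA_real_ else max_sd_for_error(m, e, probability)
    }, numeric(1))
    out[[paste0("max_sd_", nm[j])]] <- sds
    out[[paste0(nm[j], "_feasible")]] <- !is.na(sds)
  }
  out
}

#' Margin of error of an observed tolerable-error proportion
#'
#' Normal-approximation (Wald) half-width of the binomial confidence interval
#' for a proportion `p` observed in `n` participants, in percentage points:
#' `100 * z * sqrt(p (1 - p) / n)` with `z` the `(1 + confidence)/2` standard
#' normal quantile. The Wald form is the normative default; a Wilson-score
#' half-width is available as a non-default alternative.
#'
#' @param n Number of participants in the analysis.
#' @param p Proportion (fraction in (0, 1)), e.g. 0.85.
#' @param confidence Confidence level (fraction in (0, 1)), e.g. 0.90.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Margin of error in percentage points.
#' @examples
#' margin_of_error(85, 0.85, 0.90) # ~6.37, below the 7-point design margin
#' @export
margin_of_error <- function(n, p, confidence = 0.90,
                            method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly within (0, 1)", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("`confidence` must lie strictly within (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + confidence) / 2)
  if (method == "wald") {
    100 * z * sqrt(p * (1 - p) / n)
  } else {
    ## Wilson-score interval half-width
    denom <- 1 + z^2 / n
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    100 * half
  }
}

#' Assured lower bound on the probability of tolerable error
#'
#' The lowest true probability of tolerable error compatible (at the given
#' confidence) with an observed proportion `p` in `n` participants:
#' `100 p` minus the [margin_of_error()]. At the recommended design point
#' (n = 85, p = 0.85, 90% confidence) this exceeds 78%.
#'
#' @inheritParams margin_of_error
#' @return Lower bound in percent.
#' @examples
#' assured_lower_bound(85, 0.85, 0.90) # ~78.6
#' @export
assured_lower_bound <- function(n, p, confidence = 0.90,
                                method = c("wald", "wilson")) {
  100 * p - margin_of_error(n, p, confidence, method)
}

#' Sample-size plan for a validation study
#'
#' Bundles the recommended design: at least `n_analysis` participants with
#' complete data (default 85), enrolling `n_enroll` (default 90) to absorb
#' dropout, with the margin of error and assured lower bound implied by the
#' target probability and confidence.
#'
#' @param n_analysis Participants with complete data, default 85.
#' @param n_enroll Participants to enrol, default 90; must be >= `n_analysis`.
#' @param target_probability Target probability of tolerable error, default 0.85.
#' @param confidence Confidence level, default 0.90.
#' @return An object of class `sample_size_plan`.
#' @export
sample_size_plan <- function(n_analysis = 85, n_enroll = 90,
                             target_probability = 0.85, confidence = 0.90) {
  if (n_enroll < n_analysis)
    stop("`n_enroll` must be at least `n_analysis`", call. = FALSE)
  margin <- margin_of_error(n_analysis, target_probability, confidence)
  structure(list(n_analysis = n_analysis,
                 n_enroll = n_enroll,
                 target_probability = target_probability,
                 confidence = confidence,
                 margin = margin,
                 lower_bound = 100 * target_probability - margin),
            class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat("Validation sample-size plan\n")
  cat(sprintf("  analysis n: %d (enrol %d)\n", x$n_analysis, x$n_enroll))
  cat(sprintf("  target probability of tolerable error: %.0f%%\n",
              100 * x$target_probability))
  cat(sprintf("  %.0f%% confidence margin of error: %.1f points\n",
              100 * x$confidence, x$margin))
  cat(sprintf("  assured lower bound: %.1f%%\n", x$lower_bound))
  invisible(x)
}
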