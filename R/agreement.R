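#' Cohort-level agreement summary with Bland-Altman statistics
#'
#' Aggregates per-participant mean differences into the cohort agreement
#' summary on which the device is graded: mean difference, SD of the
#' difference (sample SD, n-1 denominator), limits of agreement (mean -/+ 2
#' SD exactly, as prescribed for reporting), and the Bland-Altman regression
#' of participant mean difference on participant mean average (ordinary least
#' squares; two-sided t test on the slope). Grading delegates to
#' [grade_device()].
#'
#' @param paired A list of `paired_differences` objects (one per
#'   participant), from [pair_session()].
#' @param probability Probability mass defining the tolerable-error bound.
#' @return Object of class `agreement_summary` with fields `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ba_regression` (slope, intercept,
#'   r_squared, p_value) and `grading`.
#' @export
summarize_agreement <- function(paired, probability = 0.85) {
  stopifnot(is.list(paired))
  if (length(paired) < 2L)
    stop("at least 2 participants are required to summarize agreement",
         call. = FALSE)
  d <- vapply(paired, function(p) p$participant_mean_difference, numeric(1))
  a <- vapply(paired, function(p) p$participant_mean_average, numeric(1))
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  if (stats::var(d) < 1e-24) {
    ## degenerate: constant differences fit the intercept exactly; the slope
    ## is 0 and its test is undefined
    cf <- c(mean_diff, 0)
    r_squared <- 0
    slope_p <- NA_real_
  } else {
    fit <- stats::lm(d ~ a)
    cf <- stats::coef(fit)
    sm <- summary(fit)
    r_squared <- sm$r.squared
    slope_p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  }
  structure(list(n = length(paired),
                 participant_ids = vapply(paired, function(p) as.character(p$participant_id), character(1)),
                 mean_diff = mean_diff,
                 sd_diff = sd_diff,
                 loa_low = mean_diff - 2 * sd_diff,
                 loa_high = mean_diff + 2 * sd_diff,
                 ba_regression = list(slope = unname(cf[2L]),
                                      intercept = unname(cf[1L]),
                                      r_squared = r_squared,
                                      p_value = slope_p),
                 differences = d,
                 averages = a,
                 grading = grade_device(difference_model(mean_diff, sd_diff),
                                        probability = probability)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement summary (n = %d participants)\n", x$n))
  cat(sprintf("  mean difference: %.3f m/s, SD: %.3f m/s\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement: [%.3f, %.3f] m/s\n", x$loa_low, x$loa_high))
  cat(sprintf("  BA regression: diff = %.3f + %.3f * avg (R^2 = %.3f, p = %.3g)\n",
              x$ba_regression$intercept, x$ba_regression$slope,
              x$ba_regression$r_squared, x$ba_regression$p_value))
  cat(sprintf("  grade: %s (error85 = %.2f m/s)\n", x$grading$grade,
              x$grading$error85_display))
  invisible(x)
}

#' Stratified agreement analysis
#'
#' Repeats [summarize_agreement()] within strata: by sex, by age band (<30,
#' 30-49, 50-69, >=70 years) or by vasoactive drug use. Strata with fewer
#' than 2 participants are reported as not estimable rather than dropped.
#'
#' @param paired List of `paired_differences`.
#' @param cohort Participant data frame carrying `id` plus the stratum
#'   variables (`sex`, `age`, `vasoactive_meds`).
#' @param stratum One of `"sex"`, `"age_band"`, `"vasoactive_drug_use"`.
#' @param probability Probability mass for grading.
#' @return A list with one element per stratum level: either an
#'   `agreement_summary` or a marker list with `estimable = FALSE` and the
#'   stratum `n`.
#' @export
stratified_agreement <- function(paired, cohort,
                                 stratum = c("sex", "age_band", "vasoactive_drug_use"),
                                 probability = 0.85) {
  stratum <- match.arg(stratum)
  ids <- vapply(paired, function(p) as.character(p$participant_id), character(1))
  pos <- match(ids, as.character(cohort$id))
  if (anyNA(pos))
    stop("cohort is missing demographic rows for participants: ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  labels <- switch(stratum,
    sex = as.character(cohort$sex[pos]),
    age_band = as.character(age_band(cohort$age[pos])),
    vasoactive_drug_use = ifelse(cohort$vasoactive_meds[pos], "vasoactive", "none"))
  if (anyNA(labels))
    stop("stratum labels must be present for every participant", call. = FALSE)
  levels_all <- switch(stratum,
    sex = c("male", "female"),
    age_band = age_band_levels(),
    vasoactive_drug_use = c("vasoactive", "none"))
  out <- lapply(levels_all, function(lv) {
    sel <- paired[labels == lv]
    if (length(sel) < 2L) {
      list(stratum = lv, n = length(sel), estimable = FALSE)
    } else {
      s <- summarize_agreement(sel, probability)
      s$stratum <- lv
      s$estimable <- TRUE
      s
    }
  })
  names(out) <- levels_all
  out
}

#' Coefficient of variation of two repeated measurements
#'
#' Precision metric for a pair of same-device measurements: the sample SD of
#' the two values (n-1 denominator, i.e. `|m1 - m2| / sqrt(2)`) divided by
#' their average, in percent.
#'
#' @param m1,m2 Two positive PWV measurements, m/s.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(8, 10) # ~15.71
#' @export
coefficient_of_variation <- function(m1, m2) {
  if (any(!is.finite(c(m1, m2))) || any(c(m1, m2) <= 0))
    stop("measurements must be positive", call. = FALSE)
  100 * (abs(m1 - m2) / sqrt(2)) / ((m1 + m2) / 2)
}

#' Test-retest precision report
#'
#' Bland-Altman analysis of repeated same-device measurements against a
#' predefined clinical agreement limit (default 1.0 m/s, the minimum
#' clinically important difference), with per-participant coefficient of
#' variation. Participants with fewer than two repeats are excluded with a
#' logged reason.
#'
#' @param repeats Data frame with columns `participant_id`, `pwv`; the first
#'   two readings per participant are used.
#' @param agreement_limit Predefined clinical limit for the absolute repeat
#'   difference, m/s.
#' @return Object of class `test_retest_report`: per-participant table
#'   (differences, CVs, exceed-limit flags), `mean_diff`, `sd_diff`, limits
#'   of agreement, `mean_cv`, and `excluded` (ids + reasons).
#' @export
test_retest_report <- function(repeats, agreement_limit = 1.0) {
  stopifnot(is.data.frame(repeats), all(c("participant_id", "pwv") %in% names(repeats)))
  split_by <- split(repeats$pwv, repeats$participant_id)
  counts <- vapply(split_by, length, integer(1))
  excluded <- data.frame(participant_id = names(split_by)[counts < 2L],
                         reason = rep("fewer than 2 repeated measurements",
                                      sum(counts < 2L)))
  keep <- names(split_by)[counts >= 2L]
  if (length(keep) == 0L)
    stop("no participant has 2 repeated measurements", call. = FALSE)
  tab <- do.call(rbind, lapply(keep, function(id) {
    v <- split_by[[id]][1:2]
    data.frame(participant_id = id,
               m1 = v[1], m2 = v[2],
               difference = v[1] - v[2],
               average = mean(v),
               cv_percent = coefficient_of_variation(v[1], v[2]))
  }))
  tab$exceeds_limit <- abs(tab$difference) > agreement_limit
  mean_diff <- mean(tab$difference)
  sd_diff <- if (nrow(tab) >= 2L) stats::sd(tab$difference) else 0
  structure(list(per_participant = tab,
                 n = nrow(tab),
                 mean_diff = mean_diff,
                 sd_diff = sd_diff,
                 loa_low = mean_diff - 2 * sd_diff,
                 loa_high = mean_diff + 2 * sd_diff,
                 mean_abs_diff = mean(abs(tab$difference)),
                 mean_cv = mean(tab$cv_percent),
                 agreement_limit = agreement_limit,
                 n_exceeding_limit = sum(tab$exceeds_limit),
                 excluded = excluded),
            class = "test_retest_report")
}

#' @export
print.test_retest_report <- function(x, ...) {
  cat(sprintf("Test-retest precision (n = %d participants)\n", x$n))
  cat(sprintf("  repeat bias %.3f m/s, SD %.3f m/s; mean CV %.2f%%\n",
              x$mean_diff, x$sd_diff, x$mean_cv))
  cat(sprintf("  %d participant(s) exceed the %.1f m/s agreement limit; %d excluded\n",
              x$n_exceeding_limit, x$agreement_limit, nrow(x$excluded)))
  invisible(x)
}
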