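#' Age bands of the validation protocol
#'
#' The cohort-composition rules work on four age bands: <30, 30-49, 50-69
#' and >=70 years, interpreted half-open on integer ages: [18,30), [30,50),
#' [50,70), [70, Inf). Participants under 18 are ineligible and receive `NA`.
#'
#' @param age Age(s) in years.
#' @return Factor with the four band levels.
#' @export
age_band <- function(age) {
  cut(ifelse(age < 18, NA_real_, age),
      breaks = c(18, 30, 50, 70, Inf), right = FALSE,
      labels = age_band_levels())
}

age_band_levels <- function() c("<30", "30-49", "50-69", ">=70")

participant_fields <- c("id", "age", "sex", "bmi", "rhythm", "vasoactive_meds",
                        "time_since_dose_h", "relevant_stenosis",
                        "severe_aortic_stenosis", "palpable_arteries")

#' Participant eligibility for a validation study
#'
#' Applies the selection criteria: adults only (>= 18 years), BMI below 40
#' kg/m2 (the >= 40 boundary is exclusionary because path length cannot be
#' measured reliably), sinus rhythm and not pacemaker dependent, no clinically
#' relevant stenosis between the measurement sites, no severe aortic valve
#' stenosis, palpable arteries, and no measurement inside the acute-effect
#' window after vasoactive dosing (default window 24 h, configurable; users
#' of vasoactive medication are not excluded per se).
#'
#' @param record One participant: a named list or one-row data frame with
#'   fields `id`, `age`, `sex`, `bmi`, `rhythm` (one of sinus/afib/paced/
#'   other), `vasoactive_meds` (logical), `time_since_dose_h`,
#'   `relevant_stenosis`, `severe_aortic_stenosis`, `palpable_arteries`.
#'   Missing fields raise an incomplete-record error, never a silent pass.
#' @param vasoactive_window_h Acute-effect window after dosing, hours.
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   failed rules, empty when eligible).
#' @export
check_eligibility <- function(record, vasoactive_window_h = 24) {
  record <- as.list(record)
  missing_fields <- setdiff(participant_fields, names(record))
  ## dose timing only needs to be known for medication users
  if ("vasoactive_meds" %in% names(record) && isFALSE(record$vasoactive_meds))
    missing_fields <- setdiff(missing_fields, "time_since_dose_h")
  if (length(missing_fields) > 0L)
    stop("incomplete participant record (missing: ",
         paste(missing_fields, collapse = ", "), ")", call. = FALSE)
  reasons <- character(0)
  if (is.na(record$age) || record$age < 18)
    reasons <- c(reasons, "age below 18 years")
  if (is.na(record$bmi) || record$bmi >= 40)
    reasons <- c(reasons, "BMI >= 40 kg/m2")
  if (is.na(record$rhythm) || record$rhythm != "sinus")
    reasons <- c(reasons, "not in sinus rhythm / pacemaker dependent")
  if (isTRUE(record$relevant_stenosis))
    reasons <- c(reasons, "relevant arterial stenosis between measurement sites")
  if (isTRUE(record$severe_aortic_stenosis))
    reasons <- c(reasons, "severe aortic valve stenosis")
  if (!isTRUE(record$palpable_arteries))
    reasons <- c(reasons, "relevant arteries not palpable")
  if (isTRUE(record$vasoactive_meds)) {
    tsd <- record$time_since_dose_h
    if (is.null(tsd) || is.na(tsd) || tsd < vasoactive_window_h)
      reasons <- c(reasons,
                   sprintf("measurement within %g h of vasoactive dosing",
                           vasoactive_window_h))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Cohort composition check against the protocol quotas
#'
#' Verifies that an analysis cohort supports a valid cfPWV device validation:
#' at least 85 participants with complete data out of at least 90 enrolled;
#' reference PWV spread quotas (>=5% of values <= 6 m/s, >=5% >= 10 m/s,
#' >=20% >= 8 m/s, cutoffs multiplied by `scale_factor` for other arterial
#' beds); all four age bands occupied by >= 10 participants; and >= 40% men
#' and >= 40% women within every band. Violations are reported, never used
#' to stop the analysis. A non-failing evenness ratio (smallest/largest band
#' count) is included descriptively.
#'
#' @param cohort Participant data frame with `id`, `age`, `sex`,
#'   `reference_pwv` and optionally a logical `complete` column (default all
#'   complete).
#' @param scale_factor Multiplier applied to the 6/8/10 m/s PWV cutoffs for
#'   arterial beds other than carotid-femoral; 1 for cfPWV.
#' @param n_enrolled Number enrolled; defaults to the cohort's `n_enrolled`
#'   attribute, else `nrow(cohort)`.
#' @param pwv_values Optional vector of individual reference readings; by
#'   default the participant-level `reference_pwv` means are used for the
#'   distribution quotas (per-reading mode is selected by supplying the
#'   readings).
#' @return Object of class `composition_report`: counts, per-band sex
#'   fractions, PWV distribution fractions, `evenness_ratio` and a
#'   `violations` data frame (`rule_id`, `observed`, `required`).
#' @export
check_composition <- function(cohort, scale_factor = 1, n_enrolled = NULL,
                              pwv_values = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  req <- c("id", "age", "sex", "reference_pwv")
  if (!all(req %in% names(cohort)))
    stop("cohort must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (is.null(n_enrolled))
    n_enrolled <- attr(cohort, "n_enrolled") %||% nrow(cohort)
  complete <- if ("complete" %in% names(cohort)) cohort$complete else rep(TRUE, nrow(cohort))
  n_complete <- sum(complete)
  cc <- cohort[complete, , drop = FALSE]
  if (is.null(pwv_values)) pwv_values <- cc$reference_pwv

  violations <- list()
  add_violation <- function(rule_id, observed, required) {
    violations[[length(violations) + 1L]] <<-
      data.frame(rule_id = rule_id, observed = observed, required = required)
  }
  if (n_complete < 85) add_violation("n_complete >= 85", n_complete, 85)
  if (n_enrolled < 90) add_violation("n_enrolled >= 90", n_enrolled, 90)

  lo <- 6 * scale_factor; mid <- 8 * scale_factor; hi <- 10 * scale_factor
  frac_low <- mean(pwv_values <= lo)
  frac_mid <- mean(pwv_values >= mid)
  frac_high <- mean(pwv_values >= hi)
  if (frac_low < 0.05)
    add_violation(sprintf("PWV <= %g m/s in >= 5%%", lo), 100 * frac_low, 5)
  if (frac_high < 0.05)
    add_violation(sprintf("PWV >= %g m/s in >= 5%%", hi), 100 * frac_high, 5)
  if (frac_mid < 0.20)
    add_violation(sprintf("PWV >= %g m/s in >= 20%%", mid), 100 * frac_mid, 20)

  bands <- age_band(cc$age)
  band_counts <- table(factor(bands, levels = age_band_levels()))
  sex_fractions <- t(vapply(age_band_levels(), function(b) {
    s <- cc$sex[!is.na(bands) & bands == b]
    if (length(s) == 0) c(male = NA_real_, female = NA_real_)
    else c(male = mean(s == "male"), female = mean(s == "female"))
  }, numeric(2)))
  for (b in age_band_levels()) {
    nb <- band_counts[[b]]
    if (nb < 10)
      add_violation(sprintf("age band %s: >= 10 participants", b), nb, 10)
    if (nb > 0) {
      for (sx in c("male", "female")) {
        fr <- sex_fractions[b, sx]
        if (fr < 0.40)
          add_violation(sprintf("age band %s: >= 40%% %s", b, sx), 100 * fr, 40)
      }
    }
  }
  violations <- if (length(violations)) do.call(rbind, violations)
    else data.frame(rule_id = character(0), observed = numeric(0),
                    required = numeric(0))
  structure(list(n_total = n_enrolled,
                 n_complete = n_complete,
                 band_counts = as.integer(band_counts),
                 band_labels = age_band_levels(),
                 sex_fractions = sex_fractions,
                 pwv_fractions = c(low = frac_low, mid = frac_mid, high = frac_high),
                 pwv_cutoffs = c(low = lo, mid = mid, high = hi),
                 evenness_ratio = if (max(band_counts) > 0)
                   min(band_counts) / max(band_counts) else NA_real_,
                 violations = violations),
            class = "composition_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("Cohort composition: %d enrolled, %d complete\n",
              x$n_total, x$n_complete))
  cat("  age bands:", paste(sprintf("%s: %d", x$band_labels, x$band_counts),
                            collapse = ", "), "\n")
  cat(sprintf("  reference PWV: %.1f%% <= %g m/s, %.1f%% >= %g m/s, %.1f%% >= %g m/s\n",
              100 * x$pwv_fractions["low"], x$pwv_cutoffs["low"],
              100 * x$pwv_fractions["mid"], x$pwv_cutoffs["mid"],
              100 * x$pwv_fractions["high"], x$pwv_cutoffs["high"]))
  if (nrow(x$violations) == 0) cat("  no quota violations\n")
  else {
    cat(sprintf("  %d quota violation(s):\n", nrow(x$violations)))
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("   - %s (observed %.1f, required %.1f)\n",
                  x$violations$rule_id[i], x$violations$observed[i],
                  x$violations$required[i]))
  }
  invisible(x)
}

#' Hemodynamic stability of a sequential session
#'
#' Sequential transit-time measurement is valid only under hemodynamic
#' stability: heart rate, systolic and diastolic blood pressure must each
#' change by strictly less than 5% (relative to the pre-procedure baseline)
#' between the before and after readings.
#'
#' @param session A [measurement_session()] with before/after HR and BP.
#' @param threshold Relative-change threshold (strict), default 0.05.
#' @return List with `stable` (logical) and `changes_percent` (named vector
#'   of the three relative changes, in percent).
#' @export
check_hemodynamic_stability <- function(session, threshold = 0.05) {
  vals <- list(hr = c(session$hr_before, session$hr_after),
               sbp = c(session$sbp_before, session$sbp_after),
               dbp = c(session$dbp_before, session$dbp_after))
  changes <- vapply(names(vals), function(v) {
    b <- vals[[v]][1]; a <- vals[[v]][2]
    if (is.na(b) || is.na(a))
      stop(sprintf("participant %s: missing before/after %s",
                   session$participant_id, v), call. = FALSE)
    if (b <= 0)
      stop(sprintf("participant %s: non-positive baseline %s",
                   session$participant_id, v), call. = FALSE)
    100 * abs(a - b) / b
  }, numeric(1))
  list(stable = all(changes < 100 * threshold), changes_percent = changes)
}
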