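#' Configuration of a validation run
#'
#' The protocol requires quality criteria to be declared in advance;
#' [run_validation()] refuses to run without them. The defaults encode the
#' protocol's own criteria (strict <5% hemodynamic stability for sequential
#' sessions, 24 h vasoactive window).
#'
#' @param quality_criteria Named list of pre-declared quality criteria;
#'   must contain `stability_threshold` (relative change, fraction) and
#'   `vasoactive_window_h` (hours).
#' @param scale_factor PWV cutoff scale factor for [check_composition()].
#' @param software_version,hardware_version Version strings of the device
#'   under test (required report content).
#' @param training_data_overlap Whether any validation participant was used
#'   to train the device's algorithm (must be `FALSE` for a clean report).
#' @param measurement_principle,fiducial_point,detection_method Free-text
#'   disclosures for the reporting checklist.
#' @param data_availability Data-availability statement.
#' @return Object of class `validation_config`.
#' @export
validation_config <- function(quality_criteria = list(stability_threshold = 0.05,
                                                      vasoactive_window_h = 24),
                              scale_factor = 1,
                              software_version = NULL,
                              hardware_version = NULL,
                              training_data_overlap = FALSE,
                              measurement_principle = NULL,
                              fiducial_point = "diastolic foot",
                              detection_method = "intersecting tangent",
                              data_availability = NULL) {
  structure(list(quality_criteria = quality_criteria,
                 scale_factor = scale_factor,
                 software_version = software_version,
                 hardware_version = hardware_version,
                 training_data_overlap = training_data_overlap,
                 measurement_principle = measurement_principle,
                 fiducial_point = fiducial_point,
                 detection_method = detection_method,
                 data_availability = data_availability),
            class = "validation_config")
}

#' Run a full device-validation analysis
#'
#' End-to-end pipeline: participant eligibility screening, hemodynamic
#' stability checks (sequential sessions), measurement pairing, cohort
#' agreement summary with grading, stratified analyses (sex and age band),
#' cohort-composition checking, before/after hemodynamics, and discard
#' accounting. Quality criteria must be declared in the config beforehand.
#'
#' @param cohort Participant data frame (see [simulate_cohort()] /
#'   [read_study_csv()] for the schema).
#' @param sessions List of [measurement_session()] objects.
#' @param config A [validation_config()]; `quality_criteria` must be
#'   declared (the protocol requires advance declaration).
#' @return Object of class `validation_report`.
#' @export
run_validation <- function(cohort, sessions, config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  qc <- config$quality_criteria
  if (is.null(qc) || is.null(qc$stability_threshold) || is.null(qc$vasoactive_window_h))
    stop("refusing to run: quality criteria (stability_threshold, vasoactive_window_h) must be declared in advance in the config",
         call. = FALSE)

  discards <- data.frame(participant_id = character(0), reason = character(0))
  drop_participant <- function(id, reason)
    rbind(discards, data.frame(participant_id = as.character(id), reason = reason))

  ## 1. eligibility
  keep <- logical(length(sessions))
  for (i in seq_along(sessions)) {
    id <- as.character(sessions[[i]]$participant_id)
    rec <- cohort[match(id, cohort$id), , drop = FALSE]
    if (nrow(rec) != 1L)
      stop("session participant ", id, " not found in cohort", call. = FALSE)
    el <- check_eligibility(rec, vasoactive_window_h = qc$vasoactive_window_h)
    if (!el$eligible) {
      discards <- drop_participant(id, paste("ineligible:",
                                             paste(el$reasons, collapse = "; ")))
    } else keep[i] <- TRUE
  }
  sessions_kept <- sessions[keep]

  ## 2. hemodynamic stability (required for sequential transit-time sessions)
  keep2 <- logical(length(sessions_kept))
  for (i in seq_along(sessions_kept)) {
    s <- sessions_kept[[i]]
    if (s$mode == "sequential") {
      st <- check_hemodynamic_stability(s, threshold = qc$stability_threshold)
      if (!st$stable) {
        discards <- drop_participant(s$participant_id, "hemodynamic instability")
        next
      }
    }
    keep2[i] <- TRUE
  }
  sessions_kept <- sessions_kept[keep2]

  ## 3-4. pairing and agreement
  paired <- lapply(sessions_kept, pair_session)
  summary <- summarize_agreement(paired)

  ## 5. stratified analyses
  stratified <- list(sex = stratified_agreement(paired, cohort, "sex"),
                     age_band = stratified_agreement(paired, cohort, "age_band"),
                     vasoactive_drug_use =
                       if ("vasoactive_meds" %in% names(cohort))
                         stratified_agreement(paired, cohort, "vasoactive_drug_use")
                       else NULL)

  ## 6. composition of the analyzed cohort
  analyzed_ids <- vapply(sessions_kept, function(s) as.character(s$participant_id),
                         character(1))
  analyzed <- cohort[match(analyzed_ids, cohort$id), , drop = FALSE]
  attr(analyzed, "n_enrolled") <- attr(cohort, "n_enrolled") %||% nrow(cohort)
  composition <- check_composition(analyzed, scale_factor = config$scale_factor)

  ## 7. before/after hemodynamics (mean and SD, required report content)
  hemo <- t(vapply(c("hr_before", "hr_after", "sbp_before", "sbp_after",
                     "dbp_before", "dbp_after"), function(v) {
    x <- vapply(sessions_kept, function(s) s[[v]], numeric(1))
    c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  }, numeric(2)))

  report <- structure(list(summary = summary,
                           grading = summary$grading,
                           stratified = stratified,
                           composition = composition,
                           hemodynamics = hemo,
                           n_input_sessions = length(sessions),
                           n_analyzed = length(sessions_kept),
                           discards = discards,
                           paired = paired,
                           software_version = config$software_version,
                           hardware_version = config$hardware_version,
                           config = config),
                      class = "validation_report")
  report$checklist <- render_checklist(report)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("PWV device validation report\n")
  cat(sprintf("  sessions: %d analyzed / %d input (%d discarded)\n",
              x$n_analyzed, x$n_input_sessions, nrow(x$discards)))
  cat(sprintf("  mean difference %.3f m/s, SD %.3f m/s -> error85 %.2f m/s, grade %s\n",
              x$summary$mean_diff, x$summary$sd_diff,
              x$grading$error85_display, x$grading$grade))
  cat(sprintf("  composition violations: %d\n", nrow(x$composition$violations)))
  cat(sprintf("  checklist: %d pass / %d fail / %d n.a.\n",
              sum(x$checklist$status == "pass"),
              sum(x$checklist$status == "fail"),
              sum(x$checklist$status == "not_applicable")))
  invisible(x)
}

#' Reporting checklist for a validation study
#'
#' Itemized pass/fail/not-applicable checklist of the reporting
#' requirements: disclosure of the measurement principle, fiducial point and
#' detection method, separation of training and validation data, device
#' software/hardware version strings, a data-availability statement, the
#' Bland-Altman analysis, stratified analyses, before/after hemodynamics and
#' discard accounting.
#'
#' @param report A `validation_report`.
#' @return Data frame with columns `item`, `status`, `detail`.
#' @export
render_checklist <- function(report) {
  cfg <- report$config
  item <- function(name, status, detail = "")
    data.frame(item = name, status = status, detail = detail,
               stringsAsFactors = FALSE)
  strat_ok <- !is.null(report$stratified$sex) && !is.null(report$stratified$age_band)
  rows <- rbind(
    item("measurement principle disclosed",
         if (!is.null(cfg$measurement_principle)) "pass" else "fail"),
    item("fiducial point described",
         if (!is.null(cfg$fiducial_point)) "pass" else "fail",
         cfg$fiducial_point %||% ""),
    item("foot-detection method described",
         if (!is.null(cfg$detection_method)) "pass" else "fail",
         cfg$detection_method %||% ""),
    item("training and validation sets separate",
         if (isFALSE(cfg$training_data_overlap)) "pass" else "fail",
         if (isTRUE(cfg$training_data_overlap))
           "validation participants overlap the training data" else ""),
    item("device software version reported",
         if (!is.null(report$software_version)) "pass" else "fail",
         report$software_version %||% ""),
    item("device hardware version reported",
         if (!is.null(report$hardware_version)) "pass" else "fail",
         report$hardware_version %||% ""),
    item("data availability statement",
         if (!is.null(cfg$data_availability)) "pass" else "fail"),
    item("Bland-Altman analysis presented",
         if (!is.null(report$summary)) "pass" else "fail"),
    item("stratified analyses (sex, age band) presented",
         if (strat_ok) "pass" else "fail"),
    item("HR and BP before/after reported",
         if (!is.null(report$hemodynamics)) "pass" else "fail"),
    item("discarded measurements reported with reasons", "pass",
         sprintf("%d discarded", nrow(report$discards))))
  rows
}

#' Bland-Altman plot of a validation study
#'
#' Renders the required agreement plot: per-participant differences against
#' averages, a solid horizontal line at the mean difference, dashed lines at
#' mean -/+ 2 SD, the regression line, and a text annotation with the mean,
#' SD, regression equation, R-squared and p-value (numeric annotations
#' match the summary at 2 decimals).
#'
#' @param summary An `agreement_summary` from [summarize_agreement()].
#' @param file Optional output path (png or svg by extension); when `NULL`
#'   the ggplot object is returned without writing.
#' @param width,height Device size in inches when writing.
#' @return The ggplot object, invisibly when writing.
#' @export
render_bland_altman_plot <- function(summary, file = NULL, width = 7, height = 5) {
  stopifnot(inherits(summary, "agreement_summary"))
  if (summary$n < 2L) stop("at least 2 participants required", call. = FALSE)
  df <- data.frame(average = summary$averages, difference = summary$differences)
  ann <- sprintf(
    "mean = %.2f m/s, SD = %.2f m/s\ndiff = %.2f + %.2f x avg\nR² = %.2f, p = %.3g",
    summary$mean_diff, summary$sd_diff,
    summary$ba_regression$intercept, summary$ba_regression$slope,
    summary$ba_regression$r_squared, summary$ba_regression$p_value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = average, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = summary$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(summary$loa_low, summary$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_abline(intercept = summary$ba_regression$intercept,
                         slope = summary$ba_regression$slope,
                         colour = "steelblue") +
    ggplot2::annotate("text", x = min(df$average), y = max(df$difference,
                                                           summary$loa_high),
                      label = ann, hjust = 0, vjust = 1, size = 3) +
    ggplot2::labs(x = "Mean of test and reference PWV (m/s)",
                  y = "Test - reference PWV (m/s)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Serialize a validation report to JSON
#'
#' Machine-readable counterpart of the printed report: grading, agreement
#' summary, stratified results, composition findings, hemodynamics,
#' discards and checklist.
#'
#' @param report A `validation_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when writing to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  strat_json <- function(lst) lapply(lst, function(s) {
    if (is.null(s)) return(NULL)
    if (isFALSE(s$estimable)) list(stratum = s$stratum, n = s$n, estimable = FALSE)
    else list(stratum = s$stratum, n = s$n, estimable = TRUE,
              mean_diff = s$mean_diff, sd_diff = s$sd_diff,
              grade = s$grading$grade, error85 = s$grading$error85_display)
  })
  obj <- list(
    grading = list(rounded_mean = report$grading$rounded_mean,
                   rounded_sd = report$grading$rounded_sd,
                   error85 = report$grading$error85_display,
                   grade = report$grading$grade),
    agreement = list(n = report$summary$n,
                     mean_diff = report$summary$mean_diff,
                     sd_diff = report$summary$sd_diff,
                     loa_low = report$summary$loa_low,
                     loa_high = report$summary$loa_high,
                     ba_regression = report$summary$ba_regression),
    stratified = lapply(Filter(Negate(is.null), report$stratified), strat_json),
    composition = list(n_total = report$composition$n_total,
                       n_complete = report$composition$n_complete,
                       band_counts = report$composition$band_counts,
                       violations = report$composition$violations),
    hemodynamics = as.data.frame(report$hemodynamics),
    n_input_sessions = report$n_input_sessions,
    n_analyzed = report$n_analyzed,
    discards = report$discards,
    software_version = report$software_version,
    hardware_version = report$hardware_version,
    checklist = report$checklist)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
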