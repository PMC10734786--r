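## Long-format study CSV schema: one row per reading, demographics repeated.
study_csv_columns <- c("participant_id", "device_role", "reading_index",
                       "timestamp_s", "pwv_ms", "mode", "age", "sex", "bmi",
                       "rhythm", "vasoactive_meds", "time_since_dose_h",
                       "relevant_stenosis", "severe_aortic_stenosis",
                       "palpable_arteries", "hr_before", "hr_after",
                       "sbp_before", "sbp_after", "dbp_before", "dbp_after")

#' Write a validation study to CSV
#'
#' Serializes a cohort plus its measurement sessions to the long-format
#' study schema: one row per reading with columns `participant_id`,
#' `device_role` (test/reference), `reading_index`, `timestamp_s`, `pwv_ms`,
#' `mode`, the participant demographics and the before/after hemodynamics.
#'
#' @param cohort Participant data frame.
#' @param sessions List of [measurement_session()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(cohort, sessions, path) {
  rows <- lapply(sessions, function(s) {
    rec <- cohort[match(as.character(s$participant_id), cohort$id), , drop = FALSE]
    if (nrow(rec) != 1L)
      stop("session participant ", s$participant_id, " not found in cohort",
           call. = FALSE)
    mk <- function(role, df) data.frame(
      participant_id = s$participant_id, device_role = role,
      reading_index = seq_len(nrow(df)), timestamp_s = df$timestamp_s,
      pwv_ms = df$pwv, mode = s$mode,
      age = rec$age, sex = rec$sex, bmi = rec$bmi, rhythm = rec$rhythm,
      vasoactive_meds = rec$vasoactive_meds,
      time_since_dose_h = rec$time_since_dose_h,
      relevant_stenosis = rec$relevant_stenosis,
      severe_aortic_stenosis = rec$severe_aortic_stenosis,
      palpable_arteries = rec$palpable_arteries,
      hr_before = s$hr_before, hr_after = s$hr_after,
      sbp_before = s$sbp_before, sbp_after = s$sbp_after,
      dbp_before = s$dbp_before, dbp_after = s$dbp_after)
    rbind(mk("test", s$test_readings), mk("reference", s$reference_readings))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out[, study_csv_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a validation study from CSV
#'
#' Parses and validates the long-format study schema written by
#' [write_study_csv()]. Schema violations are reported with the offending
#' CSV line numbers.
#'
#' @param path CSV path.
#' @return List with `cohort` (participant data frame; `reference_pwv` set
#'   to the per-participant mean of reference readings) and `sessions`
#'   (list of [measurement_session()]).
#' @export
read_study_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(study_csv_columns, names(df))
  if (length(missing_cols) > 0L)
    stop("study CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_role <- !df$device_role %in% c("test", "reference")
  if (any(bad_role))
    stop("invalid device_role (must be test/reference) on CSV line(s): ",
         paste(utils::head(line_no[bad_role], 5L), collapse = ", "), call. = FALSE)
  bad_pwv <- !is.finite(df$pwv_ms) | df$pwv_ms <= 0
  if (any(bad_pwv))
    stop("non-positive or missing pwv_ms on CSV line(s): ",
         paste(utils::head(line_no[bad_pwv], 5L), collapse = ", "), call. = FALSE)
  bad_mode <- !df$mode %in% c("simultaneous", "sequential")
  if (any(bad_mode))
    stop("invalid mode on CSV line(s): ",
         paste(utils::head(line_no[bad_mode], 5L), collapse = ", "), call. = FALSE)

  ids <- unique(df$participant_id)
  sessions <- vector("list", length(ids))
  demo_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$participant_id == ids[i], , drop = FALSE]
    tst <- sub[sub$device_role == "test", , drop = FALSE]
    ref <- sub[sub$device_role == "reference", , drop = FALSE]
    tst <- tst[order(tst$reading_index), , drop = FALSE]
    ref <- ref[order(ref$reading_index), , drop = FALSE]
    first <- sub[1L, , drop = FALSE]
    sessions[[i]] <- measurement_session(
      participant_id = ids[i], mode = first$mode,
      test_readings = data.frame(timestamp_s = tst$timestamp_s, pwv = tst$pwv_ms),
      reference_readings = data.frame(timestamp_s = ref$timestamp_s, pwv = ref$pwv_ms),
      hr_before = first$hr_before, hr_after = first$hr_after,
      sbp_before = first$sbp_before, sbp_after = first$sbp_after,
      dbp_before = first$dbp_before, dbp_after = first$dbp_after)
    demo_rows[[i]] <- data.frame(
      id = ids[i], age = first$age, sex = first$sex, bmi = first$bmi,
      rhythm = first$rhythm, vasoactive_meds = as.logical(first$vasoactive_meds),
      time_since_dose_h = first$time_since_dose_h,
      relevant_stenosis = as.logical(first$relevant_stenosis),
      severe_aortic_stenosis = as.logical(first$severe_aortic_stenosis),
      palpable_arteries = as.logical(first$palpable_arteries),
      reference_pwv = mean(ref$pwv_ms),
      complete = TRUE, stringsAsFactors = FALSE)
  }
  list(cohort = do.call(rbind, demo_rows), sessions = sessions)
}

#' Write a pressure waveform to CSV
#'
#' Two-column CSV (`time_s`, `pressure`) preceded by a header line of the
#' form `# sampling_rate_hz=<fs>`.
#'
#' @param wave A [pressure_waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "pressure_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", wave$sampling_rate), con)
  utils::write.csv(data.frame(time_s = wave_times(wave), pressure = wave$samples),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a pressure waveform from CSV
#'
#' @param path CSV path written by [write_waveform_csv()].
#' @param site Optional site label to attach.
#' @return A [pressure_waveform()].
#' @export
read_waveform_csv <- function(path, site = "") {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("sampling_rate_hz=([0-9.eE+-]+)", header))[[1L]]
  if (length(m) < 2L)
    stop("waveform CSV must start with a '# sampling_rate_hz=<fs>' header line",
         call. = FALSE)
  fs <- as.numeric(m[2L])
  df <- utils::read.csv(path, skip = 1L)
  pressure_waveform(df$pressure, fs, site = site)
}
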