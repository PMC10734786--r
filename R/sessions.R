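#' A participant's measurement session
#'
#' One participant's ordered test-device and reference-device PWV readings,
#' with acquisition timestamps and the hemodynamic context recorded before
#' and after the procedure. In simultaneous mode both devices acquire 3
#' readings at matched times; in sequential mode the 3 test readings are
#' interleaved between 4 reference readings (canonical order
#' R1 T1 R2 T2 R3 T3 R4).
#'
#' @param participant_id Identifier.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param test_readings Data frame with columns `timestamp_s`, `pwv` (3 rows).
#' @param reference_readings Data frame with the same columns (3 rows
#'   simultaneous, 4 rows sequential).
#' @param hr_before,hr_after Heart rate, bpm.
#' @param sbp_before,sbp_after Systolic blood pressure, mmHg.
#' @param dbp_before,dbp_after Diastolic blood pressure, mmHg.
#' @return Object of class `measurement_session`.
#' @export
measurement_session <- function(participant_id, mode = c("simultaneous", "sequential"),
                                test_readings, reference_readings,
                                hr_before = NA_real_, hr_after = NA_real_,
                                sbp_before = NA_real_, sbp_after = NA_real_,
                                dbp_before = NA_real_, dbp_after = NA_real_) {
  mode <- match.arg(mode)
  check_readings <- function(df, what, n_expected) {
    if (!is.data.frame(df) || !all(c("timestamp_s", "pwv") %in% names(df)))
      stop(sprintf("participant %s: %s must be a data frame with columns timestamp_s, pwv",
                   participant_id, what), call. = FALSE)
    if (nrow(df) != n_expected)
      stop(sprintf("participant %s: expected %d %s for %s mode, got %d",
                   participant_id, n_expected, what, mode, nrow(df)),
           call. = FALSE)
    df <- df[order(df$timestamp_s), , drop = FALSE]
    if (anyNA(df$timestamp_s))
      stop(sprintf("participant %s: missing timestamps in %s; supply timestamps or use the canonical-order fallback (`canonical_order = TRUE`)",
                   participant_id, what), call. = FALSE)
    if (any(diff(df$timestamp_s) <= 0))
      stop(sprintf("participant %s: timestamps in %s must be strictly increasing",
                   participant_id, what), call. = FALSE)
    if (any(!is.finite(df$pwv)) || any(df$pwv <= 0))
      stop(sprintf("participant %s: all PWV values in %s must be positive",
                   participant_id, what), call. = FALSE)
    rownames(df) <- NULL
    df
  }
  n_ref <- if (mode == "simultaneous") 3L else 4L
  test_readings <- check_readings(test_readings, "test readings", 3L)
  reference_readings <- check_readings(reference_readings, "reference readings", n_ref)
  structure(list(participant_id = participant_id, mode = mode,
                 test_readings = test_readings,
                 reference_readings = reference_readings,
                 hr_before = hr_before, hr_after = hr_after,
                 sbp_before = sbp_before, sbp_after = sbp_after,
                 dbp_before = dbp_before, dbp_after = dbp_after),
            class = "measurement_session")
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf("Measurement session, participant %s (%s mode): %d test / %d reference readings\n",
              x$participant_id, x$mode, nrow(x$test_readings),
              nrow(x$reference_readings)))
  invisible(x)
}

new_paired_differences <- function(participant_id, per_pair) {
  structure(list(participant_id = participant_id,
                 per_pair = per_pair,
                 participant_mean_difference = mean(per_pair$difference),
                 participant_mean_average = mean((per_pair$test + per_pair$comparator) / 2)),
            class = "paired_differences")
}

#' @export
print.paired_differences <- function(x, ...) {
  cat(sprintf("Paired differences, participant %s: mean difference %.3f m/s over %d pairs\n",
              x$participant_id, x$participant_mean_difference, nrow(x$per_pair)))
  invisible(x)
}

#' Pair simultaneous test and reference readings
#'
#' In simultaneous mode reading i of the device under test is compared
#' directly with reference reading i, yielding 3 pairs; differences are
#' oriented test minus reference.
#'
#' @param session A [measurement_session()] in simultaneous mode.
#' @return Object of class `paired_differences` carrying the 3 per-pair
#'   differences, the participant mean difference and the participant mean
#'   average (for Bland-Altman analysis).
#' @export
pair_simultaneous <- function(session) {
  stopifnot(inherits(session, "measurement_session"))
  if (session$mode != "simultaneous")
    stop(sprintf("participant %s: session mode is %s, not simultaneous",
                 session$participant_id, session$mode), call. = FALSE)
  tst <- session$test_readings
  ref <- session$reference_readings
  per_pair <- data.frame(pair = seq_len(3L),
                         test = tst$pwv,
                         comparator = ref$pwv,
                         difference = tst$pwv - ref$pwv)
  new_paired_differences(session$participant_id, per_pair)
}

## comparator reference indices for one test time: the two readings closest in
## time; a distance tie beyond the closest is broken toward the later reading
closest_two_refs <- function(t_test, ref) {
  d <- abs(ref$timestamp_s - t_test)
  ord <- order(d, ref$timestamp_s)
  first <- ord[1L]
  rest <- setdiff(seq_len(nrow(ref)), first)
  dmin <- min(d[rest])
  tied <- rest[abs(d[rest] - dmin) < 1e-12]
  second <- if (length(tied) > 1L) tied[which.max(ref$timestamp_s[tied])] else tied[1L]
  sort(c(first, second))
}

#' Pair sequential test readings with bracketing reference readings
#'
#' When simultaneous acquisition is not feasible, each test reading T_i is
#' compared against the mean of the two reference readings closest to it in
#' time (out of R1..R4). Under the canonical interleaving R1 T1 R2 T2 R3 T3
#' R4 the comparators are mean(R1,R2), mean(R2,R3) and mean(R3,R4). When the
#' second-closest distance is tied, the later of the tied readings is taken
#' (deterministic tie-break).
#'
#' @param session A [measurement_session()] in sequential mode.
#' @param canonical_order Use the canonical interleaved order instead of
#'   timestamps (fallback when timestamps are unavailable/untrusted).
#' @return Object of class `paired_differences`.
#' @export
pair_sequential <- function(session, canonical_order = FALSE) {
  stopifnot(inherits(session, "measurement_session"))
  if (session$mode != "sequential")
    stop(sprintf("participant %s: session mode is %s, not sequential",
                 session$participant_id, session$mode), call. = FALSE)
  tst <- session$test_readings
  ref <- session$reference_readings
  idx <- if (canonical_order) {
    list(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  } else {
    lapply(tst$timestamp_s, closest_two_refs, ref = ref)
  }
  comparator <- vapply(idx, function(i) mean(ref$pwv[i]), numeric(1))
  per_pair <- data.frame(pair = seq_len(3L),
                         test = tst$pwv,
                         comparator = comparator,
                         difference = tst$pwv - comparator)
  per_pair$ref_lo <- vapply(idx, `[`, integer(1), 1L)
  per_pair$ref_hi <- vapply(idx, `[`, integer(1), 2L)
  new_paired_differences(session$participant_id, per_pair)
}

#' Pair a session according to its mode
#'
#' Dispatches to [pair_simultaneous()] or [pair_sequential()].
#'
#' @param session A [measurement_session()].
#' @param ... Passed to the mode-specific pairing function.
#' @return Object of class `paired_differences`.
#' @export
pair_session <- function(session, ...) {
  if (session$mode == "simultaneous") pair_simultaneous(session)
  else pair_sequential(session, ...)
}
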