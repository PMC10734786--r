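## fixture builders shared across test files

## simultaneous session from two PWV triples (timestamps 60/120/180 s)
make_simul_session <- function(id, test_pwv, ref_pwv,
                               hr = c(60, 61), sbp = c(120, 121), dbp = c(80, 80)) {
  measurement_session(
    participant_id = id, mode = "simultaneous",
    test_readings = data.frame(timestamp_s = c(60, 120, 180), pwv = test_pwv),
    reference_readings = data.frame(timestamp_s = c(60, 120, 180), pwv = ref_pwv),
    hr_before = hr[1], hr_after = hr[2],
    sbp_before = sbp[1], sbp_after = sbp[2],
    dbp_before = dbp[1], dbp_after = dbp[2])
}

## sequential session with explicit timestamps
make_seq_session <- function(id, test_pwv, ref_pwv,
                             t_test = c(120, 240, 360),
                             t_ref = c(60, 180, 300, 420),
                             hr = c(60, 61), sbp = c(120, 121), dbp = c(80, 80)) {
  measurement_session(
    participant_id = id, mode = "sequential",
    test_readings = data.frame(timestamp_s = t_test, pwv = test_pwv),
    reference_readings = data.frame(timestamp_s = t_ref, pwv = ref_pwv),
    hr_before = hr[1], hr_after = hr[2],
    sbp_before = sbp[1], sbp_after = sbp[2],
    dbp_before = dbp[1], dbp_after = dbp[2])
}

## a fully eligible participant record
eligible_record <- function(id = "P1", age = 45, sex = "male", bmi = 27,
                            reference_pwv = 8) {
  list(id = id, age = age, sex = sex, bmi = bmi, rhythm = "sinus",
       vasoactive_meds = FALSE, time_since_dose_h = NA_real_,
       relevant_stenosis = FALSE, severe_aortic_stenosis = FALSE,
       palpable_arteries = TRUE, reference_pwv = reference_pwv)
}

## paired differences with a prescribed participant mean difference; the
## comparator level sets the participant mean average
make_paired <- function(id, d, level = 8) {
  pair_simultaneous(make_simul_session(id, rep(level + d, 3), rep(level, 3)))
}
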