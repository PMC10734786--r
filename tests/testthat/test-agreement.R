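test_that("simultaneous pairing matches readings index by index", {
  p0 <- pair_simultaneous(make_simul_session("A", c(8.0, 8.2, 8.1), c(8.0, 8.2, 8.1)))
  expect_equal(p0$participant_mean_difference, 0)

  p1 <- pair_simultaneous(make_simul_session("B", c(9.0, 9.2, 9.1), c(8.0, 8.2, 8.1)))
  expect_equal(p1$participant_mean_difference, 1.0)

  p2 <- pair_simultaneous(make_simul_session("C", c(8.4, 8.0, 8.6), c(8.1, 8.2, 8.3)))
  expect_equal(p2$per_pair$difference, c(0.3, -0.2, 0.3))
  expect_equal(p2$participant_mean_difference, 0.4 / 3)

  ## reading-count mismatch is caught at construction, naming the participant
  expect_error(measurement_session(
    "D", "simultaneous",
    test_readings = data.frame(timestamp_s = c(60, 120), pwv = c(8, 8)),
    reference_readings = data.frame(timestamp_s = c(60, 120, 180), pwv = c(8, 8, 8))),
    "D.*expected 3")
})

test_that("sequential pairing averages the two closest reference readings", {
  ## constant references: comparator is 8.0 whatever the test times
  pc <- pair_sequential(make_seq_session("A", c(9, 9, 9), rep(8.0, 4)))
  expect_equal(pc$per_pair$comparator, rep(8.0, 3))

  ## canonical interleaving with test readings at the midpoints
  pm <- pair_sequential(make_seq_session("B", c(8.3, 8.5, 8.7),
                                         c(8.0, 8.2, 8.4, 8.6)))
  expect_equal(pm$per_pair$comparator, c(8.1, 8.3, 8.5))
  expect_equal(pm$per_pair$difference, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(pm$participant_mean_difference, 0.2, tolerance = 1e-12)

  ## canonical-order fallback gives the same bracketing comparators
  pf <- pair_sequential(make_seq_session("B", c(8.3, 8.5, 8.7),
                                         c(8.0, 8.2, 8.4, 8.6)),
                        canonical_order = TRUE)
  expect_equal(pf$per_pair$comparator, pm$per_pair$comparator)

  ## readings supplied in scrambled order are sorted by timestamp first
  s_sorted <- make_seq_session("C", c(8.3, 8.5, 8.7), c(8.0, 8.2, 8.4, 8.6))
  s_perm <- make_seq_session("C", c(8.7, 8.3, 8.5)[c(2, 3, 1)],
                             c(8.4, 8.0, 8.6, 8.2),
                             t_test = c(240, 360, 120)[c(2, 3, 1)],
                             t_ref = c(300, 60, 420, 180))
  expect_equal(pair_sequential(s_perm)$per_pair$comparator,
               pair_sequential(s_sorted)$per_pair$comparator)

  ## distance tie beyond the closest reading resolves to the later reading
  pt <- pair_sequential(make_seq_session("T", c(9, 9, 9), c(7.0, 8.0, 9.0, 9.5),
                                         t_test = c(10, 25, 30),
                                         t_ref = c(0, 10, 20, 30)))
  ## T1 at t=10: closest R2 (d=0), tie R1/R3 at d=10 -> later (R3): mean(8, 9)
  expect_equal(pt$per_pair$comparator[1], 8.5)

  ## conservation: each sequential comparator uses exactly two references
  expect_true(all(pt$per_pair$ref_hi > pt$per_pair$ref_lo))
})

test_that("agreement summary computes mean, SD, LoA and BA regression", {
  ## ten hand-listed participant differences; frozen spreadsheet arithmetic
  d <- c(0.1, 0.3, -0.2, 0.5, 0.0, 0.4, -0.1, 0.2, 0.6, 0.2)
  paired <- lapply(seq_along(d), function(i) make_paired(paste0("P", i), d[i]))
  s <- summarize_agreement(paired)
  expect_equal(s$n, 10L)
  expect_equal(s$mean_diff, 0.2)
  expect_equal(s$sd_diff, 0.2581989, tolerance = 1e-6)
  expect_equal(s$loa_high - s$loa_low, 4 * s$sd_diff)
  expect_equal(s$loa_low, 0.2 - 2 * 0.2581989, tolerance = 1e-6)

  ## all differences identical: SD 0, grade from the rounded mean
  same <- lapply(1:5, function(i) make_paired(paste0("S", i), 0.3))
  ss <- summarize_agreement(same)
  expect_equal(ss$sd_diff, 0)
  expect_identical(ss$grading$grade, "good")

  ## a constant shift moves the mean and not the SD
  shifted <- lapply(seq_along(d), function(i) make_paired(paste0("P", i), d[i] + 0.5))
  s2 <- summarize_agreement(shifted)
  expect_equal(s2$mean_diff, s$mean_diff + 0.5)
  expect_equal(s2$sd_diff, s$sd_diff, tolerance = 1e-9)

  expect_error(summarize_agreement(list(make_paired("X", 0.1))), "2 participants")
})

test_that("stratified agreement recovers stratum-specific bias and conserves n", {
  set.seed(42)
  n_per <- 30
  cohort <- data.frame(id = sprintf("P%02d", 1:(2 * n_per)),
                       age = rep(c(25, 60), each = n_per),
                       sex = rep(c("male", "female"), each = n_per),
                       vasoactive_meds = FALSE)
  bias <- rep(c(0.2, 0.6), each = n_per)
  paired <- lapply(seq_len(2 * n_per), function(i) {
    pair_simultaneous(make_simul_session(
      cohort$id[i], 8 + bias[i] + rnorm(3, 0, 0.2), 8 + rnorm(3, 0, 0.2)))
  })
  strat <- stratified_agreement(paired, cohort, "sex")
  expect_lt(abs(strat$male$mean_diff - 0.2), 0.1)
  expect_lt(abs(strat$female$mean_diff - 0.6), 0.1)

  ## age bands partition the cohort: stratum sizes sum to the total
  bands <- stratified_agreement(paired, cohort, "age_band")
  ns <- vapply(bands, function(b) if (isTRUE(b$estimable)) b$n else b$n, numeric(1))
  expect_equal(sum(ns), 2 * n_per)

  ## n-weighted stratum means reproduce the overall mean exactly
  overall <- summarize_agreement(paired)
  est <- Filter(function(b) isTRUE(b$estimable), bands)
  expect_equal(sum(vapply(est, function(b) b$n * b$mean_diff, numeric(1))) /
                 sum(vapply(est, function(b) b$n, numeric(1))),
               overall$mean_diff, tolerance = 1e-12)

  ## single-sex cohort: the empty stratum is marked, never dropped
  solo <- stratified_agreement(paired[1:n_per], cohort, "sex")
  expect_true(isTRUE(solo$male$estimable))
  expect_false(isTRUE(solo$female$estimable))
  expect_equal(solo$female$n, 0)

  expect_error(stratified_agreement(paired, cohort, "height"), "arg")
})

test_that("coefficient of variation follows the two-value sample-SD form", {
  expect_equal(coefficient_of_variation(10, 10), 0)
  expect_equal(coefficient_of_variation(8, 10), 100 * sqrt(2) / 9,
               tolerance = 1e-9)
  ## scale invariance
  expect_equal(coefficient_of_variation(8, 10),
               coefficient_of_variation(800, 1000), tolerance = 1e-12)
  expect_error(coefficient_of_variation(0, 5), "positive")
})

test_that("test-retest report measures precision against the clinical limit", {
  ## identical repeats: zero bias and zero CV
  rep0 <- test_retest_report(data.frame(participant_id = rep(c("A", "B"), each = 2),
                                        pwv = c(8, 8, 9, 9)))
  expect_equal(rep0$mean_diff, 0)
  expect_equal(rep0$mean_cv, 0)
  expect_equal(rep0$n_exceeding_limit, 0L)

  ## half-normal oracle: for repeat noise SD 0.3 per reading the mean
  ## absolute repeat difference is 0.3 * 2 / sqrt(pi) ~ 0.3385
  set.seed(7)
  n <- 4000
  m <- 8 + matrix(rnorm(2 * n, 0, 0.3), ncol = 2)
  rr <- test_retest_report(data.frame(participant_id = rep(seq_len(n), each = 2),
                                      pwv = as.vector(t(m))))
  expect_lt(abs(rr$mean_abs_diff - 0.3 * 2 / sqrt(pi)), 0.02)

  ## repeats beyond the predefined limit are flagged per participant
  rf <- test_retest_report(data.frame(participant_id = rep(c("A", "B"), each = 2),
                                      pwv = c(8, 9.5, 9, 9.1)))
  expect_equal(rf$n_exceeding_limit, 1L)
  expect_true(rf$per_participant$exceeds_limit[rf$per_participant$participant_id == "A"])

  ## participants lacking a second repeat are excluded with a reason
  re <- test_retest_report(data.frame(participant_id = c("A", "A", "B"),
                                      pwv = c(8, 8.2, 9)))
  expect_equal(re$excluded$participant_id, "B")
  expect_match(re$excluded$reason, "fewer than 2")
})
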