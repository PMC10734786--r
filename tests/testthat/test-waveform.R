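test_that("waveform synthesis produces periodic feet and respects Nyquist", {
  w <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                           n_harmonics = 50)
  feet <- attr(w, "feet")
  expect_length(feet, 12L)
  expect_equal(diff(feet), rep(1.0, 11), tolerance = 1e-9)

  ## reproducible under seed
  w1 <- synthesize_waveform(noise_sd = 0.05, seed = 9)
  w2 <- synthesize_waveform(noise_sd = 0.05, seed = 9)
  expect_identical(w1$samples, w2$samples)

  ## a delayed (distal) copy shifts the ground truth by exactly the delay
  wd <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                            n_harmonics = 50, foot_delay = 0.05)
  expect_equal(attr(wd, "feet"), feet + 0.05, tolerance = 1e-12)

  ## synthesis refuses sampling rates below twice the highest harmonic
  expect_error(synthesize_waveform(heart_rate = 60, sampling_rate = 80,
                                   n_harmonics = 50), "Nyquist")
})

test_that("intersecting-tangent feet match the analytic ground truth", {
  w <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                           n_harmonics = 50)
  gt <- attr(w, "feet")
  ft <- detect_feet_intersecting_tangent(w)
  expect_equal(nrow(ft), 12L)
  expect_lt(max(abs(ft$foot_time - gt)), 0.002)  # within 2 ms at 1 kHz
  expect_true(all(diff(ft$foot_time) > 0))
})

test_that("subsample interpolation beats nearest-sample assignment at 120 Hz", {
  w <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 120,
                           n_harmonics = 50)
  gt <- attr(w, "feet")
  sub <- detect_feet_intersecting_tangent(w, resolution = 0.001)
  near <- detect_feet_intersecting_tangent(w, resolution = 1 / 120,
                                           subsample = FALSE)
  expect_equal(nrow(sub), 12L)
  mae_sub <- mean(abs(sub$foot_time - gt))
  mae_near <- mean(abs(near$foot_time - gt))
  expect_lt(mae_sub, 1 / 120)   # below one sampling interval (8.3 ms)
  expect_lt(mae_sub, mae_near)  # quantization property
})

test_that("foot detection is shift-equivariant and amplitude-invariant", {
  w <- synthesize_waveform(heart_rate = 60, n_beats = 10, sampling_rate = 1000,
                           n_harmonics = 50)
  ws <- synthesize_waveform(heart_rate = 60, n_beats = 10, sampling_rate = 1000,
                            n_harmonics = 50, foot_delay = 0.037)
  f0 <- detect_feet_intersecting_tangent(w)
  fs <- detect_feet_intersecting_tangent(ws)
  expect_lt(max(abs(fs$foot_time - (f0$foot_time + 0.037))), 0.002)

  for (detect in list(detect_feet_intersecting_tangent,
                      detect_feet_diastole_patching)) {
    scaled <- pressure_waveform(3 * w$samples + 10, w$sampling_rate)
    expect_equal(detect(scaled)$foot_time, detect(w)$foot_time,
                 tolerance = 1e-6)
  }
})

test_that("diastole patching agrees with the tangent method and is deterministic", {
  w <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                           n_harmonics = 50)
  dp <- detect_feet_diastole_patching(w)
  it <- detect_feet_intersecting_tangent(w)
  expect_equal(nrow(dp), 12L)
  expect_lt(max(abs(dp$foot_time - it$foot_time)), 0.005)  # within 5 ms
  expect_identical(dp, detect_feet_diastole_patching(w))
})

test_that("both detectors tolerate modest noise with light smoothing", {
  w <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                           n_harmonics = 50, noise_sd = 0.02, seed = 42)
  gt <- attr(w, "feet")
  for (feet in list(detect_feet_intersecting_tangent(w, smooth_window = 0.02),
                    detect_feet_diastole_patching(w, smooth_window = 0.02))) {
    expect_equal(nrow(feet), 12L)
    expect_lt(mean(abs(feet$foot_time - gt)), 0.010)
  }
})

test_that("flat signals yield recorded failures, not spurious feet", {
  flat <- pressure_waveform(rep(80, 1000), 1000)
  ft <- detect_feet_intersecting_tangent(flat)
  expect_equal(nrow(ft), 0L)
  expect_match(attr(ft, "failures")$reason, "no detectable upstroke")
})

test_that("transit time and PWV follow path length over mean delay", {
  prox <- seq(0, 9)            # 10 beats, 1 s apart
  dist <- prox + 0.075         # 75 ms transit
  res <- transit_time_and_pwv(prox, dist, path = 60, min_beats = 10)
  expect_equal(res$pwv, 8.0, tolerance = 1e-9)
  expect_equal(res$pwv_reported, 8.0)
  expect_equal(res$n_beats, 10L)

  ## PWV scale law: doubling the path doubles PWV exactly
  expect_equal(transit_time_and_pwv(prox, dist, path = 120)$pwv, 16.0,
               tolerance = 1e-9)

  ## fewer than the minimum number of cardiac cycles is an error
  expect_error(transit_time_and_pwv(prox[1:9], dist[1:9], path = 60),
               "insufficient beats")
  ## non-physiological ordering
  expect_error(transit_time_and_pwv(prox, prox - 0.02, path = 60),
               "non-physiological")

  ## jittered transit times recover the true PWV within Monte-Carlo error
  set.seed(11)
  ok <- replicate(20, {
    dt <- 0.075 + rnorm(10, 0, 0.002)
    transit_time_and_pwv(prox, prox + dt, path = 60)$pwv
  })
  expect_equal(mean(ok), 8.0, tolerance = 0.1)
})

test_that("end-to-end two-site PWV from synthesized waveforms", {
  ## 50 cm path, 62.5 ms delay -> 8.0 m/s
  prox <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                              n_harmonics = 50, site = "carotid")
  dist <- synthesize_waveform(heart_rate = 60, n_beats = 12, sampling_rate = 1000,
                              n_harmonics = 50, foot_delay = 0.0625,
                              site = "femoral")
  res <- transit_time_and_pwv(detect_feet_intersecting_tangent(prox),
                              detect_feet_intersecting_tangent(dist),
                              path_length("subtraction", notch_to_carotid = 10,
                                          notch_to_femoral = 60))
  expect_gte(res$n_beats, 10L)
  expect_equal(res$pwv, 8.0, tolerance = 0.05)
})

test_that("Nyquist compliance scales with heart rate and harmonic count", {
  r <- nyquist_compliance(180, 20)
  expect_equal(r$harmonic_frequency_hz, 60)
  expect_equal(r$min_sampling_rate_hz, 120)
  expect_equal(nyquist_compliance(60, 20)$min_sampling_rate_hz, 40)
  expect_equal(nyquist_compliance(180, 1)$harmonic_frequency_hz, 3)
  expect_error(nyquist_compliance(-10, 20), "positive")
})

test_that("path length estimators and method-mismatch warning", {
  sub <- path_length("subtraction", notch_to_carotid = 10, notch_to_femoral = 60)
  expect_equal(sub$effective_length, 50)
  d80 <- path_length("direct_80", direct = 62.5)
  expect_equal(d80$effective_length, 50)
  expect_error(path_length("subtraction", notch_to_carotid = 60,
                           notch_to_femoral = 50), "exceed")
  expect_warning(warn_path_method_mismatch(sub, d80), "differ")
  expect_silent(warn_path_method_mismatch(sub, sub))
})

test_that("waveform CSV round-trips samples and sampling rate", {
  w <- synthesize_waveform(heart_rate = 72, n_beats = 3, sampling_rate = 250,
                           n_harmonics = 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, f)
  w2 <- read_waveform_csv(f)
  expect_equal(w2$sampling_rate, 250)
  expect_equal(w2$samples, w$samples, tolerance = 1e-8)
})
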