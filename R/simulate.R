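#' Configuration of a synthetic validation study
#'
#' Defines the generative model for a full validation study with known
#' ground truth: an age-stratified cohort (ages drawn per band weights over
#' the four protocol bands), an age-linear true-PWV model with
#' between-subject variation, a device under test with constant plus
#' proportional bias, and homoscedastic Gaussian per-reading noise for both
#' devices.
#'
#' Defaults emulate the recommended study conditions: 90 enrolled
#' participants, even age-band weights, balanced sexes, true cfPWV rising
#' from about 6.5 m/s in young adults to about 11 m/s past 70 (intercept 4.5
#' m/s + 0.9 m/s per decade, between-subject SD 1.0 m/s), an unbiased test
#' device and 0.25 m/s per-reading noise on both devices.
#'
#' @param n_participants Number of participants.
#' @param age_band_weights Probabilities of the four age bands (<30, 30-49,
#'   50-69, >=70); must be non-negative and sum to 1.
#' @param sex_balance Probability of male sex.
#' @param pwv_intercept True-PWV model intercept, m/s.
#' @param pwv_slope_per_decade True-PWV increase per decade of age, m/s.
#' @param pwv_between_sd Between-subject SD of true PWV, m/s.
#' @param bias_constant Constant device bias (test minus reference), m/s.
#' @param bias_proportional Proportional device bias per m/s of true PWV.
#' @param test_noise_sd,reference_noise_sd Per-reading noise SDs, m/s.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param seed Optional RNG seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 90,
                              age_band_weights = rep(0.25, 4),
                              sex_balance = 0.5,
                              pwv_intercept = 4.5,
                              pwv_slope_per_decade = 0.9,
                              pwv_between_sd = 1.0,
                              bias_constant = 0,
                              bias_proportional = 0,
                              test_noise_sd = 0.25,
                              reference_noise_sd = 0.25,
                              mode = c("simultaneous", "sequential"),
                              seed = NULL) {
  mode <- match.arg(mode)
  if (length(age_band_weights) != 4L || any(age_band_weights < 0) ||
      sum(age_band_weights) <= 0)
    stop("`age_band_weights` must be 4 non-negative weights", call. = FALSE)
  if (abs(sum(age_band_weights) - 1) > 1e-8)
    stop("`age_band_weights` must sum to 1", call. = FALSE)
  sds <- c(pwv_between_sd, test_noise_sd, reference_noise_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative", call. = FALSE)
  structure(list(n_participants = n_participants,
                 age_band_weights = age_band_weights,
                 sex_balance = sex_balance,
                 pwv_intercept = pwv_intercept,
                 pwv_slope_per_decade = pwv_slope_per_decade,
                 pwv_between_sd = pwv_between_sd,
                 bias_constant = bias_constant,
                 bias_proportional = bias_proportional,
                 test_noise_sd = test_noise_sd,
                 reference_noise_sd = reference_noise_sd,
                 mode = mode,
                 seed = seed),
            class = "simulation_config")
}

## uniform age ranges backing the four protocol bands
band_age_ranges <- function() list(c(18, 30), c(30, 50), c(50, 70), c(70, 86))

#' Simulate a validation-study cohort
#'
#' Draws a cohort per the configuration: ages by band weights (uniform
#' within band), sex by balance, true PWV from the age-linear model (floored
#' at 3 m/s), plus eligibility-relevant fields (BMI around 26 kg/m2 and
#' truncated below 40, sinus rhythm, no exclusionary flags; about 20% of
#' participants use vasoactive medication dosed outside the acute window).
#'
#' @param config A [simulation_config()].
#' @return Data frame of participant records with a `true_pwv` column
#'   (ground truth) and `reference_pwv` initialized to the truth (updated to
#'   observed means once sessions are simulated).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  bands <- sample.int(4L, n, replace = TRUE, prob = config$age_band_weights)
  rng <- band_age_ranges()
  age <- vapply(bands, function(b) stats::runif(1, rng[[b]][1], rng[[b]][2]),
                numeric(1))
  sex <- ifelse(stats::runif(n) < config$sex_balance, "male", "female")
  true_pwv <- config$pwv_intercept +
    config$pwv_slope_per_decade * (age / 10) +
    stats::rnorm(n, 0, config$pwv_between_sd)
  true_pwv <- pmax(true_pwv, 3)
  bmi <- pmin(stats::rnorm(n, 26, 4), 39.5)
  bmi <- pmax(bmi, 18)
  vaso <- stats::runif(n) < 0.2
  data.frame(id = sprintf("P%03d", seq_len(n)),
             age = age,
             sex = sex,
             bmi = bmi,
             rhythm = "sinus",
             vasoactive_meds = vaso,
             time_since_dose_h = ifelse(vaso, 48, NA_real_),
             relevant_stenosis = FALSE,
             severe_aortic_stenosis = FALSE,
             palpable_arteries = TRUE,
             true_pwv = true_pwv,
             reference_pwv = true_pwv,
             complete = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate measurement sessions for a cohort
#'
#' Generates per-participant sessions under the configured observation
#' model: each reference reading is the participant's true PWV plus
#' Gaussian noise; each test reading additionally carries the constant and
#' proportional device bias. Timestamps follow the protocol order (matched
#' times in simultaneous mode; interleaved R1 T1 R2 T2 R3 T3 R4 in
#' sequential mode, one reading per minute). Hemodynamically stable
#' before/after HR and BP values are drawn for every session.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param config The same [simulation_config()].
#' @return List of [measurement_session()] objects. The cohort with
#'   `reference_pwv` updated to the observed per-participant reference means
#'   is attached as attribute `cohort`.
#' @export
simulate_sessions <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_ref <- if (config$mode == "simultaneous") 3L else 4L
  sessions <- vector("list", nrow(cohort))
  ref_means <- numeric(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    truth <- cohort$true_pwv[i]
    ref <- truth + stats::rnorm(n_ref, 0, config$reference_noise_sd)
    tst <- truth + config$bias_constant + config$bias_proportional * truth +
      stats::rnorm(3L, 0, config$test_noise_sd)
    if (config$mode == "simultaneous") {
      t_ref <- c(60, 120, 180)
      t_tst <- c(60, 120, 180)
    } else {
      ## canonical interleaving R1 T1 R2 T2 R3 T3 R4
      t_all <- 60 * seq_len(7L)
      t_ref <- t_all[c(1L, 3L, 5L, 7L)]
      t_tst <- t_all[c(2L, 4L, 6L)]
    }
    hr <- stats::rnorm(1, 65, 8)
    sbp <- stats::rnorm(1, 125, 12)
    dbp <- stats::rnorm(1, 75, 8)
    drift <- function(x) x * (1 + stats::runif(1, -0.02, 0.02))
    sessions[[i]] <- measurement_session(
      participant_id = cohort$id[i],
      mode = config$mode,
      test_readings = data.frame(timestamp_s = t_tst, pwv = tst),
      reference_readings = data.frame(timestamp_s = t_ref, pwv = ref),
      hr_before = hr, hr_after = drift(hr),
      sbp_before = sbp, sbp_after = drift(sbp),
      dbp_before = dbp, dbp_after = drift(dbp))
    ref_means[i] <- mean(ref)
  }
  cohort$reference_pwv <- ref_means
  attr(sessions, "cohort") <- cohort
  sessions
}

#' Simulate a complete validation study
#'
#' Convenience wrapper: [simulate_cohort()] then [simulate_sessions()].
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (reference PWV set to observed means) and
#'   `sessions`.
#' @export
simulate_study <- function(config) {
  cohort <- simulate_cohort(config)
  sessions <- simulate_sessions(cohort, config)
  list(cohort = attr(sessions, "cohort"), sessions = sessions)
}

#' Constructive cohort guaranteed to satisfy every composition quota
#'
#' Builds the canonical passing fixture: `n` complete participants allocated
#' as evenly as possible over the four age bands (each >= 10), alternating
#' sexes within band (>= 40% each), and reference PWV values placed so that
#' at least 5% are <= 6 m/s, at least 5% are >= 10 m/s and at least 20% are
#' >= 8 m/s. The study is modelled as having enrolled `n_enrolled`
#' participants (default `n + 5` dropouts), carried on the `n_enrolled`
#' attribute consumed by [check_composition()]. All eligibility fields pass.
#'
#' @param n Number of complete participants; must permit all quotas
#'   simultaneously (>= 40 for the four bands of 10; default 85).
#' @param n_enrolled Number enrolled, default `max(n + 5, 90)`.
#' @return Participant data frame (as [simulate_cohort()], deterministic).
#' @export
quota_satisfying_cohort <- function(n = 85, n_enrolled = max(n + 5, 90)) {
  if (n < 40)
    stop(sprintf(
      "infeasible: n = %d cannot satisfy the binding constraint of 4 age bands with >= 10 participants each (needs >= 40)",
      n), call. = FALSE)
  per_band <- rep(n %/% 4L, 4L) + c(rep(1L, n %% 4L), rep(0L, 4L - n %% 4L))
  bands <- rep.int(seq_len(4L), per_band)
  ## alternate sexes within each band: counts differ by at most 1 (>= 40%)
  sex <- unlist(lapply(per_band, function(k)
    rep_len(c("male", "female"), k)), use.names = FALSE)
  ## deterministic ages spread within each band
  rng <- band_age_ranges()
  age <- unlist(lapply(seq_len(4L), function(b) {
    k <- per_band[b]
    lo <- rng[[b]][1]; hi <- rng[[b]][2]
    lo + (seq_len(k) - 0.5) / k * (hi - lo - 1)
  }), use.names = FALSE)
  ## PWV placement: low tail in the youngest band, high tail in the oldest
  k_low <- ceiling(0.05 * n)   # <= 6 m/s
  k_high <- ceiling(0.05 * n)  # >= 10 m/s
  k_mid <- max(ceiling(0.20 * n) - k_high, 0L)  # additional >= 8 m/s
  pwv <- 6.2 + 1.2 * (bands - 1) / 3  # unremarkable mid-range values by age
  pwv[seq_len(k_low)] <- 5.5
  idx_old <- rev(seq_len(n))
  pwv[idx_old[seq_len(k_high)]] <- 10.5
  pwv[idx_old[k_high + seq_len(k_mid)]] <- 8.5
  cohort <- data.frame(id = sprintf("P%03d", seq_len(n)),
                       age = age,
                       sex = sex,
                       bmi = 26,
                       rhythm = "sinus",
                       vasoactive_meds = FALSE,
                       time_since_dose_h = NA_real_,
                       relevant_stenosis = FALSE,
                       severe_aortic_stenosis = FALSE,
                       palpable_arteries = TRUE,
                       true_pwv = pwv,
                       reference_pwv = pwv,
                       complete = TRUE,
                       stringsAsFactors = FALSE)
  attr(cohort, "n_enrolled") <- n_enrolled
  cohort
}
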