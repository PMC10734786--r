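#' Uniformly sampled pressure waveform
#'
#' @param samples Pressure values (mmHg or arbitrary units).
#' @param sampling_rate Sampling rate, Hz.
#' @param site Site label (e.g. "carotid", "femoral").
#' @param beat_onsets Optional sample indices of beat onsets.
#' @return Object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(samples, sampling_rate, site = "",
                              beat_onsets = NULL) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("`samples` must be a numeric vector with at least 2 values", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 site = site,
                 beat_onsets = beat_onsets),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("Pressure waveform%s: %d samples at %g Hz (%.2f s)\n",
              if (nzchar(x$site)) paste0(" [", x$site, "]") else "",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate), ...)
  invisible(x)
}

wave_times <- function(wave) (seq_along(wave$samples) - 1L) / wave$sampling_rate

## Continuous single-beat template on beat-local time tau in [0, T):
## sin^2 upstroke of duration rise_time from diastolic level to peak, then a
## normalized exponential decay returning exactly to the diastolic level at
## tau = T (continuous periodic pulse). The intersecting-tangent foot of this
## template has closed form: tangent through the max-slope point (tau =
## rise_time/2) meets the diastolic level at tau = rise_time * (1/2 - 1/pi).
beat_template <- function(tau, period, rise_time, decay_tau, baseline, amplitude) {
  tau <- tau %% period
  up <- tau < rise_time
  p <- numeric(length(tau))
  p[up] <- baseline + amplitude * sin(pi * tau[up] / (2 * rise_time))^2
  td <- tau[!up] - rise_time
  span <- period - rise_time
  k <- exp(-span / decay_tau)
  p[!up] <- baseline + amplitude * (exp(-td / decay_tau) - k) / (1 - k)
  p
}

tangent_foot_offset <- function(rise_time) rise_time * (1 / 2 - 1 / pi)

#' Synthesize a pressure-like waveform with known feet
#'
#' Builds a periodic arterial-pressure-like pulse as a truncated harmonic
#' (Fourier) series of a smooth beat template (sin^2 upstroke, exponential
#' diastolic decay), optionally adds Gaussian noise, and returns the
#' continuous-time ground-truth foot times. The ground-truth foot is defined
#' as the intersecting-tangent fiducial point of the continuous template
#' (closed form), i.e. the value a perfect tangent detector would recover
#' before any sampling or band-limiting. The record starts with half a
#' period of late diastole so the first beat has a usable preceding minimum.
#'
#' @param heart_rate Heart rate, bpm.
#' @param n_beats Number of beats.
#' @param foot_delay Time shift applied to the whole waveform, s (use for a
#'   distal copy; ground-truth feet shift by the same amount).
#' @param noise_sd Gaussian noise SD as a fraction of pulse amplitude.
#' @param sampling_rate Sampling rate, Hz; must be at least twice the highest
#'   synthesized harmonic (Nyquist).
#' @param n_harmonics Number of harmonics retained (>= 20 available).
#' @param rise_time Upstroke duration of the template, s.
#' @param decay_tau Diastolic decay time constant, s.
#' @param baseline,amplitude Diastolic level and pulse amplitude (mmHg).
#' @param site Site label.
#' @param seed Optional seed for the noise (local; does not disturb the
#'   global RNG stream).
#' @return A [pressure_waveform()] with attributes `feet` (ground-truth foot
#'   times, s), `onsets` (template upstroke-onset times, s) and the synthesis
#'   parameters.
#' @export
synthesize_waveform <- function(heart_rate = 60, n_beats = 12, foot_delay = 0,
                                noise_sd = 0, sampling_rate = 1000,
                                n_harmonics = 50, rise_time = 0.12,
                                decay_tau = 0.25, baseline = 80, amplitude = 40,
                                site = "", seed = NULL) {
  stopifnot(n_beats >= 1, heart_rate > 0, rise_time > 0)
  period <- 60 / heart_rate
  f0 <- 1 / period
  if (sampling_rate < 2 * n_harmonics * f0)
    stop(sprintf(
      "sampling rate %g Hz violates the Nyquist criterion for harmonic %d of %g Hz (need >= %g Hz)",
      sampling_rate, n_harmonics, f0, 2 * n_harmonics * f0), call. = FALSE)
  ## Fourier coefficients of the template from a fine grid over one period
  nfft <- 8192L
  tau <- (0:(nfft - 1L)) / nfft * period
  tmpl <- beat_template(tau, period, rise_time, decay_tau, baseline, amplitude)
  coef <- stats::fft(tmpl) / nfft
  duration <- (n_beats + 0.5) * period
  n <- floor(duration * sampling_rate) + 1L
  t <- (0:(n - 1L)) / sampling_rate
  phase <- period / 2  # late-diastole lead-in before the first onset
  tt <- t - phase - foot_delay
  p <- rep(Re(coef[1L]), n)
  for (k in seq_len(n_harmonics)) {
    ck <- coef[k + 1L]
    p <- p + 2 * (Re(ck) * cos(2 * pi * k * f0 * tt) -
                  Im(ck) * sin(2 * pi * k * f0 * tt))
  }
  if (noise_sd > 0) {
    rn <- local_rnorm(n, sd = noise_sd * amplitude, seed = seed)
    p <- p + rn
  }
  onsets <- phase + foot_delay + (0:(n_beats - 1L)) * period
  feet <- onsets + tangent_foot_offset(rise_time)
  wave <- pressure_waveform(p, sampling_rate, site = site)
  attr(wave, "feet") <- feet
  attr(wave, "onsets") <- onsets
  attr(wave, "params") <- list(heart_rate = heart_rate, n_beats = n_beats,
                               foot_delay = foot_delay, noise_sd = noise_sd,
                               n_harmonics = n_harmonics, rise_time = rise_time,
                               decay_tau = decay_tau, baseline = baseline,
                               amplitude = amplitude)
  wave
}

## draw noise without touching the caller's RNG stream when a seed is given
local_rnorm <- function(n, sd, seed = NULL) {
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

## zero-phase centered moving average; edges use shrinking windows
smooth_ma <- function(x, fs, window_s) {
  k <- max(1L, round(window_s * fs))
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  half <- (k - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(half)) {
    sm[i] <- mean(x[1:(i + half)])
    sm[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  sm
}

## systolic peak indices: contiguous regions above mid-range of a heavily
## smoothed copy (80 ms window), regions shorter than 30 ms rejected
find_systolic_peaks <- function(x, fs) {
  xs <- smooth_ma(x, fs, 0.08)
  rng <- range(xs)
  if (diff(rng) < .Machine$double.eps^0.5 * max(1, abs(rng[2])))
    return(integer(0))
  thr <- rng[1] + 0.6 * diff(rng)
  above <- xs > thr
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  keep <- (ends - starts + 1L) >= max(2L, round(0.03 * fs))
  starts <- starts[keep]; ends <- ends[keep]
  vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(xs[seg])]
  }, integer(1))
}

## shared per-beat segmentation: fine-grid interpolation + windows between
## consecutive systolic peaks (plus the lead-in before the first peak)
beat_windows <- function(wave, resolution, smooth_window = 0) {
  x <- wave$samples
  fs <- wave$sampling_rate
  t <- wave_times(wave)
  peaks <- find_systolic_peaks(x, fs)
  if (length(peaks) == 0L) return(NULL)
  xs <- if (smooth_window > 0) smooth_ma(x, fs, smooth_window) else x
  sf <- stats::splinefun(t, xs, method = "fmm")
  bounds <- c(t[1L], t[peaks])
  windows <- lapply(seq_len(length(bounds) - 1L),
                    function(i) c(bounds[i], bounds[i + 1L]))
  list(spline = sf, windows = windows, peak_times = t[peaks], t_range = range(t))
}

finish_feet <- function(feet, failures, method) {
  ok <- !vapply(feet, is.null, logical(1))
  out <- data.frame(beat_index = integer(0), foot_time = numeric(0),
                    method = character(0))
  if (any(ok)) {
    out <- data.frame(beat_index = seq_len(sum(ok)),
                      foot_time = unlist(feet[ok]),
                      method = method)
    ## enforce strictly increasing foot times
    keep <- c(TRUE, diff(out$foot_time) > 0)
    out <- out[keep, , drop = FALSE]
    out$beat_index <- seq_len(nrow(out))
  }
  attr(out, "failures") <- failures
  class(out) <- c("foot_annotation", class(out))
  out
}

#' Intersecting-tangent foot detection at subsample resolution
#'
#' For each beat, the foot is the intersection of (a) the tangent through
#' the point of maximum upstroke slope and (b) the horizontal line through
#' the preceding diastolic minimum. Slope and minimum are localized on a
#' cubic-spline-interpolated signal evaluated on a grid of step `resolution`
#' (default 1 ms), so foot times carry subsample resolution; at the minimum
#' compliant sampling rate of 120 Hz this is much finer than the 8.3 ms
#' sampling interval, minimizing quantization error.
#'
#' @param wave A [pressure_waveform()].
#' @param resolution Time resolution of the interpolated search grid, s.
#' @param subsample Use spline interpolation (default). With `FALSE`, the
#'   minimum and maximum-slope point are localized on the raw sample grid
#'   (nearest-sample assignment; exposed for quantization-error comparisons).
#' @param smooth_window Width (s) of a zero-phase moving average applied to
#'   the signal before interpolation; 0 (default) analyzes the raw samples.
#'   Use about 0.02 s for noisy recordings. Beat segmentation always runs on
#'   a heavily smoothed copy and is unaffected.
#' @return A `foot_annotation` data frame (`beat_index`, `foot_time`,
#'   `method`), with failed beats recorded in the `failures` attribute.
#' @export
detect_feet_intersecting_tangent <- function(wave, resolution = 0.001,
                                             subsample = TRUE,
                                             smooth_window = 0) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (resolution > 1 / wave$sampling_rate)
    stop("`resolution` must be at most one sampling interval", call. = FALSE)
  bw <- beat_windows(wave, resolution, smooth_window)
  if (is.null(bw)) {
    return(finish_feet(list(), data.frame(beat = 1L, reason = "no detectable upstroke"),
                       "intersecting_tangent"))
  }
  failures <- NULL
  feet <- lapply(seq_along(bw$windows), function(i) {
    w <- bw$windows[[i]]
    if (subsample) {
      tt <- seq(w[1], w[2], by = resolution)
      xx <- bw$spline(tt)
      dd <- bw$spline(tt, deriv = 1L)
    } else {
      ## nearest-sample variant: work on the raw grid
      fs <- wave$sampling_rate
      i0 <- max(1L, floor(w[1] * fs) + 1L)
      i1 <- min(length(wave$samples), ceiling(w[2] * fs) + 1L)
      tt <- ((i0:i1) - 1L) / fs
      xx <- wave$samples[i0:i1]
      dd <- c(diff(xx) * fs, NA_real_)
    }
    imin <- which.min(xx)
    p_min <- xx[imin]
    seg <- seq(imin, length(tt))
    if (length(seg) < 2L) {
      failures <<- rbind(failures, data.frame(beat = i, reason = "no upstroke after minimum"))
      return(NULL)
    }
    islope <- seg[which.max(dd[seg])]
    s <- dd[islope]
    if (!is.finite(s) || s <= 0) {
      failures <<- rbind(failures, data.frame(beat = i, reason = "no positive upstroke slope"))
      return(NULL)
    }
    foot <- tt[islope] - (xx[islope] - p_min) / s
    ## nearest-sample assignment quantizes the foot to the raw sample grid
    if (!subsample) foot <- round(foot * wave$sampling_rate) / wave$sampling_rate
    foot
  })
  finish_feet(feet, failures, "intersecting_tangent")
}

#' Diastole-patching foot detection at subsample resolution
#'
#' For each beat, a low-order (quadratic) polynomial is fitted to the
#' late-diastolic segment preceding the upstroke and a straight line to the
#' early systolic upstroke (between 20% and 70% of the pulse amplitude);
#' the foot is their intersection, found at subsample resolution.
#'
#' @inheritParams detect_feet_intersecting_tangent
#' @param patch_window Length of the late-diastolic segment fitted, s.
#' @return A `foot_annotation` data frame, as for the tangent detector.
#' @export
detect_feet_diastole_patching <- function(wave, patch_window = 0.08,
                                          resolution = 0.001,
                                          smooth_window = 0) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (resolution > 1 / wave$sampling_rate)
    stop("`resolution` must be at most one sampling interval", call. = FALSE)
  bw <- beat_windows(wave, resolution, smooth_window)
  if (is.null(bw)) {
    return(finish_feet(list(), data.frame(beat = 1L, reason = "no detectable upstroke"),
                       "diastole_patching"))
  }
  failures <- NULL
  feet <- lapply(seq_along(bw$windows), function(i) {
    w <- bw$windows[[i]]
    tt <- seq(w[1], w[2], by = resolution)
    xx <- bw$spline(tt)
    imin <- which.min(xx)
    t_min <- tt[imin]
    amp <- max(xx) - xx[imin]
    if (amp <= 0) {
      failures <<- rbind(failures, data.frame(beat = i, reason = "flat beat"))
      return(NULL)
    }
    ## late-diastolic patch: quadratic over [t_min - patch_window, t_min]
    dia <- tt >= (t_min - patch_window) & tt <= t_min
    ## early upstroke: rising limb between 20% and 70% amplitude after t_min
    after <- seq(imin, length(tt))
    lvl <- (xx[after] - xx[imin]) / amp
    ipk <- after[which.max(xx[after])]
    ups <- after[lvl >= 0.2 & lvl <= 0.7 & after <= ipk]
    if (sum(dia) < 4L || length(ups) < 2L) {
      failures <<- rbind(failures, data.frame(beat = i, reason = "ill-conditioned fit"))
      return(NULL)
    }
    td <- tt[dia] - t_min  # center for conditioning
    qfit <- stats::lm.fit(cbind(1, td, td^2), xx[dia])$coefficients
    tu <- tt[ups] - t_min
    lfit <- stats::lm.fit(cbind(1, tu), xx[ups])$coefficients
    ## intersection: qfit quadratic = lfit line, in centered time
    a <- qfit[3L]; b <- qfit[2L] - lfit[2L]; cc <- qfit[1L] - lfit[1L]
    root <- NULL
    if (abs(a) > 1e-12) {
      disc <- b^2 - 4 * a * cc
      if (disc >= 0) {
        r <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
        r <- r[r >= -patch_window & r <= (tt[ipk] - t_min)]
        if (length(r) > 0) root <- max(r)  # root nearest the upstroke
      }
    }
    if (is.null(root)) {
      if (abs(b) < 1e-12) {
        failures <<- rbind(failures, data.frame(beat = i, reason = "ill-conditioned fit"))
        return(NULL)
      }
      root <- -cc / b
    }
    t_min + root
  })
  finish_feet(feet, failures, "diastole_patching")
}

#' Transit time and PWV between two measurement sites
#'
#' Matches proximal and distal foot annotations beat by beat (nearest onset
#' within half a cardiac period), computes per-beat transit times (distal
#' minus proximal foot), and derives PWV as effective path length divided by
#' the mean transit time. At least `min_beats` matched beats are required
#' (default 10 cardiac cycles); any non-positive transit time is a
#' non-physiological ordering error.
#'
#' @param prox_feet,dist_feet `foot_annotation` data frames (or numeric foot
#'   times, s) for the proximal and distal sites.
#' @param path A [path_length()] object (or effective length in cm).
#' @param min_beats Minimum number of matched beats, default 10.
#' @return List with `pwv` (m/s, full precision), `pwv_reported` (rounded to
#'   0.1 m/s as recorded in validation studies), `n_beats`,
#'   `transit_times_s` and `mean_transit_time_s`.
#' @export
transit_time_and_pwv <- function(prox_feet, dist_feet, path, min_beats = 10) {
  tp <- if (is.data.frame(prox_feet)) prox_feet$foot_time else as.numeric(prox_feet)
  td <- if (is.data.frame(dist_feet)) dist_feet$foot_time else as.numeric(dist_feet)
  length_cm <- if (inherits(path, "path_length")) path$effective_length
               else as.numeric(path)
  if (length(tp) < 2L)
    stop("need at least 2 proximal feet to estimate the cardiac period",
         call. = FALSE)
  period <- stats::median(diff(tp))
  ## nearest-foot matching within half a period, each distal foot used once
  used <- rep(FALSE, length(td))
  dt <- numeric(0)
  for (t0 in tp) {
    cand <- which(!used & abs(td - t0) < period / 2 & td > t0 - period / 2)
    if (length(cand) == 0L) next
    j <- cand[which.min(abs(td[cand] - t0))]
    used[j] <- TRUE
    dt <- c(dt, td[j] - t0)
  }
  if (any(dt <= 0))
    stop("non-physiological ordering: distal foot precedes proximal foot",
         call. = FALSE)
  if (length(dt) < min_beats)
    stop(sprintf("insufficient beats: %d matched, at least %d cardiac cycles required",
                 length(dt), min_beats), call. = FALSE)
  pwv <- (length_cm / 100) / mean(dt)
  list(pwv = pwv, pwv_reported = round(pwv, 1), n_beats = length(dt),
       transit_times_s = dt, mean_transit_time_s = mean(dt))
}

#' Frequency-content requirement for pressure recording
#'
#' Accurate foot detection requires capturing at least 20 harmonics of the
#' pressure signal. For a maximum heart rate this gives the highest harmonic
#' frequency `n_harmonics * max_heart_rate / 60` Hz and, by the Nyquist
#' criterion, a minimum sampling rate of twice that (180 bpm and 20
#' harmonics: 60 Hz and 120 Hz).
#'
#' @param max_heart_rate Maximum heart rate to support, bpm.
#' @param n_harmonics Number of harmonics to capture, default 20.
#' @return List with `harmonic_frequency_hz` and `min_sampling_rate_hz`.
#' @export
nyquist_compliance <- function(max_heart_rate, n_harmonics = 20) {
  if (max_heart_rate <= 0 || n_harmonics <= 0)
    stop("inputs must be positive", call. = FALSE)
  f <- n_harmonics * max_heart_rate / 60
  list(harmonic_frequency_hz = f, min_sampling_rate_hz = 2 * f)
}

#' Carotid-femoral path length
#'
#' Computes the effective arterial path length, either by the subtraction
#' method (sternal notch-to-femoral distance minus sternal notch-to-carotid
#' distance) or as 80% of the direct carotid-to-femoral distance. The
#' estimate used for the reference PWV should match the one used in the
#' device under test; see [warn_path_method_mismatch()].
#'
#' @param method `"subtraction"` or `"direct_80"`.
#' @param notch_to_carotid,notch_to_femoral Distances for the subtraction
#'   method, cm.
#' @param direct Direct carotid-to-femoral distance, cm.
#' @return Object of class `path_length` with `method`, `distances` and
#'   `effective_length` (cm).
#' @export
path_length <- function(method = c("subtraction", "direct_80"),
                        notch_to_carotid = NULL, notch_to_femoral = NULL,
                        direct = NULL) {
  method <- match.arg(method)
  if (method == "subtraction") {
    if (is.null(notch_to_carotid) || is.null(notch_to_femoral))
      stop("subtraction method needs `notch_to_carotid` and `notch_to_femoral`",
           call. = FALSE)
    if (notch_to_carotid <= 0 || notch_to_femoral <= 0)
      stop("distances must be positive", call. = FALSE)
    eff <- notch_to_femoral - notch_to_carotid
    if (eff <= 0)
      stop("notch-to-femoral distance must exceed notch-to-carotid distance",
           call. = FALSE)
    distances <- c(notch_to_carotid = notch_to_carotid,
                   notch_to_femoral = notch_to_femoral)
  } else {
    if (is.null(direct)) stop("direct_80 method needs `direct`", call. = FALSE)
    if (direct <= 0) stop("distances must be positive", call. = FALSE)
    eff <- 0.8 * direct
    distances <- c(direct = direct)
  }
  structure(list(method = method, distances = distances, effective_length = eff),
            class = "path_length")
}

#' Warn when path-length methods differ between devices
#'
#' The reference device's path-length estimate should match the estimate
#' used by the device under test; a mismatch biases the comparison.
#'
#' @param test_path,reference_path [path_length()] objects.
#' @return `TRUE` (invisibly) if methods match, otherwise `FALSE` with a
#'   warning.
#' @export
warn_path_method_mismatch <- function(test_path, reference_path) {
  stopifnot(inherits(test_path, "path_length"),
            inherits(reference_path, "path_length"))
  if (test_path$method != reference_path$method) {
    warning(sprintf(
      "path-length methods differ between devices (test: %s, reference: %s); estimates should match",
      test_path$method, reference_path$method), call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
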