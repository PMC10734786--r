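---
title: "Methods: statistical validation of PWV measurement devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical validation of PWV measurement devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvalidr)
```

## The normative difference model

A technical validation study compares a PWV device under test (T) against a
reference standard device (R) in n participants, each contributing three
paired readings. The analysis unit is the per-participant mean difference
over the three pairs, oriented test minus reference. `pwvalidr` models these
per-participant differences as

$$D \sim \mathcal{N}(\mu, \sigma^2),$$

with $\mu$ the device bias and $\sigma$ the SD of the per-participant mean
differences, both in m/s. The normal model is the normative choice here: it
makes the tolerable-error probability a two-parameter computation, and it is
the model under which the published grading convention for the worked
values (mean 0.40, SD 0.45 giving a 0.88 m/s bound, see below) is
reproduced. The empirical fraction of participants within the bound is also
available from `summarize_agreement()` output as a supplementary
distribution-free statistic, but the normal-model grade is primary.

### The tolerable-error bound

`error_at_probability()` solves
$$P(|D| \le E) = \Phi\!\left(\frac{E-\mu}{\sigma}\right) -
  \Phi\!\left(\frac{-E-\mu}{\sigma}\right) = p$$
for $E$, with $p = 0.85$ by default. The coverage is strictly increasing in
$E$, so a bracketing bisection on $[0, |\mu| + 10\sigma]$ (tolerance
$10^{-6}$ m/s) is guaranteed to converge without derivatives. The bound is
symmetric in the sign of $\mu$, so a negative bias grades identically to a
positive one. Two degenerate cases are defined explicitly: $\sigma = 0$
collapses the bound to $|\mu|$, and constant differences in
`summarize_agreement()` yield a zero regression slope with an undefined
slope test (p-value `NA`).

`max_sd_for_error()` inverts the same relation in $\sigma$ (coverage at a
fixed bound is strictly decreasing in $\sigma$, again bisection); it is the
generator of the acceptable-SD cutoff table
(`generate_cutoff_table()`). Means at or beyond a bound admit no positive
SD and are reported as infeasible, never dropped.

### Rounding conventions

Two deliberately conservative (upward) roundings are applied:

* inputs: $|\mu|$ and $\sigma$ are rounded **up** to the 0.05 m/s grid
  before the solve (`round_up_to_grid()`, e.g. 0.41 → 0.45, 0.47 → 0.50,
  exact multiples unchanged). Rounding the *absolute* mean keeps the
  criterion symmetric.
* display: the tabulated/reported bound `error85_display` is rounded up at
  0.01 m/s. The exact bound for (0.40, 0.45) is 0.87099 m/s; plain
  2-decimal rounding would print 0.87, while the published convention
  prints 0.88 — i.e. the smallest 2-decimal value whose coverage is at
  least 85%. The ceiling at 0.01 reproduces this and never understates the
  error.

Grading itself always uses the full-precision bound: good if
$E_{85} \le 1.0$ m/s, acceptable if $\le 1.5$ m/s, fail beyond. The 1.0 m/s
threshold is the minimum clinically important difference for cfPWV; 1.5
m/s aligns with single-device reproducibility.

```{r grade}
grade_device(difference_model(0.36, 0.44))
```

## Sample-size calculus

The observed proportion of participants within the tolerable error is a
binomial estimate; `margin_of_error()` returns the normal-approximation
(Wald) half-width $100\, z_{(1+c)/2} \sqrt{p(1-p)/n}$ in percentage
points, and `assured_lower_bound()` returns $100p$ minus it. The Wald form
is the default because it is the interval under which the design point
n = 85, p = 0.85, c = 0.90 yields the published pair (margin ≤ 7 points,
lower bound ≥ 78%); a Wilson-score half-width is available via
`method = "wilson"` for users who prefer a boundary-respecting interval.
Enrolling 90 to analyze 85 absorbs expected dropout
(`sample_size_plan()`).

## Measurement pairing

* **Simultaneous mode** (3 test + 3 reference readings): pair i compares
  $T_i$ with $R_i$ directly.
* **Sequential mode** (3 test + 4 reference readings): the comparator for
  $T_i$ is the mean of the two reference readings closest in time. Under
  the canonical interleaving R1 T1 R2 T2 R3 T3 R4 this yields
  mean(R1,R2), mean(R2,R3), mean(R3,R4). The full acquisition order and
  rest intervals of the protocol table are not reproduced here, so the
  interleaving is timestamp-driven with `canonical_order = TRUE` as an
  explicit fallback when timestamps are unavailable. When the
  second-closest distance is tied, the later of the tied readings is used
  — an arbitrary but deterministic and documented tie-break.

Differences are oriented test − reference throughout (the device under
test is judged against the reference). Cohort statistics use the sample SD
(n − 1) everywhere, including the two-value coefficient of variation
$100\,|m_1 - m_2|/(\sqrt{2}\,\bar m)$ — the protocol's "SD of 2
measurements divided by their average" with the n − 1 convention, which the
source text does not fix. Limits of agreement are mean ± 2 SD exactly (not
1.96 SD), matching the prescribed reporting. The Bland–Altman regression
fits participant-mean differences on participant-mean averages by OLS with
a two-sided t test on the slope; participant means (not the 9 individual
pairs) are used so that the regression acts on the same units as the error
definition.

## Cohort screening

Eligibility (`check_eligibility()`): adults ≥ 18 years; BMI < 40 kg/m²
(the ≥ 40 boundary is exclusionary — path-length measurement becomes
unreliable); sinus rhythm, not pacemaker dependent; no relevant stenosis
between sites; no severe aortic valve stenosis; palpable arteries; and no
measurement within the acute-effect window after vasoactive dosing. The
window length is not numerically specified by the protocol; the default is
24 h and configurable. Missing fields raise an error rather than passing
silently.

Composition (`check_composition()`): ≥ 85 complete of ≥ 90 enrolled;
reference-PWV spread quotas (≥ 5% ≤ 6 m/s, ≥ 5% ≥ 10 m/s, ≥ 20% ≥ 8 m/s,
cutoffs scaled by `scale_factor` for non-carotid-femoral beds); four age
bands — interpreted half-open as [18,30), [30,50), [50,70), [70,∞) from
the printed integer labels — each with ≥ 10 participants and ≥ 40% of each
sex. "Relatively even spread" across bands has no numeric criterion in the
protocol, so evenness is reported descriptively (min/max band-count ratio)
but only the explicit ≥ 10 rule can fail. The spread quotas are evaluated
on participant-level mean reference PWV by default ("readings" mode is
available by passing the individual readings via `pwv_values`).
Enrollment is carried as an `n_enrolled` attribute (or argument) so that an
analysis cohort of 85 can represent a study that enrolled 90.

Hemodynamic stability (`check_hemodynamic_stability()`): sequential
transit-time measurement assumes a steady state, so heart rate, systolic
and diastolic BP must each change by strictly less than 5% between before
and after readings. `run_validation()` applies this check to sequential
sessions only, since simultaneous acquisition does not rely on it.

## Waveform engine

`synthesize_waveform()` builds a pressure-like pulse as a truncated Fourier
series of a smooth beat template: a sin² upstroke of duration `rise_time`
(default 0.12 s) followed by an exponential diastolic decay (time constant
0.25 s) normalized to return exactly to the diastolic level at the period
boundary. Because the template is analytic, the intersecting-tangent foot
of the *continuous* beat has closed form — the tangent through the
maximum-slope point meets the diastolic level at
`rise_time × (1/2 − 1/π)` after upstroke onset — and this is the ground
truth returned with the waveform. Synthesis refuses sampling rates below
twice the highest retained harmonic; 50 harmonics are kept by default
(well above the 20 required for faithful foot morphology), and the record
starts with half a period of late diastole so the first beat has a usable
preceding minimum.

`detect_feet_intersecting_tangent()` localizes, per beat, the diastolic
minimum and the maximum upstroke slope on a cubic-spline-interpolated
signal evaluated at `resolution` (default 1 ms — subsample relative to the
8.3 ms interval at the 120 Hz minimum sampling rate), and intersects the
max-slope tangent with the horizontal through the minimum. The algorithm
name fixes the fiducial construction but not the localization details;
these choices (spline derivative for the slope, minimum over the
inter-peak window) are covered by fixtures with analytic ground truth. A
`subsample = FALSE` variant quantizes feet to the raw sample grid and
exists purely to measure quantization error. Beat segmentation runs on a
heavily smoothed copy (80 ms zero-phase moving average) so noise cannot
fragment beats; the analyzed signal is left raw by default, with a light
`smooth_window` (≈ 20 ms) recommended for noisy recordings.

`detect_feet_diastole_patching()` fits a quadratic to the late-diastolic
segment (default 80 ms) and a line to the 20–70% rising limb and
intersects them. The published description of diastole patching names the
idea but not a unique formulation; this variant is validated against the
package's own fixtures (agreement with the tangent method within 5 ms on
noiseless beats) and is not claimed equivalent to any specific external
implementation.

`transit_time_and_pwv()` matches proximal and distal feet by nearest onset
within half a cardiac period, requires ≥ 10 matched cardiac cycles
(beat-to-beat PWV variability makes shorter recordings unreliable),
rejects non-positive transit times, and reports PWV both at full precision
and rounded to 0.1 m/s as recorded in studies. Path lengths come from
`path_length()` (subtraction or 80%-of-direct methods), with a warning
helper when test and reference use different estimates.

## Study simulator

The simulator is the package's source of ground-truthed studies. Defaults
encode the recommended study conditions: 90 enrolled participants, even
age-band weights with uniform ages within bands, balanced sexes, and an
age-linear true-PWV model — intercept 4.5 m/s, +0.9 m/s per decade,
between-subject SD 1.0 m/s, floored at 3 m/s — chosen once as a realistic
cfPWV age gradient (≈ 6.7 m/s at 25, ≈ 11 m/s at 75). Device observation:
reference readings add Normal(0, 0.25²) noise to the truth; test readings
additionally carry a constant plus proportional bias. Noise is Gaussian
and homoscedastic to match the normative difference model; a proportional
bias setting exercises the Bland–Altman regression instead. Timestamps
follow the protocol order (matched in simultaneous mode; the canonical
interleaving in sequential mode), and before/after hemodynamics drift by
at most ±2% so simulated sessions are stable.

`quota_satisfying_cohort()` is deterministic and constructive: bands as
even as possible (all ≥ 10), alternating sexes within band, and the PWV
tails placed explicitly (5% at 5.5 m/s, 5% at 10.5 m/s, enough at 8.5 m/s
to reach the 20% quota). It models a study that enrolled five more than it
analyzed. Sizes below 40 are rejected with the binding constraint (4 bands
× ≥ 10).

What the simulator does **not** emulate: operator and repositioning
variability, heteroscedastic or heavy-tailed device noise, path-length
measurement error, arrhythmia, missing readings, or waveform-level device
behavior. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not device
performance on real patients.

## Numerical choices and problem sizes

* Bisections: tolerance 10⁻⁶ m/s; brackets $[0, |\mu|+10\sigma]$ (error
  bound) and adaptively grown upper bracket (max SD).
* Grid rounding uses a 10⁻⁹ relative guard so binary representations of
  exact multiples are unchanged.
* The test suite checks coverage with 10⁶ normal draws per model (±0.002),
  inverse consistency at 10⁻⁵, and parameter recovery over 200 simulated
  studies of n = 85 — sizes chosen to make Monte-Carlo error a small
  fraction of each tolerance while keeping the suite fast.
* Foot-detection fixtures use 12 beats at 60 bpm, sampled at 1 kHz
  (accuracy) and 120 Hz (quantization), with 50 harmonics.

## Known limitations

* The grading of a *study* inherits sampling noise in $(\hat\mu,
  \hat\sigma)$; the package reports the point grade, not a confidence
  statement about the grade.
* Sequential pairing assumes the canonical 3 + 4 structure; protocols with
  more readings would need a generalized matcher.
* The diastole-patching variant is internal-fixture-validated only.
* The checklist items are reconstructed from the reporting requirements at
  the granularity available in the main text and are marked extensible.
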