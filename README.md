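# pwvalidr

Statistical and procedural toolkit for **technical validation studies of
noninvasive arterial pulse wave velocity (PWV) devices**.

Arterial stiffness, measured as PWV (m/s), is an established biomarker of
cardiovascular risk. New PWV devices must be validated against a reference
standard before clinical use, and validation studies need a common
statistical yardstick to be comparable. `pwvalidr` implements that yardstick
end to end, for device manufacturers, clinical investigators running
validation studies, and methodologists auditing them.

## The model at the core

Per-participant mean differences between the device under test (T) and the
reference device (R) are modelled as

D ~ Normal(μ, σ²),  D = mean over 3 paired readings of (T − R)

The **tolerable-error bound** E₈₅ is the symmetric bound containing 85% of
the difference distribution,

P(|D| ≤ E₈₅) = 0.85,

solved numerically (bracketing bisection, 10⁻⁶ m/s tolerance). Before the
solve, |μ| and σ are each rounded **up** to 0.05 m/s precision
(conservative), and the tabulated/displayed bound is rounded up at 0.01
m/s. The device grade follows the tolerable-error thresholds:

| grade | criterion |
|---|---|
| good | E₈₅ ≤ 1.0 m/s |
| acceptable | 1.0 < E₈₅ ≤ 1.5 m/s |
| fail | E₈₅ > 1.5 m/s |

The sample-size calculus is the Wald binomial half-width
100·z₍₀.₉₅₎·√(p(1−p)/n): with n = 85 analyzable participants and an observed
tolerable-error proportion of 0.85, the margin of error is ≤ 7 percentage
points at 90% confidence, so the true probability of tolerable error is at
least 78%.

Around this core the package provides simultaneous/sequential measurement
pairing, Bland–Altman agreement analysis with mean ± 2 SD limits and a
difference-vs-average regression, stratified analyses, test–retest
precision (CV of duplicate measurements), participant eligibility and
cohort-composition quota checks, pressure-waveform foot detection
(intersecting tangent and diastole patching at subsample resolution) with
transit-time PWV computation, and a synthetic study simulator with known
ground truth.

## Worked example

```r
library(pwvalidr)

## grade a device that showed a mean difference of 0.36 m/s with SD 0.44 m/s
grade_device(difference_model(0.36, 0.44))
#> Device grading (85% tolerable-error criterion)
#>   rounded |mean difference|: 0.40 m/s
#>   rounded SD of difference:  0.45 m/s
#>   error85: 0.88 m/s
#>   grade:   good
```

The inputs round up to (0.40, 0.45); 85% of differences then fall within
±0.88 m/s, and because 0.88 ≤ 1.0 m/s the device passes with good accuracy.

```r
sample_size_plan()
#> Validation sample-size plan
#>   analysis n: 85 (enrol 90)
#>   target probability of tolerable error: 85%
#>   90% confidence margin of error: 6.4 points
#>   assured lower bound: 78.6%
```

A complete simulated study through the full pipeline:

```r
set.seed(1)
cfg <- simulation_config(n_participants = 90, mode = "sequential",
                         bias_constant = 0.36,
                         test_noise_sd = 0.539, reference_noise_sd = 0.539)
study <- simulate_study(cfg)
report <- run_validation(study$cohort, study$sessions,
  validation_config(software_version = "2.1.0", hardware_version = "rev B",
                    measurement_principle = "tonometry",
                    data_availability = "public"))
report
#> PWV device validation report
#>   sessions: 90 analyzed / 90 input (0 discarded)
#>   mean difference 0.323 m/s, SD 0.406 m/s -> error85 0.83 m/s, grade good
#>   composition violations: 0
#>   checklist: 11 pass / 0 fail / 0 n.a.
```

Here the simulator was configured with a true constant bias of 0.36 m/s
and reading noise chosen so participant-mean differences spread with SD
0.44 m/s; the study estimates (0.32, 0.41) are one realization of that
truth, and the pipeline grades, checks cohort quotas and fills the
reporting checklist in one pass. `render_bland_altman_plot(report$summary)`
draws the required agreement plot; `report_to_json(report, "report.json")`
writes the machine-readable report.

A thin command-line wrapper over the same functions ships in
`inst/cli/pwv-tool.R`:

```sh
Rscript inst/cli/pwv-tool.R grade --mean 0.36 --sd 0.44
Rscript inst/cli/pwv-tool.R simulate --out study.csv --seed 1
Rscript inst/cli/pwv-tool.R analyze --input study.csv --out report/
```

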