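# spo2delta

Directional parenclitic deviation analysis of oxygen saturation variability.

## The problem

Continuous pulse-oximetry (SpO2) signals fluctuate, and the *structure* of
those fluctuations — quantified with sample entropy (SampEn) — reflects how
actively the cardiorespiratory system is engaging with a physiological
challenge. Entropy alone is ambiguous, though: a low-entropy signal can mean
either a stable, unchallenged system or a rigid, decompensated one. The
resolution is to interpret entropy *relative to the prevailing hypoxic
challenge*. In healthy people, graded hypoxia produces an inverse linear
relationship between mean SpO2 (x) and SampEn (y): entropy rises as oxygen
availability falls. That regression line, fitted over a healthy
hypoxia-exposure reference population, becomes the normalisation anchor for
patients.

Each subject's **directional parenclitic deviation** is the signed
perpendicular distance of their (mean SpO2, SampEn) point from the reference
line `y = m·x + b`:

```
delta = (m·x − y + b) / sqrt(m² + 1)
```

No absolute value is taken. `delta > 0` means the point lies *below* the
line — lower-than-expected entropy for the observed saturation
(under-engaged regulation, as in sepsis or COPD); `delta < 0` means
higher-than-expected entropy (over-engaged or dysregulated control, as seen
in cirrhosis). The package evaluates delta as a prognostic marker with
survivor/non-survivor comparisons, Cox proportional-hazards models of
30-day ICU mortality (per-SD hazard ratios, proportional-hazards
diagnostics), ROC discrimination, and Bland–Altman agreement between
recording durations.

Because real ICU waveform databases are credential-restricted, the package
ships a first-class synthetic subsystem: MIX-style SpO2 signals (slow
sinusoid plus probabilistic noise replacement) with independently tunable
mean and entropy, emulated graded-hypoxia reference populations, and patient
cohorts with planted deviation structure and exponential-hazard survival
outcomes, so every stage of the pipeline is testable end to end.

## Who it is for

Researchers working on physiological time-series complexity and ICU risk
stratification who want a reproducible SpO2-variability pipeline: signal QC
and segmentation at 1 Hz, entropy computation, reference-based
normalisation, and cohort survival analysis — plus simulation machinery for
method development and power analysis.

## Worked example

```r
library(spo2delta)

# 1. Emulate a healthy graded-hypoxia reference experiment
#    (FiO2 21/17/14.5/12%, 12/12/12/11 subjects, final 8-min segments)
#    and fit the reference regression over the FiO2-level means.
ref  <- gen_reference_population(hypoxia_protocol(seed = 1))
line <- fit_reference(ref$table)
print(line)
#> <reference_line> SampEn = 2.5734 + -0.025056 * meanSpO2 (R^2 = 0.9921, 4 group_mean point(s))

# 2. Generate a sepsis-like cohort (n = 164, 34 non-survivors) with planted
#    deviation strata, and compare delta across survival groups.
cohort <- gen_patient_cohort(synthetic_cohort_spec(n = 164, seed = 2), line)
survivor_table(cohort, features = "delta")
#>       group feature n_survivor n_nonsurvivor mean_survivor sd_survivor
#> 1 synthetic   delta        130            34        0.0344      0.0933
#>   mean_nonsurvivor sd_nonsurvivor p_value
#> 1           0.0881          0.146 0.00953

# 3. Cox regression of 30-day mortality on delta, z-scored (per-SD hazard).
cox_fit(cohort, "delta", standardize = TRUE)
#> <cox_model_fit> n = 164, events = 34, ties = efron, loglik = -165.960
#>   term   beta     se hazard_ratio ci95_low ci95_high  p_value per_sd
#>  delta 0.4925 0.1774        1.636    1.156     2.317 0.005492   TRUE
```

The fitted line has negative slope (entropy rises as saturation falls) with
a near-perfect group-mean fit. In the simulated cohort, non-survivors carry
larger deviations than survivors (0.088 vs 0.034, P = 0.0095), and each SD
of delta multiplies the 30-day death hazard by 1.64.

For real data, the entry points are `read_spo2_csv()` → `qc_record()` →
`extract_segment()` → `multiscale_entropy()` → `batch_delta()`, or the
orchestrated `run_reference()` / `run_cohort()` (also exposed as a thin
command-line tool in `inst/cli/spo2delta.R` with subcommands `reference`,
`cohort` and `simulate`).

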