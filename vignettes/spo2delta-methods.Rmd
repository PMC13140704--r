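---
title: "Methods: entropy, the hypoxia reference line, and directional parenclitic deviation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy, the hypoxia reference line, and directional parenclitic deviation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spo2delta)
```

This vignette is the package's own account of its methods: the measures it
computes, the modelling assumptions behind them, the parameters a user can
reasonably touch, and the design decisions taken where the design was
genuinely open.

## Sample entropy of SpO2 signals

For a series $x_1,\dots,x_N$ sampled at 1 Hz, sample entropy
$\mathrm{SampEn}(m, r)$ is the negative natural logarithm of the
conditional probability that two templates of length $m$ that are close
remain close at length $m+1$:

$$\mathrm{SampEn} = -\ln\frac{A}{B},$$

where $B$ counts unordered pairs of $m$-length templates within Chebyshev
distance $t$ of one another, $A$ the same for $(m+1)$-length templates, both
over start positions $1,\dots,N-m$, self-matches excluded. Defaults are the
standard SpO2-variability settings $m = 2$, $r = 0.2$.

**Tolerance interpretation.** The literature this follows states $r = 0.2$
without fixing whether it is relative or absolute. We default to the
canonical reading, $t = r \times \mathrm{SD}(x)$ with the sample SD
(denominator $N-1$), and retain an `"absolute"` switch
(`entropy_params(tolerance_mode = "absolute")`, $t = r$ percentage points)
because the distinction is material for integer-percent monitor exports,
whose SDs are small and discrete. Both modes are first-class and tested.

**Degenerate cases.** A constant series has SD 0, hence $t = 0$; distance-0
matches still count, so SampEn is exactly 0 rather than an error. When no
template pair matches ($B = 0$) or no extended pair matches ($A = 0$), the
entropy is *undefined*: it is reported as `NA` with a reason code
(`no_m_matches` / `no_m1_matches`), no plug-in correction is applied, and
downstream deviation analysis excludes the subject with a logged
disposition. Series shorter than $m + 2$ samples raise a degenerate-input
error.

## Multiscale entropy

Multiscale analysis coarse-grains the series with non-overlapping window
means at scales $\tau = 1,\dots,5$ (output length $\lfloor N/\tau \rfloor$,
trailing remainder discarded) and computes SampEn at each scale, then
averages the defined per-scale values into one complexity summary. One
absolute tolerance, fixed from the scale-1 series, is reused at every scale
— the standard multiscale convention, which makes the per-scale profile
reflect temporal structure rather than the shrinking variance of the
coarse-grained series. Uncorrelated noise then shows a flat-to-decreasing
profile across scales, while structured physiological signals typically
rise; this contrast is what the profile is for. Scales too short to embed
become undefined entries, not exceptions, as long as scale 1 is computable.

The scale-1 value — not the 5-scale average — is the "SpO2 entropy" used
for deviation analysis; the multiscale profile is a complementary
randomness check.

## The healthy reference line

Healthy subjects exposed to stepwise normobaric hypoxia (FiO2 21, 17, 14.5,
12 %; the final 8 minutes of each exposure analysed) provide per-subject
$(\text{FiO2}, \bar x, \mathrm{SampEn})$ points. The reference line is the
ordinary least-squares regression of entropy on mean SpO2. Two fit modes
exist:

* `"group_mean"` (default): per-subject points are averaged within each
  FiO2 level and the line is fitted to the four level means, equally
  weighted. Level-mean fitting is what makes a near-perfect $R^2$
  attainable for a graded exposure protocol, and it is the mode the
  package's own simulations reproduce.
* `"per_subject"`: all individual points, kept for sensitivity analysis.

The line is serialisable to a small JSON config (slope, intercept, $R^2$,
n, mode), so patient analysis never needs the raw reference signals.

## Directional parenclitic deviation

Given the reference line $y = mx + b$, a subject at $(x, y)$ has

$$\delta = \frac{m x - y + b}{\sqrt{m^2 + 1}}.$$

This is the perpendicular point-to-line distance with its sign retained:
positive below the line (entropy deficit for the observed saturation),
negative above it (entropy excess). Two open choices were resolved as
follows:

* **Raw axes.** The formula is applied to raw percent/entropy coordinates
  with no prior standardisation of the axes; $\delta$ therefore carries the
  mixed units of that plane. Standardising the axes would change both the
  magnitude and the subject ranking whenever the cohort's x/y spreads
  differ, and nothing in the formula's definition calls for it.
* **Scale-1 entropy.** $\delta$ uses scale-1 SampEn as $y$, consistent with
  computing the reference line from single-scale entropy.

## Cohort evaluation

* **Group comparisons** use the two-sided pooled-variance Student's t-test
  (Welch available as a switch), significance at $P \le 0.05$, no
  multiple-testing correction.
* **Cox regression** of 30-day ICU mortality is fitted by maximum partial
  likelihood through the survival package. Efron tie handling is the
  default — day-resolution ICU times tie often and Efron is the more
  accurate approximation — with Breslow as a switch. Continuous predictors
  are z-scored on request so hazard ratios are per SD; binary predictors
  stay on their natural scale. CIs are $\exp(\beta \pm 1.96\,\mathrm{se})$.
  Constant or collinear covariate matrices raise non-identifiability
  errors; non-convergence and monotone-likelihood warnings are surfaced as
  flags on the fit rather than silent failures. Follow-up is capped at the
  horizon (30 days); transplant-counted-as-death is an input-coding
  convention applied at cohort assembly, not inside the model.
* **Proportional hazards** are checked with scaled Schoenfeld residuals:
  the per-covariate correlation with event-time rank, with the rank-
  transform score test p-value. The check is diagnostic only and never
  blocks a fit; with fewer than 3 events it is undefined with a reason.
* **Discrimination** uses the Mann–Whitney rank AUC with midrank tie
  handling and a Hanley–McNeil normal-approximation CI, applied to a
  model's linear predictor against 30-day status.
* **Duration agreement** (20-min vs 10-min recordings) uses Bland–Altman
  limits $\bar d \pm 1.96\,\mathrm{SD}(d)$ with strict-inequality outside
  counts.

## The synthetic subsystem

The generator exists so the entire pipeline is buildable and testable
without restricted ICU waveform data. What it emulates, and how:

* **Signals** are a MIX-style process: a slow sinusoid (default amplitude
  1.5 %, period 240 s) around the target mean, each sample independently
  replaced with probability $p$ by uniform noise (default half-width 3 %)
  centred on the same mean, clipped to $[0, 100]$ and optionally rounded to
  integer percent. The sinusoid-plus-replacement design was chosen over an
  AR(1) alternative because a single parameter maps near-monotonically onto
  SampEn over a wide range (roughly 0.06 at $p = 0$ to above 2 at $p = 1$
  for 20-min segments), which makes entropy calibration a one-dimensional
  inversion. The period is deliberately slow: a fast sinusoid leaves
  rising/falling phase ambiguities that put a high floor under the
  deterministic limit's entropy. Amplitudes shrink automatically near the
  saturation ceiling so clipping cannot bias the realised mean; at
  durations that cover whole sinusoid periods the realised mean sits within
  0.5 % of the target.
* **Entropy calibration** inverts a Monte-Carlo map: a fixed grid of
  probe $p$ values (denser at small $p$, where the response is steepest),
  20 generated signals per probe, isotonic clean-up, then linear
  interpolation. The map's probe seeds are internal constants, so it is
  deterministic, cached across calls, and independent of the caller's RNG
  stream — one map serves a whole simulated population, which is what keeps
  repeated-population simulations fast. For signal-level cohorts the
  initial calibrated $p$ is further refined against the subject's actual
  seeded realisation (a few Newton steps on the map's local slope), so the
  realised entropy matches the planted target to ~0.004 rather than to
  within Monte-Carlo noise.
* **The reference population** draws per-subject target means around a
  saturating FiO2 dose-response (97.7, 94.5, 90.5, 84.5 % at FiO2 21, 17,
  14.5, 12 — normoxia matching a typical healthy cohort mean) with 0.5 %
  between-subject SD, and entropy targets on an internal line
  $y = 2.80 - 0.0274 x$ with SD 0.015, so the emulated mean–entropy
  relationship is linear by construction and normoxic entropy sits near
  0.12. Reported points are *realised* values computed from the generated
  signals through the complexity module, not the planted targets.
* **Patient cohorts** plant deviations directly. In `feature_level` mode,
  entropy is set algebraically,
  $y = (m x + b) - \delta\sqrt{m^2+1}$, so recovering $\delta$ from
  $(x, y)$ is an exact round trip — the algebraic identity every
  deviation-recovery test rests on. In `signal_level` mode a signal is
  synthesised per subject with calibrated irregularity and the features are
  recomputed from it; entropy targets below the generator's deterministic
  floor (or above its noise ceiling) fall back to the nearest achievable
  value and are flagged per subject (`delta_fallback`), since a planted
  deviation distribution emulating real survivor strata inevitably asks a
  floor-limited generator for a few unattainable low-entropy targets.
  Default strata follow the sepsis survivor/non-survivor pattern
  (mean 0.0391 / 0.113, SD 0.0827 / 0.126, 130/34 split at $n = 164$).
* **Survival** is exponential with hazard
  $\lambda_0 \exp(\sum_k \beta_k z_k)$ over z-scored covariates, censored
  at 30 days (constant baseline hazard: closed-form sampling and
  unambiguous $\beta$ recovery), or — for fixed-margin comparisons —
  stratified outcomes with uniform event times. Defaults
  ($\lambda_0 = 0.02$/day) give roughly the event fraction of the emulated
  sepsis cohort.

**What the generator does not emulate.** No gas-exchange physiology, no
oximeter artefact or motion-noise models, no realistic autocorrelation
beyond the sinusoid, and clinical scores are drawn from simple
distributions rather than derived from labs. Passing tests therefore
demonstrate correctness of the *measures and models* under controlled
conditions — not that the generator's waveforms are physiologically
realistic, nor that effect sizes found here transfer to real cohorts.

## Numerical choices and degenerate inputs

* Template counting is exact (vectorised pairwise comparison, no
  approximate neighbour search); tests require equality with an $O(N^2)$
  enumeration oracle at $10^{-13}$.
* Out-of-range samples (outside $[0,100]$) break a valid run exactly as a
  missing second does; nothing is imputed. Duplicate or sub-second
  timestamps are rejected rather than repaired.
* Segment selection: `earliest` takes the first qualifying run's first
  samples (patient convention), `final` the last run's last samples
  (reference-exposure convention); every segment is a contiguous slice of
  the raw record.
* OLS is solved by `lm`; $R^2$ is defined as 1 when the total sum of
  squares is 0 (all-equal responses fitted exactly).
* The Cox linear algebra guards: at least one event, finite covariates, no
  constant columns, full column rank (checked by QR before fitting).
* Ties in AUC scores are handled by midranks (half-credit), matching the
  exhaustive pairwise definition.

## Problem sizes

The simulation-based checks run at sizes chosen to make their statistical
assertions stable while keeping the default suite quick: oracle equivalence
on 100 series of 60–300 samples; irregularity sweeps and scale-profile
trends over 50 seeds; Cox recovery over 200 replicates at $n = 500$;
power of the survivor comparison over 200 replicates at $n = 164$ (the
emulated sepsis cohort size); signal-level round trips at 16–24 subjects of
20-min signals.

## Known limitations

* SampEn counting is $O((N-m)^2)$ in time and memory; fine for the 8–20 min
  1 Hz segments the package targets, not intended for hour-scale records at
  full resolution.
* The calibration map is built at one probe mean (95 %). Under the
  relative-SD tolerance the map is essentially mean-invariant, but in
  absolute-tolerance or quantised modes calibration accuracy degrades away
  from the probe mean.
* Undefined-entropy subjects are excluded, not imputed; cohorts dominated
  by constant-saturation recordings will lose subjects accordingly.
* The per-subject fallback in signal-level generation truncates the planted
  deviation distribution at the generator's achievable entropy range;
  analyses of planted-vs-recovered deviations should exclude flagged
  subjects (the package reports them).
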