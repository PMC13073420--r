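---
title: "Quantifying pancreatic fat from dual-echo chemical-shift MRI: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pancreatic fat from dual-echo chemical-shift MRI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancfat)
```

## The problem

Pancreatic steatosis — pathological fat deposition in pancreatic tissue — is
quantified non-invasively with chemical-shift (Dixon) MRI: at an in-phase
echo time the water and fat magnetization vectors add, at an opposed-phase
echo time they subtract, and the pair of signal intensities encodes the fat
fraction of the voxel. Because the pancreas is small and mobile, the
practical protocol is region-of-interest (ROI) based: a reader places small
ROIs in the caput, corpus and cauda of the pancreas on dual-echo images, and
the analysis converts ROI signal pairs into relaxation-corrected fat
fractions, aggregates them to regional and whole-pancreas values, and
compares groups (for instance alcohol-exposed men versus non-drinkers,
stratified by age) on both fat *content* and fat *distribution*.

`pancfat` implements that full analysis chain, plus a synthetic-data module
that generates phantoms, subjects and raw ROI signal tables with the
statistical structure the analysis assumes, so every stage can be exercised
and tested without any imaging data.

## Signal model and fat-fraction correction

A T1-weighted spoiled dual-echo gradient-echo acquisition produces, for a
voxel with water and fat proton-density signals $w$ and $f$ sharing an
effective transverse relaxation time $T_2^*$,

$$SI_{ip} = (w\,a + f\,b)\, e^{-TE_{ip}/T_2^*}, \qquad
  SI_{op} = \lvert w\,a - f\,b\rvert\, e^{-TE_{op}/T_2^*},$$

where $a$ and $b$ are the steady-state factors of the spoiled sequence
evaluated at the water and fat longitudinal relaxation times,

$$a,b \;=\; \frac{\sin\alpha\,\bigl(1 - e^{-TR/T_{1_{w,f}}}\bigr)}
  {1 - \cos\alpha\, e^{-TR/T_{1_{w,f}}}}.$$

The inversion implemented by `fat_fraction_corrected()` removes both the T1
weighting and the differential $T_2^*$ decay of the two echoes:

$$FF = \frac{a\,(SI_{ip}\,e_y - SI_{op}\,e_x)}
  {SI_{ip}\,e_y\,(a+b) + SI_{op}\,e_x\,(b-a)},
  \qquad e_x = e^{-TE_{ip}/T_2^*},\; e_y = e^{-TE_{op}/T_2^*}.$$

Two design points deserve emphasis.

**The decay-factor pairing.** Each signal is multiplied by the *other*
echo's decay factor, which equalizes the $T_2^*$ weighting of the pair.
This pairing is the unique one for which the inversion is the exact inverse
of the forward model — substituting the forward expressions gives
$FF = f/(w+f)$ identically — and the test suite asserts both the round-trip
identity and that the swapped pairing breaks it.

**Magnitude images and the water-dominance bound.** Magnitude
reconstruction discards the sign of $w a - f b$. The inversion is therefore
exact only while the steady-state-weighted water term dominates, i.e. for
true fat fractions below $a/(a+b)$. With the default parameters (TR 80 ms,
flip 50°, $T_{1,\text{water}}$ 828 ms, $T_{1,\text{fat}}$ 382 ms) fat is
the brighter species ($b > a$) and the bound is about 36%, tightening to
about 33% at 90° and approaching 50% as the flip angle (hence T1
weighting) shrinks. Beyond the bound a magnitude pair is indistinguishable
from its water-dominant mirror; no flag can detect this from the data
alone. Pancreatic fat fractions in practice sit far below the bound.
`forward_dual_echo(..., magnitude = FALSE)` additionally simulates a
phase-sensitive reconstruction that keeps the signed opposed-phase signal,
for which the inversion is exact at any fat fraction; the property tests
use it to verify the algebra over the full sweep and the magnitude
convention within its validity region.

T1 values are not part of the acquisition protocol and must be assumed; the
defaults are 3 T literature values and every parameter of
`acquisition_params()` is configurable.

### T2* estimation

`estimate_t2star()` fits $\log$(signal) against echo time by least squares
on a multi-echo spoiled gradient-echo series (default TEs 2.46–7.38 ms at a
4° flip) and returns $-1/\text{slope}$. With fat present, successive echoes
alternate between in-phase and opposed-phase fat-water alignment, which
superimposes an oscillation on the decay; the default policy therefore uses
only the in-phase echoes (1st, 3rd, 5th), which share the same fat-water
phase. An `"all"` echoes policy is available for fat-free or
oscillation-free series. A fitted slope above $-10^{-10}$/ms is reported as
"no decay" rather than returned as an absurd $T_2^*$. The estimation
granularity (per ROI, per subject, or global) is the caller's choice;
`quantify_rois()` estimates per ROI when multi-echo columns are present and
otherwise uses a supplied scalar.

## Phantom calibration

A 15-vial fat-water emulsion phantom (0–14% fat in 1% steps, 9 ROIs per
vial) anchors the calculated fractions to known concentrations.
`fit_calibration()` regresses **actual on calculated** — deliberately so:
the phantom's actual concentration is error-free, making this inverse
calibration whose fitted line converts future calculated fractions directly
into actual ones. The model records its fitted domain and
`apply_calibration()` flags (but does not refuse) extrapolation, since
published calibration equations are routinely applied over ranges wider
than the phantom's; negative calibrated values are clamped to zero with a
flag.

The synthetic phantom (`gen_phantom()`) inverts a stored reference line
(slope 0.9679, intercept −3.6064) to place vial means on the predictor
grid. Its default noise placement is on the *response*: vial-level Gaussian
preparation error (SD 0.40%) on the actual concentration, plus per-ROI
jitter (SD 0.30%) on the calculated side whose vial-mean contribution is
negligible (SD 0.10%). This placement keeps the fitted slope unbiased and,
given the grid's spread, yields an expected $R^2$ of about 0.991. The
alternative placement — all error on the measured predictor — is exposed as
`noise_on = "predictor"` because it is the textbook errors-in-variables
situation: it attenuates the fitted slope (by roughly 1% at these noise
levels) and is useful for sensitivity analysis, but it is not the default
precisely because of that bias.

## ROI aggregation and heterogeneity indices

The measurement protocol is fixed: 9 ROIs per region (3 layers × 3), three
regions per subject, pancreatic ROI areas 40–60 mm², phantom ROI areas
80–100 mm². `region_ff()` is the arithmetic mean of the 9 calibrated ROI
fractions and enforces the count in strict mode (lenient mode averages what
is available, with a warning, and is never used in the package's own
validation runs). Per subject,

* the **whole-pancreas fat fraction** is the mean of the caput, corpus and
  cauda fractions, and
* the **regional range** $\Delta FF = FF_{max} - FF_{min}$ across the three
  regions indexes spatial heterogeneity.

$\Delta FF$ is computed at region-mean level per subject and summarized
across subjects as mean ± SD. Calibrated fractions are used (an affine
calibration scales $\Delta FF$ by its slope). The second heterogeneity
index, the between-subject **coefficient of variation** CV = SD/mean, is
computed per group and measure with the sample SD ($n-1$ denominator) —
the convention under which reported group CV tables are reproduced from
their means and SDs. Internally all fractions are kept at full precision;
rendered tables round to 2 decimals (fat fractions) and 3 decimals (CV).

## Cohort statistics

* **Grouping.** Age bands are half-open — [20, 30), [30, 40), [40, 50) —
  with [50, 70] closed; the pooled 20–50 aggregate is the union of the
  three younger bands. The bands' printed labels overlap (20~30, 30~40) so
  a convention had to be chosen; 30 falling into 30–40 is the documented
  one. Ages outside [20, 70] are rejected.
* **Location comparisons** use one-way ANOVA (`anova_oneway()`), computed
  through a linear-model fit and verified in the tests against an explicit
  sum-of-squares oracle and against $F = t^2$ for two groups. Normality is
  annotated beforehand with `check_normality()` (Shapiro–Wilk); the
  annotation gates nothing, since the parametric analysis is the declared
  one.
* **Dispersion comparisons** use a two-sample test for equality of
  coefficients of variation. The literature offers several "u tests";
  Miller's asymptotic z-test was chosen as the default because it needs
  only (CV, n) per group — the form in which dispersion tables are
  published — with the pooled-CV variance formula documented in
  `cv_u_test()`. A bootstrap alternative (`cv_bootstrap_test()`) is
  provided for raw data. Which exact procedure produced published CV
  p-values is generally not recoverable from a paper's text; this package
  treats the choice as its own and documents it.
* **Reliability** is the two-way mixed-effects, absolute-agreement,
  single-measure intraclass correlation ICC(A,1), computed from the two-way
  ANOVA mean squares and cross-checked in the tests against an independent
  mean-squares oracle.
* **No multiple-testing correction** is applied: comparisons are reported
  per-test at two-sided α = 0.05, matching the analysis design the package
  replicates; users wanting family-wise control can feed the comparison
  JSON to `p.adjust()`.

`compare_abstinence()` lays out alcohol-exposed subjects by drinking status
(current drinkers, abstainers < 1 year, abstainers 1–2 years, plus the
pooled abstainers column), split by age 20–50 versus 50–70, and tests the
three base strata by one-way ANOVA within each split.

## The synthetic cohort generator

`gen_cohort()` draws each (age band × exposure) group from
`default_cohort_design()`, which carries the reference conditions: group
sizes 32/36/35/31/37/39/38/34 (142 controls + 140 alcohol-exposed), the
per-region fat-fraction means and SDs of each group, and the cohort-wide
drinking-status split 79/31/30 apportioned proportionally across the
alcohol groups (21/7/8, 17/7/7, 22/9/8, 19/8/7).

Regional fractions are drawn as

$$FF_{ir} = \mu_r + \sqrt{\max(s_r^2 - \sigma_h^2,\,0)}\; Z_i
  + \sigma_h\, Z_{ir},$$

with $Z_i$ shared across a subject's regions and $Z_{ir}$ independent: each
region's marginal SD reproduces the design value $s_r$ while
$\sigma_h$ ("`sigma_region`") controls between-region heterogeneity and
hence $\Delta FF$. Gaussian marginals were chosen because the replicated
analysis reports normality holding; values are truncated at 0, a deviation
that affects well under 1% of draws at the default parameters and is
counted in the `n_truncated` attribute.

$\sigma_h$ is a generative parameter no summary table states directly. For
the four groups with a reported group-mean $\Delta FF$ (controls and
drinkers aged 40+: 1.12, 1.35, 2.34, 2.89%) it was calibrated once, by
root-finding on the Monte-Carlo expectation of the three-value range under
the full model above (the shared term contributes to the range too, because
its per-region scales differ), giving 0.607, 0.713, 1.313 and 1.623%; these
are frozen in the design table. Groups without a reported range get
0.6 × the smallest regional SD, a homogeneous-pancreas default. The
heterogeneity inflation in drinkers thus switches on at age 40, matching
`heterogeneity_onset_age` in `default_generator_config()`.

One inconsistency in the reference conditions is worth recording: the
reported 20–50 alcohol aggregate (whole-pancreas 6.07%) is not the
n-weighted mean of the three sub-band rows that parameterize the generator
(5.87% from 36/31/39 subjects at 5.00/6.55/6.14%). A generator faithful to
the sub-band rows therefore produces a 20–50 alcohol aggregate near 5.87,
about 0.2 below the printed aggregate; the control side is consistent
(2.86 vs 2.94). The package keeps the sub-band parameterization and reports
the discrepancy rather than adjusting any row to force agreement.

`gen_roi_signals()` optionally deepens the simulation to raw signals: 9
ROIs per region with fat-fraction jitter (SD 0.30%), dual-echo signals from
the forward model at a shared $T_2^*$ of 25 ms, additive Gaussian signal
noise (SD 1% of the noiseless signal), and a five-echo multi-echo series
(with the fat-water phase alternation) for per-ROI $T_2^*$ estimation.
Additive Gaussian noise on magnitude signals is an approximation: true
magnitude noise is Rician and the two coincide only at moderate-to-high
SNR, so very low-signal regimes are deliberately out of scope. The
generator also does not emulate field inhomogeneity, reader variability in
ROI placement, partial-volume contamination, or covariates (BMI, glycemia)
beyond the group labels — so passing tests validate the computational
pipeline under its stated statistical model, not the acquisition physics or
reader behaviour of a real study.

## Determinism and problem sizes

All generators take explicit seeds and are byte-reproducible under them;
`run_study()` routes every source of randomness through a single seed and
records it in the run manifest. The package's own validation runs use
desk-scale replication chosen to keep Monte-Carlo error well below the
tolerances being asserted: 50 phantom replicates for calibration recovery,
20 cohort replicates for group-mean recovery, 100 seeds for the null
calibration of the drinking-status comparison and the normality check, and
1000 replicates for the $T_2^*$ noise-bias check.

## Known limitations

* Single-$T_2^*$, single-fat-peak signal model; no multi-peak fat spectrum,
  no field-map estimation, no k-space or coil effects.
* Magnitude inversion is silently mirrored above the $a/(a+b)$ bound (an
  information-theoretic limit of the dual-echo magnitude method, not an
  implementation choice); the package documents the bound instead of
  guessing.
* The calibration is strictly linear over the phantom's range; no
  per-scanner or nonlinear calibration management.
* CSV-level signals only: no DICOM/NIfTI ingestion and no image
  segmentation — ROI tables are upstream inputs.
* Within-subject ROI variance in the generator is an assumption (no
  per-subject raw data exist to constrain it); its default is stated, not
  inferred.
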