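# pancfat

Quantification of pancreatic fat from T1- and T2\*-corrected dual-echo
chemical-shift (Dixon) MRI, and analysis of its spatial heterogeneity.

Pancreatic steatosis — fat deposition in pancreatic tissue — is measured
non-invasively by exploiting the resonance-frequency difference between
water and fat protons: at an in-phase echo time their signals add, at an
opposed-phase echo time they subtract. `pancfat` is aimed at imaging
researchers who work with ROI-level dual-echo measurements of the pancreas
(caput, corpus, cauda) and need a tested, reproducible pipeline from raw
signal pairs to group-level statistics, including the cross-sectional
design that compares alcohol-exposed men with non-drinkers across age
bands.

## What it computes

The core inversion converts an in-phase/opposed-phase magnitude pair into a
relaxation-corrected fat fraction,

```
FF = a (SI_ip e_y − SI_op e_x) / [ SI_ip e_y (a + b) + SI_op e_x (b − a) ]
```

with steady-state factors `a, b = sin α (1 − e^(−TR/T1_{w,f})) /
(1 − cos α e^(−TR/T1_{w,f}))` at the water/fat T1s and decay factors
`e_x = e^(−TE_ip/T2*)`, `e_y = e^(−TE_op/T2*)`; T2\* comes from a
log-linear fit of a multi-echo series. Around it the package provides:

* the forward signal model (`forward_dual_echo()`), exact inverse of the
  correction, for simulation and round-trip validation;
* phantom calibration (`fit_calibration()`, `apply_calibration()`) against
  a 15-level fat-water emulsion phantom, with domain/extrapolation flags;
* ROI-to-subject aggregation (`quantify_rois()`): 9 ROIs per region, three
  regions, whole-pancreas mean and the regional range ΔFF = FF_max −
  FF_min as a spatial-heterogeneity index;
* cohort statistics (`summarize_groups()`, `anova_oneway()`,
  `cv_u_test()` — Miller's asymptotic test for CV equality —,
  `icc_intraobserver()`, `check_normality()`, `compare_abstinence()`);
* synthetic-data generators (`gen_phantom()`, `gen_cohort()`,
  `gen_roi_signals()`) reproducing the reference study conditions, and a
  one-call study replication (`run_study()`).

See the vignette (`vignettes/pancfat-methods.Rmd`) for the models,
assumptions and design decisions.

## Worked example

```r
library(pancfat)

# 1. Calibrate against a (here: simulated) 15-vial fat-water phantom
phantom <- gen_phantom(seed = 42)
fit_calibration(phantom)
#> Phantom calibration: actual = 0.9568 * calculated -3.2665
#>   domain (calculated FF): 3.58 to 18.13 %
#>   R^2 = 0.9910 (Pearson r = 0.9955, n = 15 vials)

# 2. Replicate the full study design synthetically
study <- run_study(seed = 42)
study$ff_table[study$ff_table$age_band %in% c("20-50", "50-70"), ]
#>  age_band exposure   n         caput        corpus         cauda         whole      delta_ff
#>     20-50  alcohol 106 5.65 +/- 1.92 6.01 +/- 1.97 5.34 +/- 1.63 5.67 +/- 1.66 1.77 +/- 0.93
#>     20-50  control 104 2.62 +/- 0.75 2.88 +/- 0.77 2.83 +/- 0.83 2.78 +/- 0.67 0.86 +/- 0.48
#>     50-70  alcohol  34 9.62 +/- 3.82 9.90 +/- 3.15 9.01 +/- 2.69 9.51 +/- 3.01 2.61 +/- 1.37
#>     50-70  control  38 6.26 +/- 1.80 6.50 +/- 1.55 5.81 +/- 1.36 6.19 +/- 1.47 1.32 +/- 0.68

study$comparisons[["anova_whole_20-50"]]
#> one-way ANOVA: statistic = 272.1, p = 1.221e-39
```

The fat-fraction table shows mean ± SD per group in percent: exposed
subjects carry roughly double the pancreatic fat of age-matched controls,
older groups sit above younger ones, and the regional range `delta_ff` of
exposed subjects over 40 is inflated (heterogeneous fat distribution). The
ANOVA line is the headline alcohol-vs-control comparison of whole-pancreas
fat in the pooled 20–50 band.

Quantification also runs from raw per-ROI signals (27 ROIs per subject,
per-ROI T2\* estimation from the multi-echo columns, optional calibration):

```r
cfg <- default_generator_config()
rois <- gen_roi_signals(gen_cohort(seed = 7)[1:2, ], cfg, seed = 8)
res <- run_quantify(rois, cfg$acquisition,
                    calibration = calibration_model(1, 0, 0, 100))
res$profiles
#>              subject_id ff_caput ff_corpus ff_cauda ff_whole delta_ff
#>  s001_control_20-30_001     3.21      4.46     3.63     3.77     1.25
#>  s002_control_20-30_002     2.15      2.27     1.06     1.82     1.21
```

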