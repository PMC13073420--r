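#' Reference cohort conditions for the synthetic-data generator
#'
#' `default_cohort_design()` returns the study conditions the generator
#' emulates: eight (age band x exposure) groups with their sample sizes and
#' the per-region fat-fraction means and standard deviations (in %) reported
#' for a male alcohol-exposure cross-sectional cohort (142 controls, 140
#' alcohol-exposed), together with
#' \itemize{
#'   \item `sigma_region`: the between-region (within-subject) SD in %,
#'     which controls spatial heterogeneity. For the four groups with a
#'     reported regional fat-fraction range (controls and drinkers aged
#'     40 and over) it is calibrated once so the expected subject-level
#'     `delta_ff` matches the reported group means (1.12, 1.35, 2.34,
#'     2.89%); for the remaining groups it defaults to 0.6 x the smallest
#'     regional SD.
#'   \item `abst_*`: the drinking-status quota of each alcohol group
#'     (current drinkers / abstainers < 1 year / abstainers 1-2 years),
#'     apportioned proportionally so the cohort-wide split is 79/31/30.
#' }
#'
#' @return A data frame with one row per group.
#' @examples
#' default_cohort_design()
#' @export
default_cohort_design <- function() {
  d <- read.csv(text = "
age_band,exposure,n,mean_caput,sd_caput,mean_corpus,sd_corpus,mean_cauda,sd_cauda,sigma_region,abst_current,abst_lt1y,abst_1to2y
20-30,control,32,2.55,0.42,2.91,0.66,2.35,0.62,0.252,NA,NA,NA
20-30,alcohol,36,4.95,1.10,5.42,1.50,4.51,0.96,0.576,21,7,8
30-40,control,35,2.54,0.60,3.08,0.77,3.11,0.84,0.360,NA,NA,NA
30-40,alcohol,31,6.31,1.42,7.38,1.98,6.00,1.67,0.852,17,7,7
40-50,control,37,3.18,0.79,2.81,0.67,3.13,0.63,0.607,NA,NA,NA
40-50,alcohol,39,6.20,2.25,6.30,2.15,5.90,1.71,1.313,22,9,8
50-70,control,38,5.97,1.54,6.36,1.31,5.75,1.26,0.713,NA,NA,NA
50-70,alcohol,34,9.34,3.54,9.26,2.77,8.88,2.88,1.623,19,8,7
", stringsAsFactors = FALSE)
  d
}

#' Reference group fat-fraction statistics
#'
#' The reported per-group mean and SD (%) of the caput, corpus, cauda and
#' whole-pancreas fat fractions for the reference cohort, including the
#' pooled 20-50 aggregate rows. The regional cells of the eight primary
#' groups parameterize [default_cohort_design()]; the whole-pancreas and
#' aggregate rows are derived quantities reported alongside them.
#'
#' @return A data frame with columns `age_band`, `exposure`, `n`, and
#'   `mean_*` / `sd_*` for the four measures.
#' @export
reference_fat_table <- function() {
  read.csv(text = "
age_band,exposure,n,mean_caput,sd_caput,mean_corpus,sd_corpus,mean_cauda,sd_cauda,mean_whole,sd_whole
20-30,control,32,2.55,0.42,2.91,0.66,2.35,0.62,2.61,0.60
20-30,alcohol,36,4.95,1.10,5.42,1.50,4.51,0.96,5.00,1.07
30-40,control,35,2.54,0.60,3.08,0.77,3.11,0.84,2.91,0.66
30-40,alcohol,31,6.31,1.42,7.38,1.98,6.00,1.67,6.55,1.57
40-50,control,37,3.18,0.79,2.81,0.67,3.13,0.63,3.09,0.57
40-50,alcohol,39,6.20,2.25,6.30,2.15,5.90,1.71,6.14,1.61
20-50,control,104,3.02,0.95,3.03,0.81,2.77,0.84,2.94,0.62
20-50,alcohol,106,5.96,1.89,6.59,1.80,5.63,1.62,6.07,1.59
50-70,control,38,5.97,1.54,6.36,1.31,5.75,1.26,5.98,1.00
50-70,alcohol,34,9.34,3.54,9.26,2.77,8.88,2.88,9.14,2.22
", stringsAsFactors = FALSE)
}

#' Reference coefficient-of-variation table
#'
#' The reported between-subject coefficients of variation of the regional
#' and whole-pancreas fat fractions, per (age band, exposure) group, for
#' the same cohort as [default_cohort_design()]. Useful for checking that
#' CV computed as SD/mean from the reported group means and SDs reproduces
#' the reported dispersion table.
#'
#' @return A data frame with columns `age_band`, `exposure`, `caput`,
#'   `corpus`, `cauda`, `whole`.
#' @export
reference_cv_table <- function() {
  read.csv(text = "
age_band,exposure,caput,corpus,cauda,whole
20-30,control,0.164,0.227,0.262,0.230
20-30,alcohol,0.223,0.278,0.213,0.214
30-40,control,0.236,0.249,0.269,0.226
30-40,alcohol,0.225,0.268,0.279,0.240
40-50,control,0.249,0.238,0.201,0.185
40-50,alcohol,0.362,0.342,0.289,0.262
50-70,control,0.258,0.206,0.219,0.167
50-70,alcohol,0.379,0.299,0.324,0.243
", stringsAsFactors = FALSE)
}

#' Reference phantom calibration
#'
#' The published linear calibration between calculated and actual fat
#' fractions from a 15-level fat-water phantom:
#' `actual = 0.9679 * calculated - 3.6064`, valid for calculated fractions
#' between 3.26 and 18.36%, with R^2 = 0.991.
#'
#' @return A [calibration_model()].
#' @export
reference_calibration <- function() {
  calibration_model(slope = 0.9679, intercept = -3.6064,
                    domain_low = 3.26, domain_high = 18.36,
                    r_squared = 0.991, pearson_r = sqrt(0.991),
                    n_points = 15L)
}

#' Generator configuration
#'
#' Noise levels and physical constants used by the synthetic-data
#' generators, with the package defaults:
#' \describe{
#'   \item{sigma_phantom_response}{Vial-level Gaussian error (%) on the
#'     phantom's actual fat concentration (preparation error); 0.40 yields
#'     the reference calibration's R^2 of about 0.991 over the 0-14% grid.}
#'   \item{sigma_phantom_roi}{Per-ROI jitter (%) of the phantom's calculated
#'     fat fraction around the vial mean.}
#'   \item{sigma_roi_ff}{Per-ROI fat-fraction jitter (%) around a subject's
#'     regional mean when raw signals are generated.}
#'   \item{si_noise_frac}{Additive Gaussian noise on magnitude signals, as a
#'     fraction of the noiseless signal.}
#'   \item{t2_star}{Shared effective T2* (ms) of simulated tissue.}
#'   \item{s0}{Total proton-density signal scale (arbitrary units).}
#'   \item{heterogeneity_onset_age}{Age (years) from which alcohol-exposed
#'     groups carry the inflated between-region SD in the default design.}
#'   \item{acquisition}{An [acquisition_params()] object.}
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A list of class `generator_config`.
#' @export
default_generator_config <- function(...) {
  cfg <- list(sigma_phantom_response = 0.40, sigma_phantom_roi = 0.30,
              sigma_roi_ff = 0.30, si_noise_frac = 0.01,
              t2_star = 25, s0 = 100, heterogeneity_onset_age = 40,
              acquisition = acquisition_params())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown generator config field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  bad <- vapply(cfg[grep("^si(gma)?_", names(cfg))],
                function(v) is.numeric(v) && v < 0, logical(1))
  if (any(bad)) stop("noise SDs must be non-negative")
  structure(cfg, class = "generator_config")
}
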