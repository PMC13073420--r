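#' Generate a synthetic fat-water phantom
#'
#' Simulates the 15-level fat-water dilution phantom used to calibrate
#' calculated fat fractions: vials at actual concentrations 0-14% in 1%
#' steps, each measured by 9 ROIs (3 layers x 3 ROIs). The generating law
#' is the inverse of a stored linear calibration: a vial's mean calculated
#' fraction sits at `(actual - intercept) / slope`.
#'
#' Noise placement (`noise_on`):
#' \describe{
#'   \item{`"response"` (default)}{Vial preparation error: the realized
#'     actual concentration deviates from nominal by Gaussian error of SD
#'     `sigma_response`, while ROI replicates jitter around the vial's
#'     calculated mean with SD `sigma_phantom_roi`. Regressing actual on
#'     calculated then recovers the stored slope without attenuation.}
#'   \item{`"predictor"`}{All error on the measured (calculated) side: per
#'     ROI SD `3 * sigma_response / slope`, so the vial mean of 9 ROIs has
#'     SD `sigma_response / slope`. This is the classical
#'     errors-in-predictor situation and attenuates the fitted slope; it is
#'     provided for sensitivity analysis, not as the default.}
#' }
#'
#' @param config A [default_generator_config()]; `sigma_phantom_response`
#'   and `sigma_phantom_roi` are used.
#' @param seed Integer seed (`NULL` to leave the RNG alone).
#' @param model The generating [calibration_model()]; defaults to
#'   [reference_calibration()].
#' @param noise_on `"response"` or `"predictor"`, see above.
#' @return A data frame with one row per ROI: `vial_id`, `actual_ff`,
#'   `layer`, `roi_index`, `area` (mm^2, 80-100), `calculated_ff` (%).
#'   Ready for [fit_calibration()].
#' @examples
#' ph <- gen_phantom(seed = 1)
#' fit_calibration(ph)
#' @export
gen_phantom <- function(config = default_generator_config(), seed = NULL,
                        model = reference_calibration(),
                        noise_on = c("response", "predictor")) {
  noise_on <- match.arg(noise_on)
  if (!is.null(seed)) set.seed(seed)
  nominal <- 0:14
  grid <- (nominal - model$intercept) / model$slope
  n_roi <- 9L
  if (noise_on == "response") {
    actual <- nominal + stats::rnorm(length(nominal),
                                     0, config$sigma_phantom_response)
    calc <- rep(grid, each = n_roi) +
      stats::rnorm(length(grid) * n_roi, 0, config$sigma_phantom_roi)
  } else {
    actual <- nominal
    calc <- rep(grid, each = n_roi) +
      stats::rnorm(length(grid) * n_roi, 0,
                   3 * config$sigma_phantom_response / abs(model$slope))
  }
  data.frame(
    vial_id = rep(sprintf("vial_%02d", nominal), each = n_roi),
    actual_ff = rep(actual, each = n_roi),
    layer = rep(rep(1:3, each = 3L), times = length(nominal)),
    roi_index = rep(1:3, times = 3L * length(nominal)),
    area = stats::runif(length(grid) * n_roi, 80, 100),
    calculated_ff = calc)
}

apportion_strata <- function(n, quotas = c(current = 79, `<1y` = 31,
                                           `1-2y` = 30)) {
  p <- quotas / sum(quotas)
  base <- floor(n * p)
  rem <- n * p - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  base[extra] <- base[extra] + 1L
  rep(names(quotas), times = base)
}

#' Generate synthetic subjects for one cohort group
#'
#' Draws per-subject regional fat fractions for a single (age band,
#' exposure) group as
#' `ff_region = mean_region + sd_subject_region * Z_subject +
#' sigma_region * Z_region`, where `Z_subject` is shared across the three
#' regions of a subject (between-subject variation) and `Z_region` is
#' independent per region (between-region heterogeneity). The subject-level
#' SD is `sqrt(max(sd_region^2 - sigma_region^2, 0))`, so each region's
#' marginal SD reproduces the design value (floored at the heterogeneity SD
#' when that exceeds the marginal SD). Fractions are truncated at 0.
#'
#' @param spec A one-row slice of [default_cohort_design()].
#' @param seed Integer seed (`NULL` to leave the RNG alone).
#' @param n Number of subjects; defaults to `spec$n`.
#' @return A subject-profile data frame (see [subject_profile()]) with an
#'   attribute `n_truncated` counting fractions clamped at 0.
#' @export
gen_subject <- function(spec, seed = NULL, n = spec$n) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(spec) == 1L, n > 0)
  mu <- c(spec$mean_caput, spec$mean_corpus, spec$mean_cauda)
  s <- c(spec$sd_caput, spec$sd_corpus, spec$sd_cauda)
  sig_h <- spec$sigma_region
  s_subj <- sqrt(pmax(s^2 - sig_h^2, 0))
  z_subj <- stats::rnorm(n)
  ff <- sapply(1:3, function(r)
    mu[r] + s_subj[r] * z_subj + stats::rnorm(n, 0, sig_h))
  ff <- matrix(ff, nrow = n)
  n_trunc <- sum(ff < 0)
  ff[ff < 0] <- 0
  band <- strsplit(spec$age_band, "-")[[1L]]
  age <- stats::runif(n, as.numeric(band[1L]), as.numeric(band[2L]))
  abst <- if (spec$exposure == "alcohol") {
    q <- c(spec$abst_current, spec$abst_lt1y, spec$abst_1to2y)
    if (anyNA(q)) apportion_strata(n)
    else rep(c("current", "<1y", "1-2y"), times = q)[seq_len(n)]
  } else rep("none", n)
  out <- data.frame(
    subject_id = sprintf("%s_%s_%03d", spec$exposure, spec$age_band,
                         seq_len(n)),
    age = age, exposure = spec$exposure, abstinence = abst,
    ff_caput = ff[, 1L], ff_corpus = ff[, 2L], ff_cauda = ff[, 3L],
    ff_whole = rowMeans(ff),
    delta_ff = apply(ff, 1L, max) - apply(ff, 1L, min))
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Generate a full synthetic cohort
#'
#' Draws every group of a cohort design with [gen_subject()] and stacks the
#' profiles. Under the default design this yields 282 subjects (142
#' controls, 140 alcohol-exposed; drinking-status split 79/31/30) with the
#' group sizes, regional means and SDs of the reference conditions.
#'
#' @param design A cohort design data frame, see [default_cohort_design()].
#' @param seed Integer seed controlling all randomness of the cohort.
#' @return A subject-profile data frame; attribute `n_truncated` counts
#'   fractions clamped at 0 across the cohort.
#' @examples
#' cohort <- gen_cohort(seed = 1)
#' table(cohort$exposure)
#' @export
gen_cohort <- function(design = default_cohort_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- design[design$n > 0, , drop = FALSE]
  parts <- lapply(seq_len(nrow(design)),
                  function(i) gen_subject(design[i, ], seed = NULL))
  out <- do.call(rbind, parts)
  out$subject_id <- sprintf("s%03d_%s", seq_len(nrow(out)), out$subject_id)
  rownames(out) <- NULL
  attr(out, "n_truncated") <- sum(vapply(parts, attr, numeric(1),
                                         "n_truncated"))
  out
}

#' Generate raw ROI signal tables for subject profiles
#'
#' Expands subject profiles into the per-ROI signal table the quantification
#' stage consumes: for each region, 9 ROIs whose in-phase/opposed-phase
#' magnitude signals come from [forward_dual_echo()] at the region's fat
#' fraction (with per-ROI fat-fraction jitter `sigma_roi_ff` and additive
#' signal noise `si_noise_frac`), plus a five-echo multi-echo series for
#' per-ROI T2* estimation, simulated with the multi-echo sequence's flip
#' angle and TR.
#'
#' @param profiles A subject-profile data frame ([subject_profile()] /
#'   [gen_cohort()]).
#' @param config A [default_generator_config()].
#' @param seed Integer seed (`NULL` to leave the RNG alone).
#' @return A data frame with one row per ROI (27 per subject): `subject_id`,
#'   `age`, `exposure`, `abstinence`, `roi_id`, `region`, `layer`, `area`
#'   (mm^2, 40-60), `si_ip`, `si_op`, `te_1..te_5`, `signal_1..signal_5`.
#' @export
gen_roi_signals <- function(profiles, config = default_generator_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$acquisition
  n_roi <- 9L
  regions <- pancreas_regions
  rows <- profiles[rep(seq_len(nrow(profiles)), each = 3L * n_roi), ]
  rows$region <- rep(rep(regions, each = n_roi), times = nrow(profiles))
  rows$layer <- rep(rep(1:3, each = 3L), times = 3L * nrow(profiles))
  rows$roi_id <- paste0(rows$subject_id, "_", rows$region, "_l", rows$layer,
                        "_", rep(1:3, times = 3L * 3L * nrow(profiles)))
  rows$area <- stats::runif(nrow(rows), 40, 60)
  region_ff_col <- ff_measures[rows$region]
  true_ff <- vapply(seq_len(nrow(rows)),
                    function(i) rows[[region_ff_col[i]]][i], numeric(1))
  roi_ff <- pmax(true_ff + stats::rnorm(nrow(rows), 0, config$sigma_roi_ff),
                 0) / 100

  fat <- roi_ff * config$s0
  water <- (1 - roi_ff) * config$s0
  comp <- tissue_composition(water, fat, config$t2_star)
  sig <- forward_dual_echo(comp, p)
  noisy <- function(x) x + stats::rnorm(length(x), 0,
                                        config$si_noise_frac * x)
  rows$si_ip <- noisy(sig$si_ip)
  rows$si_op <- noisy(sig$si_op)

  # multi-echo series: echoes alternate in/opposed fat-water phase
  aw <- steady_state_factor(p$t1_water, p$multi_echo_tr, p$multi_echo_flip)
  ab <- steady_state_factor(p$t1_fat, p$multi_echo_tr, p$multi_echo_flip)
  for (k in seq_along(p$multi_echo_tes)) {
    te <- p$multi_echo_tes[k]
    amp <- if (k %% 2L == 1L) water * aw + fat * ab
           else abs(water * aw - fat * ab)
    rows[[paste0("te_", k)]] <- te
    rows[[paste0("signal_", k)]] <- noisy(amp * t2star_decay(te,
                                                             config$t2_star))
  }
  keep <- c("subject_id", "age", "exposure", "abstinence", "roi_id",
            "region", "layer", "area", "si_ip", "si_op",
            paste0("te_", seq_along(p$multi_echo_tes)),
            paste0("signal_", seq_along(p$multi_echo_tes)))
  rownames(rows) <- NULL
  rows[keep]
}
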