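run_manifest <- function(stage, seed = NULL, config = NULL, inputs = NULL,
                         outputs = NULL, warnings = character()) {
  structure(list(stage = stage, seed = seed, config = config,
                 inputs = inputs, outputs = outputs,
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 elapsed_s = NA_real_, warnings = warnings),
            class = "run_manifest")
}

#' Write a run manifest to JSON
#'
#' Every pipeline run produces a manifest recording the configuration
#' snapshot, seed, timings and warnings, so that runs with identical
#' config and seed can be recognized as describing identical outputs.
#'
#' @param manifest A manifest as attached to pipeline results.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Quantify subject fat profiles from raw signals, end to end
#'
#' Chains the quantification stages -- relaxation-corrected inversion of the
#' dual-echo signals (with per-ROI T2* estimation when multi-echo columns
#' are present), optional phantom calibration, and ROI-to-subject
#' aggregation -- and attaches a run manifest.
#'
#' @inheritParams quantify_rois
#' @return A list with `profiles` (one row per subject, see
#'   [subject_profile()]) and `manifest`.
#' @export
run_quantify <- function(rois, params = acquisition_params(),
                         calibration = NULL, t2_star = 25,
                         echoes = "in_phase", strict = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  warn <- character()
  profiles <- withCallingHandlers(
    quantify_rois(rois, params, calibration = calibration,
                  t2_star = t2_star, echoes = echoes, strict = strict),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  manifest <- run_manifest(
    stage = "quantify", seed = NULL,
    config = list(acquisition = unclass(params),
                  calibration = if (!is.null(calibration))
                    unclass(calibration),
                  t2_star = t2_star, echoes = echoes, strict = strict),
    inputs = list(n_rois = nrow(rois),
                  n_subjects = length(unique(rois$subject_id))),
    outputs = list(n_profiles = nrow(profiles)), warnings = warn)
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  list(profiles = profiles, manifest = manifest)
}

#' Run a full synthetic study
#'
#' Generates a phantom and fits its calibration, generates a cohort,
#' summarizes it into the study's table layouts (group fat fractions,
#' coefficients of variation, drinking-status comparison), and runs the
#' study's tests: alcohol-vs-control one-way ANOVA per age band (and the
#' 20-50 aggregate) on the whole-pancreas fat fraction, CV equality u-tests
#' per band and measure, normality checks, and the drinking-status ANOVA.
#' All randomness flows from `seed`; identical seed and configuration give
#' identical reports.
#'
#' @param design Cohort design, see [default_cohort_design()].
#' @param config Generator configuration, see [default_generator_config()].
#' @param seed Integer seed.
#' @return A list with `profiles`, `calibration`, `summaries` (long format),
#'   `ff_table`, `cv_table` (rendered wide tables), `abstinence`
#'   (see [compare_abstinence()]), `comparisons` (named list of
#'   `comparison_result`), `normality`, and `manifest`.
#' @examples
#' study <- run_study(seed = 1)
#' study$ff_table
#' @export
run_study <- function(design = default_cohort_design(),
                      config = default_generator_config(), seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  warn <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  set.seed(seed)
  phantom <- gen_phantom(config, seed = NULL)
  calibration <- fit_calibration(phantom)
  profiles <- gen_cohort(design, seed = NULL)
  summaries <- collect(summarize_groups(profiles))

  bands <- unique(summaries$age_band)
  comparisons <- list()
  for (band in bands) {
    sub <- profiles[assign_age_band(profiles$age) %in%
                      (if (band == "20-50") c("20-30", "30-40", "40-50")
                       else band), ]
    if (length(unique(sub$exposure)) < 2L) next
    comparisons[[paste0("anova_whole_", band)]] <-
      anova_oneway(sub$ff_whole, sub$exposure)
    for (m in c("caput", "corpus", "cauda", "whole")) {
      s <- summaries[summaries$age_band == band & summaries$measure == m, ]
      if (nrow(s) == 2L)
        comparisons[[paste0("cv_u_", m, "_", band)]] <- cv_u_test(
          s$cv[s$exposure == "alcohol"], s$n[s$exposure == "alcohol"],
          s$cv[s$exposure == "control"], s$n[s$exposure == "control"])
    }
  }
  normality <- lapply(split(profiles$ff_whole,
                            list(assign_age_band(profiles$age),
                                 profiles$exposure)),
                      function(v) if (length(v) >= 3L && stats::var(v) > 0)
                        check_normality(v))
  abstinence <- collect(compare_abstinence(profiles))

  manifest <- run_manifest(
    stage = "study", seed = seed,
    config = list(design = design,
                  generator = unclass(config)[setdiff(names(config),
                                                      "acquisition")],
                  acquisition = unclass(config$acquisition)),
    inputs = list(n_groups = nrow(design)),
    outputs = list(n_subjects = nrow(profiles),
                   n_truncated = attr(profiles, "n_truncated"),
                   n_comparisons = length(comparisons)),
    warnings = warn)
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  list(profiles = profiles, calibration = calibration,
       summaries = summaries, ff_table = render_ff_table(summaries),
       cv_table = render_cv_table(summaries),
       abstinence = abstinence, comparisons = comparisons,
       normality = Filter(Negate(is.null), normality),
       manifest = manifest)
}

#' Serialize comparison results to JSON
#'
#' @param comparisons A named list of `comparison_result` objects (e.g.
#'   `run_study()$comparisons`).
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  jsonlite::write_json(
    lapply(comparisons, function(x)
      list(test = x$test_name, statistic = x$statistic,
           p_value = x$p_value)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
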