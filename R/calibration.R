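#' Construct a phantom calibration model
#'
#' A linear map from calculated (relaxation-corrected, in percent) to actual
#' fat fraction, as obtained by regressing the known fat concentrations of a
#' fat-water phantom on the fractions the imaging pipeline calculates for
#' them. Usually produced by [fit_calibration()]; constructing one directly
#' is useful to apply published calibration equations.
#'
#' @param slope Dimensionless regression slope.
#' @param intercept Intercept (% fat fraction).
#' @param domain_low,domain_high Calculated-FF range (%) over which the model
#'   was fitted; applications outside it are flagged as extrapolation.
#' @param r_squared,pearson_r Fit statistics (optional for hand-built models).
#' @param n_points Number of vials behind the fit.
#' @return An object of class `calibration_model`.
#' @examples
#' # a published pancreatic calibration equation
#' calibration_model(0.9679, -3.6064, domain_low = 3.26, domain_high = 18.36)
#' @export
calibration_model <- function(slope, intercept, domain_low, domain_high,
                              r_squared = NA_real_, pearson_r = NA_real_,
                              n_points = NA_integer_) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            domain_low < domain_high)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("`r_squared` must lie in [0, 1]")
  if (!is.na(r_squared) && !is.na(pearson_r) &&
      abs(r_squared - pearson_r^2) > 1e-8)
    stop("`r_squared` must equal `pearson_r` squared")
  structure(
    list(slope = slope, intercept = intercept,
         domain_low = domain_low, domain_high = domain_high,
         r_squared = r_squared, pearson_r = pearson_r,
         n_points = n_points),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Phantom calibration: actual = %.4f * calculated %+.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  domain (calculated FF): %.2f to %.2f %%\n",
              x$domain_low, x$domain_high))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.4f (Pearson r = %.4f, n = %d vials)\n",
                x$r_squared, x$pearson_r, as.integer(x$n_points)))
  invisible(x)
}

#' Fit the phantom calibration regression
#'
#' Ordinary least squares of the known (actual) fat concentration on the
#' calculated fat fraction, across the vials of a fat-water phantom. The
#' regression direction is deliberately actual ~ calculated: the phantom's
#' actual concentration is (near) error-free, so this is inverse calibration
#' whose fitted line converts future calculated fractions directly into
#' actual ones.
#'
#' @param phantom A data frame with columns `actual_ff` and `calculated_ff`
#'   (both in %). Rows may be individual ROI measurements; they are averaged
#'   per vial first, using `vial_id` if present, otherwise `actual_ff`, as
#'   the vial key.
#' @return A [calibration_model()] with slope, intercept, R^2, Pearson r,
#'   the fitted domain (range of observed vial-mean calculated FF) and the
#'   number of vials.
#' @examples
#' ph <- data.frame(actual_ff = 0:14,
#'                  calculated_ff = (0:14 + 3.6064) / 0.9679)
#' fit_calibration(ph)
#' @export
fit_calibration <- function(phantom) {
  stopifnot(is.data.frame(phantom),
            all(c("actual_ff", "calculated_ff") %in% names(phantom)))
  key <- if ("vial_id" %in% names(phantom)) phantom$vial_id
         else phantom$actual_ff
  x <- tapply(phantom$calculated_ff, key, mean)
  y <- tapply(phantom$actual_ff, key, mean)
  if (length(unique(round(x, 12))) < 3L)
    stop("calibration requires at least 3 vials with distinct calculated FF")
  if (stats::var(x) == 0) stop("zero variance in calculated FF")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  calibration_model(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    domain_low = min(x), domain_high = max(x),
    r_squared = r^2, pearson_r = r, n_points = length(x))
}

#' Apply a calibration model to calculated fat fractions
#'
#' Evaluates `slope * x + intercept`. Inputs outside the model's fitted
#' domain are still converted but flagged as extrapolation; negative results
#' are clamped to 0 and flagged. Flags never abort a pipeline run.
#'
#' @param ff_calculated Calculated fat fractions (%), vectorized.
#' @param model A [calibration_model()].
#' @return A data frame with columns `ff_calibrated` (%), `extrapolated` and
#'   `clamped` (logical flags).
#' @examples
#' m <- calibration_model(0.9679, -3.6064, 3.26, 18.36)
#' apply_calibration(c(10, 2), m)
#' @export
apply_calibration <- function(ff_calculated, model) {
  stopifnot(inherits(model, "calibration_model"),
            is.numeric(ff_calculated))
  y <- model$slope * ff_calculated + model$intercept
  clamped <- y < 0
  data.frame(
    ff_calibrated = pmax(y, 0),
    extrapolated = ff_calculated < model$domain_low |
      ff_calculated > model$domain_high,
    clamped = clamped)
}

#' Serialize a calibration model to and from JSON
#'
#' @param model A [calibration_model()].
#' @param path JSON file path.
#' @return `read_calibration()` returns a `calibration_model`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$slope, x$intercept, x$domain_low, x$domain_high,
                    r_squared = x$r_squared %||% NA_real_,
                    pearson_r = x$pearson_r %||% NA_real_,
                    n_points = x$n_points %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
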