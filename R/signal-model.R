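#' Steady-state amplitude of a spoiled gradient-echo sequence
#'
#' For an ideally spoiled gradient-echo sequence the steady-state transverse
#' magnetization available at excitation is
#' \deqn{A(T_1) = \frac{\sin\alpha\,(1 - E_1)}{1 - \cos\alpha\, E_1},
#'   \qquad E_1 = e^{-TR/T_1}.}
#' Evaluated at the water and fat T1 values this gives the relative
#' T1 weighting of the two species (the `a` and `b` factors of the corrected
#' fat-fraction formula).
#'
#' @param t1 Longitudinal relaxation time (ms), > 0. Vectorized.
#' @param tr Repetition time (ms), > 0.
#' @param flip_angle Flip angle (degrees), in (0, 90].
#' @return Dimensionless factor in (0, 1], strictly decreasing in `t1`.
#' @examples
#' steady_state_factor(828, tr = 80, flip_angle = 50)  # water at 3 T
#' @export
steady_state_factor <- function(t1, tr, flip_angle) {
  if (any(t1 <= 0)) stop("`t1` must be positive")
  if (any(tr <= 0)) stop("`tr` must be positive")
  if (any(flip_angle <= 0 | flip_angle > 90))
    stop("`flip_angle` must be in (0, 90] degrees")
  a <- flip_angle * pi / 180
  e1 <- exp(-tr / t1)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Monoexponential T2* signal decay factor
#'
#' `exp(-te / t2_star)`: the fraction of transverse magnetization surviving
#' to the echo under effective transverse relaxation.
#'
#' @param te Echo time (ms), >= 0. Vectorized.
#' @param t2_star Effective transverse relaxation time (ms), > 0.
#' @return Dimensionless factor in (0, 1].
#' @export
t2star_decay <- function(te, t2_star) {
  if (any(te < 0)) stop("`te` must be non-negative")
  if (any(t2_star <= 0)) stop("`t2_star` must be positive")
  exp(-te / t2_star)
}

#' Water/fat tissue composition
#'
#' Proton-density-weighted water and fat magnetizations sharing a single
#' effective T2*. The true fat fraction of the composition is
#' `fat / (water + fat)`.
#'
#' @param water,fat Signal densities in arbitrary units, >= 0 (not both 0).
#' @param t2_star Shared effective T2* (ms), > 0.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(water, fat, t2_star) {
  stopifnot(length(water) == length(fat))
  if (any(water < 0) || any(fat < 0))
    stop("signal densities must be non-negative")
  if (any(water + fat == 0)) stop("water + fat must be positive")
  if (any(t2_star <= 0)) stop("`t2_star` must be positive")
  structure(list(water = water, fat = fat, t2_star = t2_star),
            class = "tissue_composition")
}

#' Simulate dual-echo magnitude signals for a water/fat mixture
#'
#' Forward model for in-phase and opposed-phase magnitude images of a
#' spoiled dual-echo gradient-echo acquisition:
#' \deqn{SI_{ip} = (w a + f b)\, e^{-TE_{ip}/T_2^*}, \qquad
#'       SI_{op} = |w a - f b|\, e^{-TE_{op}/T_2^*},}
#' where `a` and `b` are the steady-state factors at the water and fat T1.
#' Magnitude images cannot carry sign, hence the absolute value in the
#' opposed-phase signal; downstream inversion assumes water dominance.
#'
#' With magnitude reconstruction the sign of `w a - f b` is lost: once the
#' fat term dominates the steady-state-weighted signal (true fat fraction
#' above `a / (a + b)`), a magnitude pair is indistinguishable from its
#' water-dominant mirror and the inversion returns the mirrored solution.
#' `magnitude = FALSE` simulates a phase-sensitive reconstruction that keeps
#' the signed opposed-phase signal, for which the inversion is exact at any
#' fat fraction.
#'
#' @param comp A [tissue_composition()].
#' @param params An [acquisition_params()].
#' @param magnitude Simulate magnitude images (default)? If `FALSE` the
#'   opposed-phase signal keeps its sign (phase-sensitive reconstruction).
#' @return A data frame with columns `si_ip` and `si_op` (arbitrary units).
#' @examples
#' p <- acquisition_params()
#' forward_dual_echo(tissue_composition(90, 10, t2_star = 25), p)
#' @export
forward_dual_echo <- function(comp, params, magnitude = TRUE) {
  stopifnot(inherits(comp, "tissue_composition"),
            inherits(params, "acquisition_params"))
  a <- steady_state_factor(params$t1_water, params$tr, params$flip_angle)
  b <- steady_state_factor(params$t1_fat, params$tr, params$flip_angle)
  diff <- comp$water * a - comp$fat * b
  si_ip <- (comp$water * a + comp$fat * b) *
    t2star_decay(params$te_ip, comp$t2_star)
  si_op <- (if (magnitude) abs(diff) else diff) *
    t2star_decay(params$te_op, comp$t2_star)
  data.frame(si_ip = si_ip, si_op = si_op)
}

#' Estimate T2* from a multi-echo gradient-echo series
#'
#' Fits `log(signal)` against echo time by least squares and returns
#' `-1 / slope`. With fat present, signals at alternating echoes oscillate as
#' fat and water move in and out of phase; the default `echoes = "in_phase"`
#' policy therefore uses only the in-phase echoes (the 1st, 3rd, 5th, ... of
#' a series whose first echo is in phase), which share the same fat-water
#' phase and decay purely with T2*. `echoes = "all"` uses every echo.
#'
#' @param tes Echo times (ms), strictly increasing, length >= 2.
#' @param signals Magnitude signals at each echo; all selected signals
#'   must be > 0.
#' @param echoes Echo-selection policy, `"in_phase"` (default) or `"all"`.
#' @return Estimated T2* (ms).
#' @examples
#' tes <- c(2.46, 3.69, 4.92, 6.15, 7.38)
#' estimate_t2star(tes, 100 * exp(-tes / 20))
#' @export
estimate_t2star <- function(tes, signals, echoes = c("in_phase", "all")) {
  echoes <- match.arg(echoes)
  stopifnot(length(tes) == length(signals))
  sel <- if (echoes == "in_phase") seq(1L, length(tes), by = 2L)
         else seq_along(tes)
  if (length(sel) < 2L) stop("need at least 2 echoes to estimate T2*")
  tes <- tes[sel]; signals <- signals[sel]
  if (any(signals <= 0))
    stop("all selected signals must be positive for log-linear T2* fitting")
  fit <- stats::lm.fit(cbind(1, tes), log(signals))
  slope <- fit$coefficients[[2L]]
  if (slope >= -1e-10)
    stop("no decay: fitted log-signal slope is non-negative, T2* undefined")
  -1 / slope
}

#' T1/T2*-corrected fat fraction from dual-echo signals
#'
#' Inverts the dual-echo magnitude signal pair into a fat fraction,
#' correcting both the T1 weighting of the spoiled gradient-echo sequence
#' and the differential T2* decay of the two echoes:
#' \deqn{FF = \frac{a\,(SI_{ip} e_y - SI_{op} e_x)}
#'   {SI_{ip} e_y (a + b) + SI_{op} e_x (b - a)},}
#' with `a`, `b` the steady-state factors at the water and fat T1,
#' `e_x = exp(-te_ip / t2_star)` and `e_y = exp(-te_op / t2_star)`. This
#' pairing (each echo's signal multiplied by the *other* echo's decay
#' factor) equalizes the T2* weighting of the two signals and is the unique
#' pairing for which inverting [forward_dual_echo()] returns the true fat
#' fraction.
#'
#' With magnitude signals the inversion assumes a water-dominant voxel: it
#' is exact while the steady-state-weighted water term exceeds the fat term,
#' i.e. for true fat fractions below `a / (a + b)` (about 36% at the default
#' 50 degree flip angle; approaching 50% as T1 weighting vanishes). Beyond
#' that bound a magnitude pair carries no sign information and the mirrored
#' solution is returned. Signed (phase-sensitive) opposed-phase signals
#' invert exactly at any fat fraction and may be passed directly. Raw
#' values outside `[0, 1]` (possible under noise) are clamped and flagged.
#'
#' @param si_ip,si_op In-phase and opposed-phase signals (vectorized);
#'   `si_ip` must be positive. `si_op` is a magnitude by convention but may
#'   be negative for phase-sensitive reconstructions.
#' @param t2_star Effective T2* (ms) shared by fat and water; scalar or one
#'   value per signal pair.
#' @param params An [acquisition_params()].
#' @return A data frame with columns `ff` (clamped fat fraction,
#'   dimensionless in `[0, 1]`), `ff_raw` (unclamped) and `out_of_range`
#'   (logical flag).
#' @examples
#' p <- acquisition_params()
#' sig <- forward_dual_echo(tissue_composition(90, 10, 25), p)
#' fat_fraction_corrected(sig$si_ip, sig$si_op, t2_star = 25, params = p)
#' @export
fat_fraction_corrected <- function(si_ip, si_op, t2_star, params) {
  stopifnot(inherits(params, "acquisition_params"),
            length(si_ip) == length(si_op))
  if (any(si_ip <= 0)) stop("`si_ip` must be positive")
  a <- steady_state_factor(params$t1_water, params$tr, params$flip_angle)
  b <- steady_state_factor(params$t1_fat, params$tr, params$flip_angle)
  e_x <- t2star_decay(params$te_ip, t2_star)
  e_y <- t2star_decay(params$te_op, t2_star)
  num <- a * (si_ip * e_y - si_op * e_x)
  den <- si_ip * e_y * (a + b) + si_op * e_x * (b - a)
  if (any(den == 0))
    stop("degenerate signal pair: corrected fat-fraction denominator is zero")
  ff_raw <- num / den
  out <- ff_raw < 0 | ff_raw > 1
  data.frame(ff = pmin(pmax(ff_raw, 0), 1), ff_raw = ff_raw,
             out_of_range = out)
}
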