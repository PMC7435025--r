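#' Kinetic parameters of the adiabatic tissue-homogeneity model
#'
#' Bundles the five voxel-level parameters of the impulse retention function
#' (IRF): tissue perfusion `F` (ml/min/100g), bolus arrival time `t0` (s),
#' minimal transit time `minTT` (s), extraction fraction `E` (dimensionless,
#' in \[0, 1\]) and excretion rate `k` (1/s).
#'
#' @param F Tissue perfusion, ml/min/100g. Must be positive.
#' @param t0 Bolus arrival time, s. Must be non-negative.
#' @param minTT Minimal transit time, s. Must be positive.
#' @param E Extraction fraction in \[0, 1\].
#' @param k Excretion rate, 1/s. Must be non-negative.
#' @return An object of class `irf_params` (a named list).
#' @examples
#' irf_params(F = 300, t0 = 2, minTT = 6, E = 0.4, k = 0.15)
#' @export
irf_params <- function(F, t0, minTT, E, k) {
  vals <- c(F = F, t0 = t0, minTT = minTT, E = E, k = k)
  check_finite_numeric(vals, "irf_params")
  if (F <= 0) stop_invalid("`F` must be positive")
  if (t0 < 0) stop_invalid("`t0` must be non-negative")
  if (minTT <= 0) stop_invalid("`minTT` must be positive")
  if (E < 0 || E > 1) stop_invalid("`E` must lie in [0, 1]")
  if (k < 0) stop_invalid("`k` must be non-negative")
  structure(list(F = F, t0 = t0, minTT = minTT, E = E, k = k),
            class = "irf_params")
}

#' @export
print.irf_params <- function(x, ...) {
  cat(sprintf(
    "IRF parameters: F = %g ml/min/100g, t0 = %g s, minTT = %g s, E = %g, k = %g 1/s\n",
    x$F, x$t0, x$minTT, x$E, x$k))
  invisible(x)
}

as_irf_params <- function(x) {
  if (inherits(x, "irf_params")) return(x)
  x <- as.list(x)
  irf_params(x$F, x$t0, x$minTT, x$E, x$k)
}

#' Evaluate the impulse retention function
#'
#' The adiabatic tissue-homogeneity IRF is piecewise: zero before bolus
#' arrival, a vascular plateau of height `F/6000` (perfusion converted from
#' ml/min/100g to 1/s, assuming unit tissue density) for
#' `t0 <= t < t0 + minTT`, and an extraction tail
#' `(F/6000) * E * exp(-k * (t - t0 - minTT))` afterwards. The function is
#' right-continuous at both breakpoints.
#'
#' @param params An [irf_params()] object.
#' @param t Time(s) since injection, s. Vectorized; must be non-negative.
#' @return Retention values in 1/s, same length as `t`.
#' @examples
#' p <- irf_params(300, 2, 6, 0.4, 0.15)
#' irf_evaluate(p, c(1, 4, 8))
#' @export
irf_evaluate <- function(params, t) {
  params <- as_irf_params(params)
  check_finite_numeric(t, "t")
  if (any(t < 0)) stop_invalid("`t` must be non-negative")
  irf_eval_cpp(t, params$F, params$t0, params$minTT, params$E, params$k)
}

#' Convolution forward model for a tissue concentration curve
#'
#' Predicts the tissue contrast-enhancement (TC) curve as the causal
#' rectangle-rule convolution of the arterial input function with the IRF:
#' `TC(t_i) = dt * sum_{j <= i} AIF(t_j) * IRF(t_i - t_j)`.
#'
#' @param params An [irf_params()] object.
#' @param aif Arterial input function, mM, one value per frame.
#' @param dt Frame interval, s.
#' @return Predicted TC curve, mM, same length as `aif`.
#' @examples
#' aif <- generate_aif(aif_spec())
#' tc <- forward_model(irf_params(150, 3, 6, 0.4, 0.15), aif)
#' @export
forward_model <- function(params, aif, dt = 1) {
  params <- as_irf_params(params)
  check_curve(aif, dt, "aif")
  as.numeric(forward_model_cpp(aif, dt, params$F, params$t0, params$minTT,
                               params$E, params$k))
}

#' Acquisition parameters of the saturation-recovery signal model
#'
#' @param delay_time Saturation-recovery delay TD, s.
#' @param r1 Longitudinal relaxivity of the contrast agent, 1/s/mM.
#'   Default 4.0 (gadoteridol at 3 T).
#' @param R10 Pre-contrast longitudinal relaxation rate, 1/s.
#'   Default 1/1.4 (resting skeletal muscle at 3 T).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(delay_time = 0.3, r1 = 4.0, R10 = 1 / 1.4) {
  vals <- c(delay_time = delay_time, r1 = r1, R10 = R10)
  check_finite_numeric(vals, "acquisition_params")
  if (any(vals <= 0)) stop_invalid("acquisition parameters must be strictly positive")
  structure(list(delay_time = delay_time, r1 = r1, R10 = R10),
            class = "acquisition_params")
}

as_acquisition_params <- function(x) {
  if (inherits(x, "acquisition_params")) return(x)
  x <- as.list(x)
  acquisition_params(x$delay_time, x$r1, x$R10)
}

#' Convert measured signal to tracer concentration
#'
#' Inverts the saturation-recovery signal model
#' `S / PD = 1 - exp(-TD * (R10 + r1 * C))`. Concentrations that invert to
#' negative values (pre-contrast noise below baseline) are clamped to 0.
#'
#' @param signal Measured signal intensity (non-negative). Vectorized.
#' @param proton_density Proton-density signal from the long-TR reference
#'   scan, same units as `signal`. Scalar or same length as `signal`.
#' @param acq An [acquisition_params()] object.
#' @return Tracer concentration, mM.
#' @export
signal_to_concentration <- function(signal, proton_density,
                                    acq = acquisition_params()) {
  acq <- as_acquisition_params(acq)
  check_finite_numeric(signal, "signal")
  check_finite_numeric(proton_density, "proton_density")
  if (any(signal < 0)) stop_invalid("`signal` must be non-negative")
  if (any(proton_density <= 0)) stop_invalid("`proton_density` must be positive")
  ratio <- signal / proton_density
  if (any(ratio >= 1)) {
    rlang::abort("signal/proton_density ratio >= 1: saturated, unphysical signal",
                 class = "dceperf_saturation_error")
  }
  conc <- (-log(1 - ratio) / acq$delay_time - acq$R10) / acq$r1
  pmax(conc, 0)
}

#' Convert tracer concentration to measured signal
#'
#' Exact inverse of [signal_to_concentration()]:
#' `S = PD * (1 - exp(-TD * (R10 + r1 * C)))`, monotone increasing in `C`.
#'
#' @param concentration Tracer concentration, mM (non-negative). Vectorized.
#' @param proton_density Proton-density signal.
#' @param acq An [acquisition_params()] object.
#' @return Signal intensity, same units as `proton_density`.
#' @export
concentration_to_signal <- function(concentration, proton_density,
                                    acq = acquisition_params()) {
  acq <- as_acquisition_params(acq)
  check_finite_numeric(concentration, "concentration")
  if (any(concentration < 0)) stop_invalid("`concentration` must be non-negative")
  proton_density * (1 - exp(-acq$delay_time * (acq$R10 + acq$r1 * concentration)))
}
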