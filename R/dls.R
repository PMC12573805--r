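## Multi-angle DLS: cumulants fit of g2(tau)-1, decay rate vs q^2
## regression with zero intercept, Stokes-Einstein sizing and PDI.

#' Construct a DLS autocorrelation curve
#'
#' Holds one measured `g2(tau) - 1` curve plus the optical and solvent
#' metadata needed to convert its decay rate into a diffusion
#' coefficient.  Defaults (532 nm laser, water refractive index 1.33,
#' 25 C, 0.89 mPa s) are explicit, overridable configuration.
#'
#' @param lag Delay times, seconds, strictly increasing, length >= 10.
#' @param g2m1 Corresponding `g2 - 1` values.
#' @param angle Scattering angle, degrees.
#' @param wavelength Laser wavelength in vacuo, nm.
#' @param refractive_index Medium refractive index.
#' @param temperature Absolute temperature, K.
#' @param viscosity Solvent dynamic viscosity, Pa s.
#' @return Object of class `correlation_curve`.
#' @export
correlation_curve <- function(lag, g2m1, angle, wavelength = 532,
                              refractive_index = 1.33,
                              temperature = 298.15, viscosity = 0.89e-3) {
  if (length(lag) != length(g2m1)) .stopf("lag and g2m1 lengths differ")
  if (length(lag) < 10) .stopf("a curve needs at least 10 points")
  if (any(lag <= 0) || any(diff(lag) <= 0)) .stopf("lag must be positive and strictly increasing")
  if (any(!is.finite(g2m1))) .stopf("g2m1 must be finite")
  structure(list(lag = as.numeric(lag), g2m1 = as.numeric(g2m1),
                 angle = angle, wavelength = wavelength,
                 refractive_index = refractive_index,
                 temperature = temperature, viscosity = viscosity),
            class = "correlation_curve")
}

#' Scattering vector magnitude for light scattering
#'
#' `q = 4 pi n sin(theta / 2) / lambda`, in 1/nm.
#'
#' @param angle Scattering angle, degrees, in `(0, 180]`.
#' @param wavelength Laser wavelength in vacuo, nm.
#' @param refractive_index Medium refractive index.
#' @return Scattering vector in 1/nm.
#' @examples
#' scattering_vector(90, 532, 1.33)
#' @export
scattering_vector <- function(angle, wavelength = 532, refractive_index = 1.33) {
  if (any(angle <= 0) || any(angle > 180)) .stopf("angle must be in (0, 180] degrees")
  if (any(wavelength <= 0) || any(refractive_index <= 0)) {
    .stopf("wavelength and refractive index must be > 0")
  }
  4 * pi * refractive_index * sin(angle * pi / 360) / wavelength
}

#' Cumulants fit of a DLS autocorrelation curve
#'
#' Fits `g2(tau) - 1 = B + beta * (exp(-gamma_bar tau) (1 + mu2 tau^2 / 2))^2`
#' by unweighted nonlinear least squares, where `B ~ 0` is the baseline,
#' `beta` (close to 1) the coherence factor, `gamma_bar` the mean decay
#' rate and `mu2` the second cumulant (variance of the decay-rate
#' distribution).  Initial values: `B` from the tail mean, `beta` from the
#' first point, `gamma_bar` from a log-linear fit of the early decay,
#' `mu2 = 0`.
#'
#' @param curve A [correlation_curve()].
#' @param truncate When `TRUE`, lag points beyond where the decayed signal
#'   falls below 1% of `beta` are dropped before fitting.
#' @return Object of class `cumulants_fit` with fields `B0`, `beta`,
#'   `gamma_bar` (1/s), `mu2` (1/s^2), `pdi = mu2 / gamma_bar^2` and the
#'   parent curve metadata (`angle`, optics).
#' @export
fit_cumulants <- function(curve, truncate = FALSE) {
  stopifnot(inherits(curve, "correlation_curve"))
  tau <- curve$lag; y <- curve$g2m1
  if (y[1] <= y[length(y)]) .stopf("no visible decay (first value <= last)")
  n <- length(y)
  B0 <- mean(tail(y, max(5L, round(0.1 * n))))
  beta0 <- max(y[1] - B0, 1e-3)
  f <- pmax((y - B0) / beta0, 0)
  g1 <- sqrt(f)
  sel <- which(g1 > 0.2 & g1 < 0.95)
  gamma0 <- if (length(sel) >= 2) {
    max(-coef(lm(log(g1[sel]) ~ tau[sel]))[[2]], 1 / max(tau))
  } else {
    1 / tau[which.min(abs(f - exp(-2)))]
  }
  if (truncate) {
    keep <- seq_len(max(which(f >= 0.01), 10L))
    tau <- tau[keep]; y <- y[keep]
  }
  df <- data.frame(tau = tau, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ B + beta * (exp(-g * tau) * (1 + 0.5 * mu2 * tau^2))^2, data = df,
      start = list(B = B0, beta = beta0, g = gamma0, mu2 = 0),
      lower = c(-Inf, 1e-6, 1e-6, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) .stopf("cumulants fit failed: %s", conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["g"]] <= 0) .stopf("cumulants fit returned non-positive decay rate")
  structure(list(B0 = cf[["B"]], beta = cf[["beta"]], gamma_bar = cf[["g"]],
                 mu2 = cf[["mu2"]], pdi = cf[["mu2"]] / cf[["g"]]^2,
                 angle = curve$angle, wavelength = curve$wavelength,
                 refractive_index = curve$refractive_index,
                 temperature = curve$temperature, viscosity = curve$viscosity,
                 n = length(tau)),
            class = "cumulants_fit")
}

#' @export
print.cumulants_fit <- function(x, ...) {
  cat(sprintf("Cumulants fit (%g deg): gamma_bar = %.4g 1/s, mu2 = %.4g 1/s^2, PDI = %.3f\n",
              x$angle, x$gamma_bar, x$mu2, x$pdi))
  invisible(x)
}

#' Polydispersity index of a cumulants fit
#'
#' The dimensionless polydispersity index `PDI = mu2 / gamma_bar^2`
#' (normalised second cumulant), invariant under a change of time units.
#'
#' @param fit A [fit_cumulants()] result.
#' @return The PDI.
#' @export
pdi <- function(fit) {
  stopifnot(inherits(fit, "cumulants_fit"))
  fit$mu2 / fit$gamma_bar^2
}

#' Diffusion coefficient from decay rates at several angles
#'
#' Zero-intercept least squares of `gamma_bar = D q^2` over all supplied
#' (decay rate, scattering vector) pairs — typically three repeats at each
#' of two angles, pooled into six points.  The closed-form slope is
#' `D = sum(gamma q^2) / sum(q^4)`.
#'
#' @param gamma_bars Mean decay rates, 1/s.
#' @param qs Scattering vectors, 1/nm (from [scattering_vector()]).
#' @param temperature Absolute temperature, K (for the reported diameter).
#' @param viscosity Solvent viscosity, Pa s.
#' @return Object of class `diffusion_result` with fields `D_dif` (m^2/s),
#'   `D_H_nm` (Stokes-Einstein hydrodynamic diameter), `n_points` and
#'   `fit_rms` (1/s).
#' @export
fit_diffusion <- function(gamma_bars, qs, temperature = 298.15,
                          viscosity = 0.89e-3) {
  if (length(gamma_bars) != length(qs) || length(qs) < 1) {
    .stopf("need >= 1 matching (gamma_bar, q) pair")
  }
  if (all(qs == 0)) .stopf("all q values are zero")
  q_m <- qs * 1e9 # 1/nm -> 1/m
  D <- sum(gamma_bars * q_m^2) / sum(q_m^4)
  structure(list(D_dif = D,
                 D_H_nm = hydrodynamic_diameter(D, temperature, viscosity),
                 n_points = length(qs),
                 fit_rms = sqrt(mean((gamma_bars - D * q_m^2)^2))),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("Diffusion fit (%d points): D = %.4g m^2/s, D_H = %.4g nm\n",
              x$n_points, x$D_dif, x$D_H_nm))
  invisible(x)
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' `D_H = k_B T / (3 pi eta D_dif)`, reported in nm.
#'
#' @param D_dif Translational diffusion coefficient, m^2/s.
#' @param temperature Absolute temperature, K.
#' @param viscosity Solvent dynamic viscosity, Pa s.
#' @return Hydrodynamic diameter in nm.
#' @examples
#' hydrodynamic_diameter(3.43e-12) # ~143 nm
#' @export
hydrodynamic_diameter <- function(D_dif, temperature = 298.15,
                                  viscosity = 0.89e-3) {
  if (any(D_dif <= 0) || any(temperature <= 0) || any(viscosity <= 0)) {
    .stopf("D_dif, temperature and viscosity must be > 0")
  }
  .kB * temperature / (3 * pi * viscosity * D_dif) * 1e9
}

#' Mean PDI across scattering angles
#'
#' Each angle contributes one PDI (the mean across its repeats); the
#' reported value is the arithmetic mean of the per-angle PDIs.
#'
#' @param pdis Per-curve PDI values.
#' @param angles Matching scattering angles.
#' @return The reported PDI.
#' @export
mean_pdi <- function(pdis, angles) {
  if (length(pdis) == 0 || length(pdis) != length(angles)) {
    .stopf("need matching, non-empty pdis and angles")
  }
  mean(tapply(pdis, angles, mean))
}

#' Full multi-angle DLS analysis
#'
#' Fits every curve with the cumulants model, pools all (decay rate, q)
#' pairs into a zero-intercept `gamma = D q^2` regression, and reports the
#' Stokes-Einstein hydrodynamic diameter and the angle-averaged PDI.
#' Temperature and viscosity are taken from the first curve's metadata.
#'
#' @param curves List of [correlation_curve()] objects.
#' @param truncate Passed to [fit_cumulants()].
#' @return Object of class `dls_result` with fields `fits` (per-curve
#'   cumulants fits), `diffusion` (a `diffusion_result`), `D_H_nm` and
#'   `pdi`.
#' @export
analyze_dls <- function(curves, truncate = FALSE) {
  if (length(curves) == 0) .stopf("no curves supplied")
  fits <- lapply(curves, fit_cumulants, truncate = truncate)
  gammas <- vapply(fits, function(f) f$gamma_bar, numeric(1))
  qs <- vapply(fits, function(f)
    scattering_vector(f$angle, f$wavelength, f$refractive_index), numeric(1))
  dres <- fit_diffusion(gammas, qs,
                        temperature = fits[[1]]$temperature,
                        viscosity = fits[[1]]$viscosity)
  structure(list(fits = fits, diffusion = dres, D_H_nm = dres$D_H_nm,
                 pdi = mean_pdi(vapply(fits, pdi, numeric(1)),
                                vapply(fits, function(f) f$angle, numeric(1)))),
            class = "dls_result")
}

#' @export
print.dls_result <- function(x, ...) {
  cat(sprintf("DLS analysis: %d curves, D_H = %.4g nm, PDI = %.3f\n",
              length(x$fits), x$D_H_nm, x$pdi))
  invisible(x)
}
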