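## Flow-focusing mixing model: deterministic calculators for every
## flow-derived quantity in the cross-junction device.

#' Microfluidic device geometry
#'
#' Describes a cross-shaped hydrodynamic flow-focusing chip by its outlet
#' channel cross-section and length.  The default corresponds to a
#' commercial chip with a 100 x 100 um^2 square channel and an 81 mm long
#' outlet (mixing) channel.
#'
#' @param width_um Channel width in micrometres.
#' @param height_um Channel height in micrometres.
#' @param length_mm Outlet-channel length in millimetres (the distance over
#'   which mixing occurs before the fluid exits the device).
#' @return An object of class `device_geometry`.
#' @examples
#' device_geometry()
#' device_geometry(width_um = 150, height_um = 150, length_mm = 35)
#' @export
device_geometry <- function(width_um = 100, height_um = 100, length_mm = 81) {
  if (any(c(width_um, height_um, length_mm) <= 0)) {
    .stopf("all device dimensions must be strictly positive")
  }
  structure(list(width_um = width_um, height_um = height_um,
                 length_mm = length_mm),
            class = "device_geometry")
}

#' Solvent-pair fluid properties
#'
#' Bulk properties of the mixing solvent pair used by the mixing-time and
#' Reynolds-number calculators.  The default mutual diffusion coefficient
#' is a constant composition-averaged value for water/ethanol
#' interdiffusion (6.53e-10 m^2/s); density and viscosity default to pure
#' water at 25 C.  All values are explicit configuration, never hidden.
#'
#' @param D_m Mutual diffusion coefficient of the solvent pair, m^2/s.
#' @param density Fluid density, kg/m^3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param temperature Absolute temperature, K.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(D_m = 6.53e-10, density = 1000,
                             viscosity = 1.0e-3, temperature = 298.15) {
  if (any(c(D_m, density, viscosity, temperature) <= 0)) {
    .stopf("all fluid properties must be strictly positive")
  }
  structure(list(D_m = D_m, density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "fluid_properties")
}

#' Partition a total flow rate into central and side streams
#'
#' For a cross junction with one central (precursor) stream `Q_m` and two
#' side (focusing) streams each at `Q_s`, the total flow rate is
#' `Q_T = Q_m + 2 Q_s` and the flow rate ratio is `Q_R = 2 Q_s / Q_m`.
#' Given `(Q_T, Q_R)` the unique partition is
#' `Q_m = Q_T / (1 + Q_R)` and `Q_s = Q_T Q_R / (2 (1 + Q_R))`.
#' Because the side streams are the anti-solvent, `Q_R` also equals the
#' in-device dilution ratio `Dil_R` of the precursor.
#'
#' @param Q_T Total volumetric flow rate, uL/min.
#' @param Q_R Dimensionless flow rate ratio (>= 0).
#' @return An object of class `flow_condition` with fields `Q_T`, `Q_R`,
#'   `Q_m`, `Q_s` (all uL/min where applicable) and `Dil_R`.
#' @examples
#' make_flow_condition(100, 8)
#' @export
make_flow_condition <- function(Q_T, Q_R) {
  if (Q_T <= 0) .stopf("Q_T must be > 0 (got %g)", Q_T)
  if (Q_R < 0) .stopf("Q_R must be >= 0 (got %g)", Q_R)
  Q_m <- Q_T / (1 + Q_R)
  Q_s <- Q_T * Q_R / (2 * (1 + Q_R))
  structure(list(Q_T = Q_T, Q_R = Q_R, Q_m = Q_m, Q_s = Q_s, Dil_R = Q_R),
            class = "flow_condition")
}

#' @export
print.flow_condition <- function(x, ...) {
  cat("Flow condition (uL/min):\n")
  cat(sprintf("  Q_T = %g, Q_R = %g  ->  Q_m = %.4g, Q_s = %.4g (per side), Dil_R = %g\n",
              x$Q_T, x$Q_R, x$Q_m, x$Q_s, x$Dil_R))
  invisible(x)
}

#' Height-averaged width of the hydrodynamically focused stream
#'
#' Under the viscosity-matched approximation the focused precursor sheet
#' has height-averaged width `w_f = w_c / (1.5 (1 + Q_R))`, where the
#' factor 1.5 accounts for the focused sheet travelling about 1.5 times
#' faster than the mean flow velocity.  Strictly decreasing in `Q_R`.
#'
#' @param geom A [device_geometry()].
#' @param Q_R Flow rate ratio(s), >= 0 (vectorised).
#' @return Focused width(s) in micrometres.
#' @examples
#' focused_width(device_geometry(), c(0, 8, 30))
#' @export
focused_width <- function(geom, Q_R) {
  stopifnot(inherits(geom, "device_geometry"))
  if (any(Q_R < 0)) .stopf("Q_R must be >= 0")
  geom$width_um / (1.5 * (1 + Q_R))
}

#' Diffusive mixing time across the focused stream
#'
#' Characteristic time for solvent interdiffusion across a focused stream
#' of width `w_f`: `tau_mix = w_f^2 / (4 D_m)`.
#'
#' @param w_f_um Focused stream width(s) in micrometres (vectorised).
#' @param fluid A [fluid_properties()]; only `D_m` is used.
#' @return Mixing time(s) in seconds.
#' @examples
#' mixing_time(focused_width(device_geometry(), 8)) # ~0.021 s
#' @export
mixing_time <- function(w_f_um, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(w_f_um < 0)) .stopf("w_f must be >= 0")
  (w_f_um * .UM_TO_M)^2 / (4 * fluid$D_m)
}

#' Average fluid residence time in the outlet channel
#'
#' Outlet-channel length divided by the mean fluid velocity, i.e.
#' `tau_res = L * A / Q_T` with cross-section `A = width * height`.
#'
#' @param geom A [device_geometry()].
#' @param Q_T Total flow rate, uL/min (> 0).
#' @return Residence time in seconds.
#' @examples
#' residence_time(device_geometry(), 100) # ~0.49 s
#' @export
residence_time <- function(geom, Q_T) {
  stopifnot(inherits(geom, "device_geometry"))
  if (any(Q_T <= 0)) .stopf("Q_T must be > 0")
  A <- (geom$width_um * .UM_TO_M) * (geom$height_um * .UM_TO_M)
  (geom$length_mm * .MM_TO_M) * A / (Q_T * .UL_MIN_TO_M3S)
}

#' Channel Reynolds number
#'
#' `Re = rho v D_h / mu` with mean velocity `v = Q_T / A` and hydraulic
#' diameter `D_h = 2 w h / (w + h)` (equal to the side length for a square
#' channel).  Values well below ~2000 indicate laminar flow.
#'
#' @param geom A [device_geometry()].
#' @param Q_T Total flow rate, uL/min.
#' @param fluid A [fluid_properties()] supplying density and viscosity.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(device_geometry(), 100) # ~17: laminar
#' @export
reynolds_number <- function(geom, Q_T, fluid = fluid_properties()) {
  stopifnot(inherits(geom, "device_geometry"), inherits(fluid, "fluid_properties"))
  if (any(Q_T < 0)) .stopf("Q_T must be >= 0")
  w <- geom$width_um * .UM_TO_M
  h <- geom$height_um * .UM_TO_M
  v <- (Q_T * .UL_MIN_TO_M3S) / (w * h)
  D_h <- 2 * w * h / (w + h)
  fluid$density * v * D_h / fluid$viscosity
}

#' Combined mixing estimate for one flow condition
#'
#' Convenience wrapper evaluating focused width, mixing time, residence
#' time, their ratio and the Reynolds number for a single `(Q_T, Q_R)`
#' condition.
#'
#' @inheritParams reynolds_number
#' @param Q_R Flow rate ratio.
#' @return An object of class `mixing_estimate` with fields `w_f_bar`
#'   (um), `tau_mix` (s), `tau_res` (s), `res_mix_ratio` and `reynolds`.
#' @export
mixing_estimate <- function(geom = device_geometry(), Q_T = 100, Q_R = 8,
                            fluid = fluid_properties()) {
  w_f <- focused_width(geom, Q_R)
  tm <- mixing_time(w_f, fluid)
  tr <- residence_time(geom, Q_T)
  structure(list(Q_T = Q_T, Q_R = Q_R, w_f_bar = w_f, tau_mix = tm,
                 tau_res = tr, res_mix_ratio = tr / tm,
                 reynolds = reynolds_number(geom, Q_T, fluid)),
            class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat(sprintf("Mixing estimate at Q_T = %g uL/min, Q_R = %g:\n", x$Q_T, x$Q_R))
  cat(sprintf("  focused width     %.4g um\n", x$w_f_bar))
  cat(sprintf("  mixing time       %.4g ms\n", 1000 * x$tau_mix))
  cat(sprintf("  residence time    %.4g s\n", x$tau_res))
  cat(sprintf("  tau_res/tau_mix   %.4g\n", x$res_mix_ratio))
  cat(sprintf("  Reynolds number   %.4g\n", x$reynolds))
  invisible(x)
}

#' Final solute concentration after in-device dilution
#'
#' Treats the dilution ratio as a volume ratio between anti-solvent and
#' precursor with equal densities, so that weight fractions combine as
#' `C_final = C_init / (1 + Dil_R)`.
#'
#' @param C_init Initial precursor concentration (e.g. wt %), >= 0.
#' @param Dil_R Dilution ratio, >= 0 (vectorised).
#' @return Final concentration in the same units as `C_init`.
#' @examples
#' final_concentration(c(1.0, 1.5, 2.0), 30) # 0.032, 0.048, 0.065 wt %
#' @export
final_concentration <- function(C_init, Dil_R) {
  if (any(C_init < 0) || any(Dil_R < 0)) .stopf("C_init and Dil_R must be >= 0")
  C_init / (1 + Dil_R)
}

#' Anti-solvent volume needed to reach a target dilution ratio
#'
#' Samples collected at flow rate ratio `Q_R` carry an in-device dilution
#' `Dil_R = Q_R`; adding anti-solvent afterwards standardises them to a
#' common target.  Volume balance gives
#' `V_add = V_collected (Dil_R_target - Q_R) / (1 + Q_R)`, after which the
#' precursor volume fraction equals `1 / (1 + Dil_R_target)`.
#'
#' @param V_collected Collected sample volume (any volume unit).
#' @param Q_R Flow rate ratio at collection (= initial dilution ratio).
#' @param Dil_R_target Target dilution ratio, must be >= `Q_R` (a sample
#'   cannot be concentrated by adding liquid).
#' @return Volume of anti-solvent to add, same unit as `V_collected`.
#' @examples
#' postdilution_volume(100, 8, 30) # 244.4
#' @export
postdilution_volume <- function(V_collected, Q_R, Dil_R_target) {
  if (any(V_collected < 0) || any(Q_R < 0)) .stopf("volumes and ratios must be >= 0")
  if (any(Dil_R_target < Q_R)) {
    .stopf("Dil_R_target (%g) < Q_R (%g): cannot concentrate by addition",
           Dil_R_target[Dil_R_target < Q_R][1], Q_R[Dil_R_target < Q_R][1])
  }
  V_collected * (Dil_R_target - Q_R) / (1 + Q_R)
}

#' Damkohler number for nanoprecipitation
#'
#' `Da_p = tau_mix / tau_assbl`, the ratio of the solvent mixing time to
#' the characteristic lipid self-assembly time.  `Da_p < 1` means mixing
#' completes before assembly: supersaturation is homogeneous, nucleation
#' dominates growth and particles approach their lower size limit.
#' `Da_p > 1` means assembly starts in partially mixed fluid
#' (transport-controlled kinetics, fewer nuclei, larger particles).
#'
#' @param tau_mix Mixing time, s (> 0).
#' @param tau_assbl Assembly time, s (> 0).
#' @return Dimensionless Damkohler number.
#' @seealso [damkohler_regime()]
#' @export
damkohler <- function(tau_mix, tau_assbl) {
  if (any(tau_mix <= 0) || any(tau_assbl <= 0)) {
    .stopf("tau_mix and tau_assbl must be > 0")
  }
  tau_mix / tau_assbl
}

#' Classify a Damkohler number
#'
#' @param Da Damkohler number(s) from [damkohler()].
#' @return Character vector: `"nucleation-dominated"` (`Da < 1`),
#'   `"transport-controlled"` (`Da > 1`) or `"balanced"`.
#' @export
damkohler_regime <- function(Da) {
  ifelse(Da < 1, "nucleation-dominated",
         ifelse(Da > 1, "transport-controlled", "balanced"))
}

#' Relative nucleation-rate scaling with supersaturation
#'
#' Classical-nucleation-theory-style scaling of the nucleation rate with
#' supersaturation `S`: `J_rel = exp(-(ln S)^-2)`, a dimensionless factor
#' in `[0, 1)` that increases steeply once `S` exceeds 1 and approaches 1
#' as `S -> Inf`.  Defined only in the nucleation regime `S > 1`.
#'
#' @param S Supersaturation ratio(s), each > 1.
#' @return Relative nucleation rate(s) in `[0, 1)`.
#' @examples
#' nucleation_rate_scaling(exp(1)) # exp(-1)
#' @export
nucleation_rate_scaling <- function(S) {
  if (any(S <= 1)) .stopf("nucleation-rate scaling requires S > 1")
  exp(-(log(S))^-2)
}

#' Supersaturation state of the lipid in the focused stream
#'
#' @param C_phyt Local lipid concentration (e.g. wt %).
#' @param C_phyt_star Lipid solubility in the local solvent mixture, same
#'   units.
#' @return Object of class `supersaturation_state` with fields `C_phyt`,
#'   `C_phyt_star`, `S` and `J_rel` (`NA` when `S <= 1`, i.e. outside the
#'   nucleation regime).
#' @export
supersaturation_state <- function(C_phyt, C_phyt_star) {
  if (C_phyt < 0 || C_phyt_star <= 0) .stopf("concentrations must be positive")
  S <- C_phyt / C_phyt_star
  structure(list(C_phyt = C_phyt, C_phyt_star = C_phyt_star, S = S,
                 J_rel = if (S > 1) nucleation_rate_scaling(S) else NA_real_),
            class = "supersaturation_state")
}

#' Lipid partition between a cubosome and a same-size vesicle
#'
#' Compares the lipid content of a cubosome (a sphere of diameter
#' `diameter` filled with cubic phase of lipid volume fraction `phi_cub`)
#' with a unilamellar vesicle of the same outer diameter whose lipid
#' occupies a spherical shell of thickness `delta`.  Returns the fraction
#' of the combined lipid residing in the cubosome:
#' `V_cub * phi_cub / (V_cub * phi_cub + V_shell)`.
#'
#' @param diameter Particle outer diameter (any length unit).
#' @param delta Bilayer thickness, same unit; must satisfy
#'   `0 < delta < diameter / 2`.
#' @param phi_cub Lipid volume fraction of the cubic phase, in `(0, 1]`.
#' @return Fraction in `(0, 1)` of total lipid held by the cubosome.
#' @examples
#' lipid_partition_fraction(70, 2.87, 0.74) # ~0.77
#' @export
lipid_partition_fraction <- function(diameter, delta, phi_cub) {
  r <- diameter / 2
  if (delta <= 0 || delta >= r) .stopf("need 0 < delta < diameter/2")
  if (phi_cub <= 0 || phi_cub > 1) .stopf("need 0 < phi_cub <= 1")
  V_cub <- r^3                 # 4pi/3 cancels in the ratio
  V_shell <- r^3 - (r - delta)^3
  V_cub * phi_cub / (V_cub * phi_cub + V_shell)
}
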