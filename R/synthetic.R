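## Seeded synthetic-data generators.  Each generator inverts the model its
## matching analysis stage fits, so noiseless output is a fixed point of
## the analysis and noisy output supports parameter-recovery studies.
## Generator defaults are the study conditions of the emulated experiment
## (two DLS angles with 3 repeats, 5 flow rate ratios, Pn3m patterns with
## 6 reflections); noise models are documented choices: multiplicative
## Gaussian on g2-1 (correlator-like), Poisson on SAXS counts, additive
## Gaussian per size-series run.

#' Generate synthetic multi-angle DLS curves
#'
#' For each angle and repeat, builds the cumulants decay
#' `g2 - 1 = B + beta (exp(-gamma tau) (1 + mu2 tau^2 / 2))^2` with
#' `gamma = D(D_H) q^2` and `mu2 = PDI gamma^2`, on a logarithmic lag
#' grid, then applies multiplicative Gaussian noise of relative standard
#' deviation `noise_sd`.
#'
#' @param dh_nm Ground-truth hydrodynamic diameter, nm.
#' @param pdi_true Ground-truth polydispersity index (>= 0).
#' @param angles Scattering angles, degrees.
#' @param repeats Repeats per angle.
#' @param noise_sd Relative noise level (0 disables noise).
#' @param n_lag,lag_range Lag grid: `n_lag` log-spaced points spanning
#'   `lag_range` seconds.
#' @param beta,baseline Coherence factor and baseline of the decay.
#' @param wavelength,refractive_index,temperature,viscosity Optical and
#'   solvent metadata embedded in each curve.
#' @param seed Optional integer seed; `NULL` leaves the RNG state alone
#'   (useful inside a larger seeded simulation).
#' @return List of [correlation_curve()] objects with a `truth`
#'   attribute.
#' @examples
#' curves <- gen_dls_curves(dh_nm = 143, pdi_true = 0.16, seed = 1)
#' analyze_dls(curves)
#' @export
gen_dls_curves <- function(dh_nm = 143, pdi_true = 0.16,
                           angles = c(90, 173), repeats = 3,
                           noise_sd = 0.005, n_lag = 200,
                           lag_range = c(1e-6, 1), beta = 0.98,
                           baseline = 0, wavelength = 532,
                           refractive_index = 1.33, temperature = 298.15,
                           viscosity = 0.89e-3, seed = NULL) {
  if (dh_nm <= 0 || pdi_true < 0 || noise_sd < 0) {
    .stopf("dh_nm must be > 0; pdi_true and noise_sd >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  D <- .kB * temperature / (3 * pi * viscosity * dh_nm * 1e-9)
  lag <- exp(seq(log(lag_range[1]), log(lag_range[2]), length.out = n_lag))
  curves <- list()
  for (ang in angles) {
    q_m <- scattering_vector(ang, wavelength, refractive_index) * 1e9
    gam <- D * q_m^2
    mu2 <- pdi_true * gam^2
    clean <- baseline + beta * (exp(-gam * lag) * (1 + 0.5 * mu2 * lag^2))^2
    for (r in seq_len(repeats)) {
      y <- if (noise_sd > 0) clean * (1 + rnorm(n_lag, sd = noise_sd)) else clean
      curves[[length(curves) + 1L]] <-
        correlation_curve(lag, y, angle = ang, wavelength = wavelength,
                          refractive_index = refractive_index,
                          temperature = temperature, viscosity = viscosity)
    }
  }
  attr(curves, "truth") <- list(dh_nm = dh_nm, pdi = pdi_true, D_dif = D)
  curves
}

#' Generate a synthetic Pn3m SAXS pattern
#'
#' Sum of Lorentzian Bragg peaks at the first `n_peaks` Pn3m reflection
#' positions for lattice parameter `a_nm`, all with half-width
#' `k = pi / xi` (domain-size broadening) and heights decaying
#' geometrically with reflection order, over a constant background, with
#' an optional broad Gaussian bump at low q and optional Poisson counting
#' noise.
#'
#' @param a_nm Ground-truth lattice parameter, nm.
#' @param xi_nm Ground-truth domain size, nm (sets the peak HWHM).
#' @param n_peaks Number of reflections (<= 6).
#' @param q_range,n_q q grid (1/Angstrom) matching a typical instrument
#'   span.
#' @param peak_height Height of the first peak above background (counts).
#' @param decay Geometric height decay per reflection order.
#' @param background Constant background level.
#' @param bump Add the broad low-q bump?
#' @param bump_q,bump_height,bump_sigma Bump position (1/Angstrom),
#'   height and Gaussian width; `bump_height = NULL` uses 5% of
#'   `peak_height`.
#' @param poisson Apply Poisson counting noise to the intensities?
#' @param seed Optional integer seed (see [gen_dls_curves()]).
#' @return A [scattering_pattern()] with a `truth` attribute.
#' @examples
#' pat <- gen_saxs_pattern(a_nm = 6.7, xi_nm = 81)
#' fit_lattice_parameter(detect_peaks(pat))
#' @export
gen_saxs_pattern <- function(a_nm = 6.7, xi_nm = 81, n_peaks = 6,
                             q_range = c(0.0125, 0.75), n_q = 1500,
                             peak_height = 1000, decay = 0.5,
                             background = 10, bump = FALSE,
                             bump_q = 0.045, bump_height = NULL,
                             bump_sigma = 0.008, poisson = FALSE,
                             seed = NULL) {
  if (a_nm <= 0 || xi_nm <= 0) .stopf("a_nm and xi_nm must be > 0")
  if (!is.null(seed)) set.seed(seed)
  q <- seq(q_range[1], q_range[2], length.out = n_q)
  refl <- reflection_ratios("pn3m", n_peaks)
  q_hkl <- 2 * pi / (a_nm / .ANGSTROM_TO_NM) * refl$root_sums
  outside <- q_hkl < q_range[1] | q_hkl > q_range[2]
  if (any(outside)) {
    warning(sprintf("reflections outside the q grid dropped: %s",
                    paste(sprintf("{%s}", vapply(refl$hkl_list[outside],
                                                 paste, "", collapse = "")),
                          collapse = ", ")))
    q_hkl <- q_hkl[!outside]
  }
  k <- pi / (xi_nm / .ANGSTROM_TO_NM)
  I <- rep(background, n_q)
  for (j in seq_along(q_hkl)) {
    I <- I + peak_height * decay^(j - 1) * k^2 / (k^2 + (q - q_hkl[j])^2)
  }
  if (bump) {
    if (is.null(bump_height)) bump_height <- 0.05 * peak_height
    I <- I + bump_height * exp(-(q - bump_q)^2 / (2 * bump_sigma^2))
  }
  if (poisson) I <- rpois(n_q, I)
  pat <- scattering_pattern(q, I, label = sprintf("synthetic a=%g nm", a_nm))
  attr(pat, "truth") <- list(a_nm = a_nm, xi_nm = xi_nm, k = k,
                             q_hkl = q_hkl)
  pat
}

#' Generate a synthetic size-vs-flow-rate-ratio series
#'
#' Per-run diameters follow the empirical model
#' `D_H = beta1 (1 + Q_R)^(-beta2) + D_H0` plus additive Gaussian noise.
#' Defaults emulate the microfluidic study design: five ratios between 8
#' and 30, three independent runs, 4 nm run-to-run noise.
#'
#' @param beta1,beta2,dh0 Ground-truth model parameters (nm, -, nm).
#' @param qr Flow rate ratios.
#' @param repeats Independent runs per ratio.
#' @param noise_sd Additive noise standard deviation, nm.
#' @param label Series label.
#' @param seed Optional integer seed.
#' @return A [size_series()] with a `truth` attribute.
#' @export
gen_size_series <- function(beta1 = 2000, beta2 = 2, dh0 = 134,
                            qr = c(8, 10, 15, 20, 30), repeats = 3,
                            noise_sd = 4, label = "synthetic", seed = NULL) {
  if (any(qr <= 0) || repeats < 1) .stopf("qr must be > 0 and repeats >= 1")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(run = seq_len(repeats), qr = qr)
  mu <- beta1 * (1 + grid$qr)^(-beta2) + dh0
  dh <- mu + if (noise_sd > 0) rnorm(nrow(grid), sd = noise_sd) else 0
  s <- size_series(grid$qr, dh, run = grid$run, label = label)
  attr(s, "truth") <- list(beta1 = beta1, beta2 = beta2, dh0 = dh0)
  s
}

#' Generate a bulk-mixing counterpart series
#'
#' Bulk solvent exchange shows only a weak, generally nonsignificant
#' drift toward larger sizes at higher dilution ratios; this generator
#' draws per-run sizes from a shallow increasing linear trend with
#' comparatively large run-to-run noise (two runs per ratio).
#'
#' @param dh_base Size at `Dil_R = 0`, nm.
#' @param slope Linear drift, nm per dilution-ratio unit.
#' @param qr Dilution ratios (plotted on the same axis as `Q_R`).
#' @param repeats Independent runs per ratio.
#' @param noise_sd Additive noise, nm.
#' @param label Series label.
#' @param seed Optional integer seed.
#' @return A [size_series()] with a `truth` attribute.
#' @export
gen_bulk_series <- function(dh_base = 150, slope = 0.3,
                            qr = c(8, 10, 15, 20, 30), repeats = 2,
                            noise_sd = 8, label = "bulk", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(run = seq_len(repeats), qr = qr)
  dh <- dh_base + slope * grid$qr +
    if (noise_sd > 0) rnorm(nrow(grid), sd = noise_sd) else 0
  s <- size_series(grid$qr, dh, run = grid$run, label = label)
  attr(s, "truth") <- list(dh_base = dh_base, slope = slope)
  s
}

#' Generate a full synthetic study bundle
#'
#' Emulates the study design: one microfluidic series per precursor
#' concentration (1.0, 1.5, 2.0 wt%; asymptotic sizes ordered with
#' concentration, 3/3/5 runs) and one bulk counterpart per concentration
#' with a weak positive drift.  Optionally writes each series as a CSV
#' (`qr, dh_nm, run_id, series_label`) consumable by the analysis stages.
#'
#' @param concentrations Precursor concentration labels, wt%.
#' @param dh0 Per-concentration asymptotic sizes, nm.
#' @param beta1,beta2 Shared amplitude and exponent of the microfluidic
#'   truth.
#' @param repeats Per-concentration run counts.
#' @param noise_sd Microfluidic run-to-run noise, nm.
#' @param qr Flow rate ratios.
#' @param seed Integer seed fixing the whole bundle.
#' @param out_dir Optional directory to write CSVs into.
#' @return List with elements `microfluidic` and `bulk` (each a named
#'   list of [size_series()]) and `files` (written paths or `NULL`).
#' @export
gen_study_bundle <- function(concentrations = c(1.0, 1.5, 2.0),
                             dh0 = c(133, 135, 160),
                             beta1 = 2000, beta2 = 2,
                             repeats = c(3, 3, 5), noise_sd = 4,
                             qr = c(8, 10, 15, 20, 30),
                             seed = 1, out_dir = NULL) {
  if (length(dh0) != length(concentrations) ||
      length(repeats) != length(concentrations)) {
    .stopf("dh0 and repeats must match concentrations")
  }
  set.seed(seed)
  micro <- list(); bulk <- list()
  for (i in seq_along(concentrations)) {
    lab <- sprintf("%.1fwt", concentrations[i])
    micro[[lab]] <- gen_size_series(beta1 = beta1, beta2 = beta2,
                                    dh0 = dh0[i], qr = qr,
                                    repeats = repeats[i],
                                    noise_sd = noise_sd,
                                    label = paste0("micro_", lab))
    bulk[[lab]] <- gen_bulk_series(dh_base = dh0[i] + 10, qr = qr,
                                   label = paste0("bulk_", lab))
  }
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    all <- c(micro, bulk)
    files <- vapply(all, function(s) {
      path <- file.path(out_dir, paste0(attr(s, "label"), ".csv"))
      write.csv(data.frame(qr = s$qr, dh_nm = s$dh, run_id = s$run,
                           series_label = attr(s, "label")),
                path, row.names = FALSE)
      path
    }, character(1))
  }
  list(microfluidic = micro, bulk = bulk, files = files,
       truth = list(dh0 = setNames(dh0, names(micro)), beta1 = beta1,
                    beta2 = beta2))
}

#' Read a size-series CSV written by [gen_study_bundle()]
#'
#' @param path CSV with columns `qr`, `dh_nm`, `run_id` and optionally
#'   `series_label`.
#' @return A [size_series()].
#' @export
read_size_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("qr", "dh_nm", "run_id")
  if (!all(need %in% names(d))) {
    .stopf("'%s': expected columns %s", path, paste(need, collapse = ", "))
  }
  size_series(d$qr, d$dh_nm, run = d$run_id,
              label = if ("series_label" %in% names(d)) d$series_label[1] else "")
}
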