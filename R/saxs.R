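## SAXS structural analysis of bicontinuous cubic phases: reflection
## indexing, lattice-parameter regression, Lorentzian peak fitting and the
## nodal-surface bilayer-thickness relation.

#' Construct a validated 1-D scattering pattern
#'
#' @param q Scattering-vector magnitudes, 1/Angstrom, strictly increasing.
#' @param intensity Scattered intensities (arbitrary units), same length.
#' @param label Optional sample label.
#' @return Object of class `scattering_pattern`.
#' @export
scattering_pattern <- function(q, intensity, label = "") {
  if (length(q) != length(intensity)) .stopf("q and intensity lengths differ")
  if (length(q) < 2) .stopf("a pattern needs at least 2 points")
  if (any(!is.finite(q)) || any(!is.finite(intensity))) {
    .stopf("q and intensity must be finite")
  }
  if (any(diff(q) <= 0)) .stopf("q must be strictly increasing")
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 label = label),
            class = "scattering_pattern")
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat(sprintf("Scattering pattern%s: %d points, q in [%.4g, %.4g] 1/A\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Read a two-column q/intensity text file
#'
#' Accepts whitespace- or comma-delimited numeric columns; lines starting
#' with `#` are comments.  Rows are sorted by `q`; duplicated `q` values
#' are a format error.
#'
#' @param source Path to the text file.
#' @param label Optional sample label (defaults to the file name).
#' @return A [scattering_pattern()].
#' @export
read_pattern <- function(source, label = basename(source)) {
  lines <- readLines(source, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(gsub(",", " ", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) .stopf("'%s': fewer than 2 data rows", source)
  dat <- tryCatch(read.table(text = lines, header = FALSE,
                             colClasses = "numeric"),
                  error = function(e) .stopf("'%s': %s", source, conditionMessage(e)))
  if (ncol(dat) < 2) .stopf("'%s': need two numeric columns", source)
  ord <- order(dat[[1]])
  q <- dat[[1]][ord]
  if (anyDuplicated(q)) .stopf("'%s': duplicated q values after sorting", source)
  scattering_pattern(q, dat[[2]][ord], label = label)
}

## first six allowed Pn-3m reflections and their sqrt(h^2+k^2+l^2)
.PN3M_HKL <- list(c(1, 1, 0), c(1, 1, 1), c(2, 0, 0),
                  c(2, 1, 1), c(2, 2, 0), c(2, 2, 1))

#' Allowed reflections of a cubic space group
#'
#' For the double-diamond `Pn3m` phase the first six allowed reflections
#' are \{110\}, \{111\}, \{200\}, \{211\}, \{220\} and \{221\}, whose peak
#' positions satisfy `q_hkl = (2 pi / a) sqrt(h^2 + k^2 + l^2)`, so the
#' position ratios relative to the first peak are
#' `sqrt(2):sqrt(3):2:sqrt(6):sqrt(8):3` divided by `sqrt(2)`.
#'
#' @param space_group Space-group label; only `"pn3m"` is implemented.
#' @param n Number of reflections requested (at most 6 tabulated).
#' @return Object of class `reflection_set` with fields `space_group`,
#'   `hkl_list`, `root_sums` and `ratios` (positions relative to the
#'   first reflection).
#' @examples
#' reflection_ratios("pn3m", 6)$ratios
#' @export
reflection_ratios <- function(space_group = "pn3m", n = 6) {
  sg <- tolower(gsub("[^a-z0-9]", "", tolower(space_group)))
  if (!sg %in% c("pn3m", "pn3barm")) {
    .stopf("space group '%s' not implemented (only Pn3m)", space_group)
  }
  if (n < 1 || n > length(.PN3M_HKL)) {
    .stopf("n must be between 1 and %d tabulated reflections", length(.PN3M_HKL))
  }
  hkl <- .PN3M_HKL[seq_len(n)]
  rs <- vapply(hkl, function(v) sqrt(sum(v^2)), numeric(1))
  structure(list(space_group = "Pn3m", hkl_list = hkl, root_sums = rs,
                 ratios = rs / rs[1]),
            class = "reflection_set")
}

#' Lattice parameter from indexed peak positions
#'
#' Least-squares regression of peak positions `q_hkl` on
#' `sqrt(h^2+k^2+l^2)` through the origin: the slope is `m = 2 pi / a`, so
#' `a = 2 pi / m`.  Peaks are assigned to reflections in ascending order;
#' a trailing truncation (fewer peaks than tabulated reflections) is the
#' common case for weakly ordered samples, and `mask` allows arbitrary
#' gaps in the assignment.
#'
#' @param q_peaks Peak positions, 1/Angstrom, ascending.
#' @param reflections A [reflection_ratios()] set; defaults to the first
#'   `length(q_peaks)` Pn3m reflections.
#' @param mask Optional integer indices into the reflection table, one per
#'   peak, for non-contiguous assignments.
#' @return Object of class `lattice_fit` with fields `a_nm`, `slope_m`
#'   (1/Angstrom per unit root-sum), `residual_rms` and `n_peaks`.
#' @examples
#' a <- 6.7 # nm
#' q <- 2 * pi / (a * 10) * reflection_ratios("pn3m", 6)$root_sums
#' fit_lattice_parameter(q)$a_nm
#' @export
fit_lattice_parameter <- function(q_peaks,
                                  reflections = reflection_ratios("pn3m", length(q_peaks)),
                                  mask = NULL) {
  if (length(q_peaks) < 1 || any(q_peaks <= 0)) {
    .stopf("q_peaks must be positive (got %d peaks)", length(q_peaks))
  }
  s <- reflections$root_sums
  if (!is.null(mask)) {
    if (length(mask) != length(q_peaks)) .stopf("mask length must match q_peaks")
    s <- reflection_ratios(reflections$space_group, max(mask))$root_sums[mask]
  }
  if (length(s) != length(q_peaks)) {
    .stopf("%d peaks but %d reflections", length(q_peaks), length(s))
  }
  m <- sum(q_peaks * s) / sum(s^2)
  structure(list(a_nm = 2 * pi / m * .ANGSTROM_TO_NM, slope_m = m,
                 residual_rms = sqrt(mean((q_peaks - m * s)^2)),
                 n_peaks = length(q_peaks)),
            class = "lattice_fit")
}

#' @export
print.lattice_fit <- function(x, ...) {
  cat(sprintf("Cubic lattice fit: a = %.4g nm (slope %.4g 1/A, %d peaks, rms %.2g 1/A)\n",
              x$a_nm, x$slope_m, x$n_peaks, x$residual_rms))
  invisible(x)
}

#' Detect Bragg peaks in a scattering pattern
#'
#' Finds local maxima of the square-root intensity (a variance-stabilising
#' scale for counting noise that still compresses the dynamic range),
#' keeps those whose topographic prominence above the flanking valleys
#' exceeds `min_prominence` times the global signal range, and refines
#' each kept position by a three-point parabolic interpolation of the
#' log-intensity.
#'
#' @param pattern A [scattering_pattern()].
#' @param min_prominence Fraction of the global square-root-intensity
#'   range that a peak must rise above its surrounding valleys.
#' @param window Optional `c(qmin, qmax)` restricting the search.
#' @return Sorted numeric vector of peak positions (1/Angstrom); empty
#'   when no peak qualifies.
#' @export
detect_peaks <- function(pattern, min_prominence = 0.02, window = NULL) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  q <- pattern$q
  I <- pattern$intensity
  if (!is.null(window)) {
    keep <- q >= window[1] & q <= window[2]
    q <- q[keep]; I <- I[keep]
  }
  if (length(q) < 5) return(numeric(0))
  y <- log(pmax(I, .Machine$double.xmin))
  # candidates are found on the square-root scale: a running median kills
  # single-point counting-noise spikes, the short mean filter smooths what
  # remains; positional refinement below goes back to the raw data
  y0s <- sqrt(pmax(I, 0))
  ys <- stats::runmed(y0s, 5, endrule = "median")
  ys <- as.numeric(stats::filter(ys, rep(1 / 3, 3), sides = 2))
  ys[c(1, length(ys))] <- y0s[c(1, length(y0s))]
  pk <- pracma::findpeaks(ys, nups = 1, ndowns = 1, zero = "+")
  if (is.null(pk)) return(numeric(0))
  rng <- diff(range(ys))
  if (rng <= 0) return(numeric(0))
  # prominence: peak height above the higher of its two flanking valleys
  prom <- pk[, 1] - pmax(ys[pk[, 3]], ys[pk[, 4]])
  idx <- pk[prom / rng >= min_prominence, 2]
  if (length(idx) == 0) return(numeric(0))
  refine <- function(i) {
    # recentre on the raw-data maximum next to the smoothed candidate
    lo <- max(i - 2, 1); hi <- min(i + 2, length(q))
    i <- (lo:hi)[which.max(y[lo:hi])]
    if (i <= 1 || i >= length(q)) return(q[i])
    x0 <- q[i - 1]; x1 <- q[i]; x2 <- q[i + 1]
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    # vertex of the parabola through three (possibly non-uniform) points
    d <- (x0 - x1) * (x0 - x2) * (x1 - x2)
    a <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / d
    b <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / d
    if (a >= 0) return(x1)
    v <- -b / (2 * a)
    if (v < x0 || v > x2) x1 else v
  }
  sort(vapply(idx, refine, numeric(1)))
}

#' Fit a Lorentzian to a single Bragg peak
#'
#' Least-squares fit of `I(q) = A / (k^2 + (q - q0)^2) + B` over a window
#' around the peak, where `k` is the half-width at half-maximum.  Assuming
#' finite crystalline domain size dominates the broadening, a lower bound
#' on the domain size is `xi >= pi / k`; the estimate is reported as a
#' lower bound because instrumental resolution and thermal fluctuations
#' also broaden the peak.
#'
#' Initial values come from the window maximum (`q0`), the half-maximum
#' crossings (`k`) and the window minimum (`B`).  The default window is
#' `q0 +/- 5 k` around the initial estimates.
#'
#' @param pattern A [scattering_pattern()].
#' @param window Optional `c(qmin, qmax)` containing one dominant peak
#'   (at least 8 points); when `NULL` a window is derived from the global
#'   maximum.
#' @return Object of class `lorentzian_fit` with fields `A`, `k`, `q0`,
#'   `B` (fit parameters, q units 1/Angstrom), their standard errors
#'   (`se`), and `xi_nm = pi / k` in nm.
#' @export
fit_lorentzian <- function(pattern, window = NULL) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  q <- pattern$q; y <- pattern$intensity
  if (!is.null(window)) {
    keep <- q >= window[1] & q <= window[2]
    qw <- q[keep]; yw <- y[keep]
  } else {
    qw <- q; yw <- y
  }
  if (length(qw) < 8) .stopf("fit window must contain at least 8 points")
  i0 <- which.max(yw)
  q0_init <- qw[i0]
  B_init <- min(yw)
  h <- yw[i0] - B_init
  half <- B_init + h / 2
  li <- which(qw < q0_init & yw <= half)
  ri <- which(qw > q0_init & yw <= half)
  k_init <- if (length(li) && length(ri)) {
    (qw[min(ri)] - qw[max(li)]) / 2
  } else {
    diff(range(qw)) / 10
  }
  if (is.null(window)) {
    keep <- q >= q0_init - 5 * k_init & q <= q0_init + 5 * k_init
    qw <- q[keep]; yw <- y[keep]
    if (length(qw) < 8) .stopf("auto window around q0 = %.4g holds < 8 points", q0_init)
  }
  df <- data.frame(q = qw, I = yw)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A / (k^2 + (q - q0)^2) + B, data = df,
                      start = list(A = h * k_init^2, k = k_init,
                                   q0 = q0_init, B = B_init),
                      lower = c(0, 1e-10, min(qw), -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) .stopf("Lorentzian fit failed: %s", conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  structure(list(A = cf[["A"]], k = cf[["k"]], q0 = cf[["q0"]], B = cf[["B"]],
                 se = setNames(se, names(cf)),
                 xi_nm = pi / cf[["k"]] * .ANGSTROM_TO_NM,
                 window = range(qw), n = nrow(df)),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("Lorentzian peak: q0 = %.4g 1/A, HWHM k = %.4g 1/A, domain size xi >= %.4g nm\n",
              x$q0, x$k, x$xi_nm))
  invisible(x)
}

## nodal-surface constants for the Pn-3m minimal surface
.PN3M_A0 <- 1.919
.PN3M_CHI <- -2
.PN3M_XMAX <- 0.39 # upper edge of the physical (monotone) branch

#' Lipid volume fraction of a Pn3m phase from its bilayer thickness
#'
#' Forward nodal-surface relation
#' `phi = 2 A0 x + (4 pi chi / 3) x^3` with `x = delta / (2 a)`,
#' `A0 = 1.919` and Euler characteristic `chi = -2`.
#'
#' @param delta_nm Bilayer thickness, nm.
#' @param a_nm Cubic lattice parameter, nm.
#' @return Lipid volume fraction.
#' @seealso [bilayer_thickness()] for the inverse.
#' @export
bilayer_volume_fraction <- function(delta_nm, a_nm) {
  if (any(delta_nm <= 0) || any(a_nm <= 0)) .stopf("delta and a must be > 0")
  x <- delta_nm / (2 * a_nm)
  2 * .PN3M_A0 * x + (4 * pi * .PN3M_CHI / 3) * x^3
}

#' Bilayer thickness of a Pn3m phase from its lattice parameter
#'
#' Inverts the nodal-surface relation
#' `phi = 2 A0 x + (4 pi chi / 3) x^3` (`x = delta / (2 a)`,
#' `A0 = 1.919`, `chi = -2`) for the unique root on the physical branch
#' `x` in `(0, 0.39)`, where the cubic is strictly increasing.  Root
#' finding is by bracketed bisection to near machine precision.
#'
#' @param a_nm Cubic lattice parameter, nm.
#' @param phi_phyt Lipid volume fraction in the cubic phase; must lie in
#'   the attainable range of the physical branch (up to ~1.0).
#' @return Object of class `bilayer_result` with fields `delta_nm`,
#'   `phi_phyt` and the reduced variable `x`.
#' @examples
#' bilayer_thickness(6.7, 0.74) # delta ~ 2.87 nm
#' @export
bilayer_thickness <- function(a_nm, phi_phyt) {
  if (a_nm <= 0) .stopf("a must be > 0")
  phi_max <- 2 * .PN3M_A0 * .PN3M_XMAX + (4 * pi * .PN3M_CHI / 3) * .PN3M_XMAX^3
  if (phi_phyt <= 0 || phi_phyt > phi_max) {
    .stopf("phi_phyt = %g outside attainable range (0, %.4f]", phi_phyt, phi_max)
  }
  root <- uniroot(function(x) 2 * .PN3M_A0 * x + (4 * pi * .PN3M_CHI / 3) * x^3 - phi_phyt,
                  interval = c(.Machine$double.eps, .PN3M_XMAX),
                  tol = .Machine$double.eps^0.75)$root
  structure(list(delta_nm = 2 * a_nm * root, phi_phyt = phi_phyt, x = root,
                 a_nm = a_nm),
            class = "bilayer_result")
}

#' @export
print.bilayer_result <- function(x, ...) {
  cat(sprintf("Bilayer thickness: delta = %.4g nm (a = %.4g nm, phi = %.4g, x = %.4g)\n",
              x$delta_nm, x$a_nm, x$phi_phyt, x$x))
  invisible(x)
}

#' Convert a lipid weight fraction to a volume fraction
#'
#' Ideal-mixing conversion `phi = (w / rho_l) / (w / rho_l + (1 - w) / rho_w)`.
#' The default lipid density 0.90 g/mL is representative of phytantriol.
#'
#' @param w_lipid Lipid mass fraction, in `[0, 1]`.
#' @param rho_lipid Lipid density, g/mL.
#' @param rho_water Aqueous-phase density, g/mL.
#' @return Lipid volume fraction.
#' @examples
#' weight_to_volume_fraction(0.72) # ~0.74 at the 28 wt% water boundary
#' @export
weight_to_volume_fraction <- function(w_lipid, rho_lipid = 0.90, rho_water = 1.0) {
  if (any(w_lipid < 0) || any(w_lipid > 1)) .stopf("w_lipid must be in [0, 1]")
  if (any(rho_lipid <= 0) || any(rho_water <= 0)) .stopf("densities must be > 0")
  vl <- w_lipid / rho_lipid
  vl / (vl + (1 - w_lipid) / rho_water)
}

#' Real-space spacing from a scattering vector
#'
#' `d = 2 pi / q`, converted from Angstrom to nm.
#'
#' @param q Scattering vector(s), 1/Angstrom, > 0.
#' @return Spacing(s) in nm.
#' @examples
#' d_spacing(0.045) # ~14 nm
#' @export
d_spacing <- function(q) {
  if (any(q <= 0)) .stopf("q must be > 0")
  2 * pi / q * .ANGSTROM_TO_NM
}
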