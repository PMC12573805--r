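## End-to-end orchestration: the flow-condition sweep table and the
## self-validating synthetic reproduction run.

#' Flow-condition sweep report
#'
#' Evaluates the full mixing model over a set of flow rate ratios at one
#' total flow rate, producing the per-condition table of stream
#' partitioning, focused width, mixing and residence times, Reynolds
#' number and dilution ratio.
#'
#' @param Q_R Flow rate ratios to sweep (may be empty).
#' @param Q_T Total flow rate, uL/min.
#' @param geom A [device_geometry()].
#' @param fluid A [fluid_properties()].
#' @return A data frame of class `flow_report` with one row per ratio and
#'   columns `Q_R`, `Q_m`, `Q_s` (uL/min), `w_f_um`, `tau_mix_ms`,
#'   `tau_res_s`, `res_mix_ratio`, `reynolds`, `Dil_R`.
#' @examples
#' run_flow_calc(c(8, 10, 15, 20, 30))
#' @export
run_flow_calc <- function(Q_R = c(8, 10, 15, 20, 30), Q_T = 100,
                          geom = device_geometry(),
                          fluid = fluid_properties()) {
  rows <- lapply(Q_R, function(qr) {
    fc <- make_flow_condition(Q_T, qr)
    me <- mixing_estimate(geom, Q_T, qr, fluid)
    data.frame(Q_R = qr, Q_m = fc$Q_m, Q_s = fc$Q_s,
               w_f_um = me$w_f_bar, tau_mix_ms = 1000 * me$tau_mix,
               tau_res_s = me$tau_res, res_mix_ratio = me$res_mix_ratio,
               reynolds = me$reynolds, Dil_R = fc$Dil_R)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Q_R = numeric(0), Q_m = numeric(0), Q_s = numeric(0),
               w_f_um = numeric(0), tau_mix_ms = numeric(0),
               tau_res_s = numeric(0), res_mix_ratio = numeric(0),
               reynolds = numeric(0), Dil_R = numeric(0))
  structure(out, class = c("flow_report", "data.frame"),
            Q_T = Q_T, geometry = geom, fluid = fluid)
}

#' @export
print.flow_report <- function(x, ...) {
  cat(sprintf("Flow sweep at Q_T = %g uL/min (%g x %g um^2 channel, L = %g mm):\n",
              attr(x, "Q_T"), attr(x, "geometry")$width_um,
              attr(x, "geometry")$height_um, attr(x, "geometry")$length_mm))
  if (nrow(x) == 0) {
    cat("  (empty sweep)\n")
    return(invisible(x))
  }
  df <- as.data.frame(lapply(x, signif, digits = 4))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write a report object as JSON
#'
#' Full-precision machine-readable form of a `flow_report` or
#' `reproduce_report`; numbers are written unrounded so the JSON agrees
#' numerically with the in-memory object.
#'
#' @param report The report object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- if (inherits(report, "flow_report")) {
    list(Q_T_uL_min = attr(report, "Q_T"),
         geometry_um_mm = unclass(attr(report, "geometry")),
         fluid = unclass(attr(report, "fluid")),
         sweep = as.data.frame(report))
  } else if (inherits(report, "reproduce_report")) {
    list(seed = report$seed, checks = report$checks,
         all_pass = report$all_pass)
  } else {
    unclass(report)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

.check_row <- function(stage, quantity, truth, estimate, tol, pass) {
  data.frame(stage = stage, quantity = quantity, truth = truth,
             estimate = estimate, tolerance = tol, pass = pass,
             stringsAsFactors = FALSE)
}

#' End-to-end synthetic reproduction run
#'
#' Generates a full synthetic study (DLS curves, a SAXS pattern, the
#' microfluidic and bulk size-series bundle) from one seed, pushes every
#' data set through its analysis stage, and checks that each ground-truth
#' parameter is recovered within its documented tolerance: hydrodynamic
#' diameter within 3%, PDI within 0.03, lattice parameter within 0.5%,
#' domain size within 5%, asymptotic size `D_H0` within 8 nm per series
#' (with a significant negative monotonic trend), and a majority of
#' nonsignificant bulk trends.
#'
#' @param seed Integer seed driving every generator.
#' @param out_dir Optional directory: bundle CSVs and a JSON report are
#'   written there.
#' @return Object of class `reproduce_report` with fields `seed`,
#'   `checks` (a data frame of stage/quantity/truth/estimate/pass rows)
#'   and `all_pass`.
#' @examples
#' \donttest{
#' rep <- run_reproduce(seed = 1)
#' rep$all_pass
#' }
#' @export
run_reproduce <- function(seed = 1, out_dir = NULL) {
  set.seed(seed)
  checks <- list()

  ## DLS stage: multi-angle curves at the study's noise level
  dh_true <- 143; pdi_true <- 0.16
  curves <- gen_dls_curves(dh_nm = dh_true, pdi_true = pdi_true,
                           noise_sd = 0.005, seed = NULL)
  dls <- analyze_dls(curves)
  checks[[length(checks) + 1L]] <- .check_row(
    "dls", "D_H (nm)", dh_true, dls$D_H_nm, "3%",
    abs(dls$D_H_nm - dh_true) / dh_true <= 0.03)
  checks[[length(checks) + 1L]] <- .check_row(
    "dls", "PDI", pdi_true, dls$pdi, "0.03",
    abs(dls$pdi - pdi_true) <= 0.03)

  ## SAXS stage: Poisson-noise pattern at 1e4 peak counts
  a_true <- 6.7; xi_true <- 81
  pat <- gen_saxs_pattern(a_nm = a_true, xi_nm = xi_true,
                          peak_height = 1e4, poisson = TRUE, seed = NULL)
  peaks <- detect_peaks(pat)
  lat <- fit_lattice_parameter(peaks)
  lor <- fit_lorentzian(pat, window = attr(pat, "truth")$q_hkl[1] + c(-1, 1) * 5 * attr(pat, "truth")$k)
  checks[[length(checks) + 1L]] <- .check_row(
    "saxs", "lattice parameter a (nm)", a_true, lat$a_nm, "0.5%",
    abs(lat$a_nm - a_true) / a_true <= 0.005)
  checks[[length(checks) + 1L]] <- .check_row(
    "saxs", "domain size xi (nm)", xi_true, lor$xi_nm, "5%",
    abs(lor$xi_nm - xi_true) / xi_true <= 0.05)

  ## size-model stage: per-concentration recovery + trend significance
  bundle <- gen_study_bundle(seed = seed, out_dir = out_dir)
  for (lab in names(bundle$microfluidic)) {
    s <- bundle$microfluidic[[lab]]
    truth <- attr(s, "truth")
    fit <- fit_size_model(s, fix_beta2 = 2)
    cs <- correlation_suite(s)
    checks[[length(checks) + 1L]] <- .check_row(
      "size-model", sprintf("D_H0 (%s, nm)", lab), truth$dh0, fit$D_H0,
      "8 nm", abs(fit$D_H0 - truth$dh0) <= 8)
    checks[[length(checks) + 1L]] <- .check_row(
      "size-model", sprintf("Kendall trend (%s)", lab), -1, cs$kendall_tau,
      "tau < 0, p < 0.05", cs$kendall_tau < 0 && cs$kendall_p < 0.05)
  }
  bulk_ns <- vapply(bundle$bulk, function(s) {
    cs <- correlation_suite(s)
    is.na(cs$kendall_p) || cs$kendall_p >= 0.05
  }, logical(1))
  checks[[length(checks) + 1L]] <- .check_row(
    "size-model", "bulk nonsignificant fraction", 1, mean(bulk_ns),
    "> 0.5", mean(bulk_ns) > 0.5)

  checks <- do.call(rbind, checks)
  out <- structure(list(seed = seed, checks = checks,
                        all_pass = all(checks$pass)),
                   class = "reproduce_report")
  if (!is.null(out_dir)) {
    write_report_json(out, file.path(out_dir, "reproduce_report.json"))
  }
  out
}

#' @export
print.reproduce_report <- function(x, ...) {
  cat(sprintf("Synthetic reproduction run (seed %d): %s\n", x$seed,
              if (x$all_pass) "all checks passed" else "CHECK FAILURES"))
  df <- x$checks
  df$truth <- signif(df$truth, 4)
  df$estimate <- signif(df$estimate, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
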