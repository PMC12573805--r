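## Empirical size-vs-flow-rate-ratio model and its statistical validation:
## D_H = beta1 (1 + Q_R)^(-beta2) + D_H0 (equivalently, via the mixing
## time, D_H = alpha1 tau_mix^alpha2 + D_H0 with beta2 = 2 alpha2), plus
## rank/linear correlations and ANCOVA between formulations.

#' Construct a hydrodynamic-size series
#'
#' Replicate-level observations of mean hydrodynamic diameter versus flow
#' rate ratio.
#'
#' @param qr Flow rate ratios, > 0.
#' @param dh Hydrodynamic diameters, nm, > 0.
#' @param run Optional replicate identifier per observation.
#' @param sem Optional standard error of the mean per observation, nm.
#' @param label Series label (e.g. precursor concentration).
#' @return A data frame of class `size_series` with columns `qr`, `dh`,
#'   `run` and optionally `sem`.
#' @export
size_series <- function(qr, dh, run = NULL, sem = NULL, label = "") {
  if (length(qr) != length(dh)) .stopf("qr and dh lengths differ")
  if (any(qr <= 0) || any(dh <= 0)) .stopf("qr and dh must be > 0")
  d <- data.frame(qr = as.numeric(qr), dh = as.numeric(dh),
                  run = if (is.null(run)) 1L else run)
  if (!is.null(sem)) d$sem <- as.numeric(sem)
  structure(d, class = c("size_series", "data.frame"), label = label)
}

#' Per-ratio means of a size series
#'
#' @param series A [size_series()].
#' @return Data frame with columns `qr`, `dh` (mean), `sem` and `n`.
#' @export
series_means <- function(series) {
  stopifnot(inherits(series, "size_series"))
  agg <- aggregate(dh ~ qr, data = series, FUN = mean)
  agg$sem <- aggregate(dh ~ qr, data = series,
                       FUN = function(v) sd(v) / sqrt(length(v)))$dh
  agg$n <- aggregate(dh ~ qr, data = series, FUN = length)$dh
  agg[order(agg$qr), , drop = FALSE]
}

.new_size_model_fit <- function(est, se, r2, beta2_fixed, corr_b1_dh0,
                                n, data, fitted, parameterization) {
  structure(list(beta1 = est[["beta1"]], beta2 = est[["beta2"]],
                 D_H0 = est[["D_H0"]],
                 se_beta1 = se[["beta1"]], se_beta2 = se[["beta2"]],
                 se_DH0 = se[["D_H0"]], r2 = r2,
                 beta2_fixed = beta2_fixed,
                 alpha2 = est[["beta2"]] / 2,
                 corr_beta1_DH0 = corr_b1_dh0,
                 n_points = n, data = data, fitted = fitted,
                 parameterization = parameterization),
            class = "size_model_fit")
}

#' Fit the empirical size model in flow-rate-ratio form
#'
#' Nonlinear least squares for
#' `D_H = beta1 (1 + Q_R)^(-beta2) + D_H0`: `beta1` (nm) sets the
#' amplitude of the flow-controlled size reduction, `beta2` the power-law
#' exponent (2 when size tracks the diffusive mixing time), and `D_H0`
#' (nm) the asymptotic small-particle limit reached when mixing is much
#' faster than assembly.  By default the fit uses the per-ratio mean
#' sizes, unweighted; standard errors come from the Jacobian-based
#' covariance at the optimum, and `r2 = 1 - SS_res / SS_tot` is computed
#' on the fitted points.
#'
#' `beta1` and `D_H0` can partially compensate for changes in `beta2` in
#' three-parameter fits on few points; the returned `corr_beta1_DH0`
#' quantifies this identifiability limit rather than hiding it.
#'
#' @param series A [size_series()].
#' @param fix_beta2 Optional fixed exponent (e.g. `2`); `NULL` fits it.
#' @param use_means Fit per-ratio means (default) or replicate-level
#'   points.
#' @param weight_sem Weight points by `1/sem^2` (requires per-ratio
#'   standard errors).
#' @return Object of class `size_model_fit` with estimates, standard
#'   errors, `r2`, `beta2_fixed` flag, `alpha2 = beta2 / 2`, and the
#'   `beta1`-`D_H0` estimate correlation.
#' @examples
#' s <- gen_size_series(seed = 1)
#' fit_size_model(s, fix_beta2 = 2)
#' @export
fit_size_model <- function(series, fix_beta2 = NULL, use_means = TRUE,
                           weight_sem = FALSE) {
  stopifnot(inherits(series, "size_series"))
  d <- if (use_means) series_means(series) else as.data.frame(series)
  x <- d$qr; y <- d$dh
  free_beta2 <- is.null(fix_beta2)
  if (length(x) < (if (free_beta2) 4L else 3L)) {
    .stopf("need >= %d points (got %d)", if (free_beta2) 4L else 3L, length(x))
  }
  w <- if (weight_sem) {
    if (is.null(d$sem) || any(!is.finite(d$sem)) || any(d$sem <= 0)) {
      .stopf("weight_sem = TRUE requires finite positive sem values")
    }
    1 / d$sem^2
  } else {
    rep(1, length(x))
  }
  if (sd(y) < 1e-8) {
    warning("degenerate series (constant D_H): returning beta1 = 0")
    b2 <- if (free_beta2) 2 else fix_beta2
    return(.new_size_model_fit(
      c(beta1 = 0, beta2 = b2, D_H0 = mean(y)),
      c(beta1 = NA_real_, beta2 = NA_real_, D_H0 = NA_real_),
      r2 = NA_real_, beta2_fixed = !free_beta2, corr_b1_dh0 = NA_real_,
      n = length(x), data = d, fitted = rep(mean(y), length(x)),
      parameterization = "qr"))
  }
  dh0_0 <- min(y)
  b2_0 <- if (free_beta2) 2 else fix_beta2
  b1_0 <- max(y[which.min(x)] - dh0_0, 1) * (1 + min(x))^b2_0
  df <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (free_beta2) {
      minpack.lm::nlsLM(y ~ b1 * (1 + x)^(-b2) + dh0, data = df,
                        start = list(b1 = b1_0, b2 = b2_0, dh0 = dh0_0),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ b1 * (1 + x)^(-fix_beta2) + dh0, data = df,
                        start = list(b1 = b1_0, dh0 = dh0_0), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) .stopf("size-model fit failed: %s", conditionMessage(e)))
  cf <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(cf)) else sqrt(diag(V))
  names(se) <- names(cf)
  est <- c(beta1 = cf[["b1"]],
           beta2 = if (free_beta2) cf[["b2"]] else fix_beta2,
           D_H0 = cf[["dh0"]])
  ses <- c(beta1 = se[["b1"]],
           beta2 = if (free_beta2) se[["b2"]] else 0,
           D_H0 = se[["dh0"]])
  yhat <- as.numeric(predict(fit))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  corr <- if (!is.null(V) && all(diag(V) > 0)) {
    stats::cov2cor(V)["b1", "dh0"]
  } else NA_real_ # perfect fits have a singular covariance
  .new_size_model_fit(est, ses, r2, !free_beta2, corr, length(x), d, yhat,
                      parameterization = "qr")
}

#' Fit the size model in mixing-time form
#'
#' Equivalent parameterization `D_H = alpha1 tau_mix^alpha2 + D_H0`, with
#' the per-point mixing time computed from the device geometry and fluid
#' properties via [focused_width()] and [mixing_time()].  Since
#' `tau_mix` is proportional to `(1 + Q_R)^-2`, the exponents are related
#' by `beta2 = 2 alpha2`, and the fitted `D_H0` must agree with
#' [fit_size_model()] on the same data.
#'
#' @inheritParams fit_size_model
#' @param geom A [device_geometry()].
#' @param fluid A [fluid_properties()].
#' @param fix_alpha2 Optional fixed exponent (e.g. `1`).
#' @return A `size_model_fit` whose `beta1`/`beta2` slots hold `alpha1`
#'   and `alpha2` translated to the flow-rate-ratio form (`beta2 =
#'   2 alpha2`; `beta1` converted through the `tau_mix(Q_R)` constant);
#'   `alpha1` and `alpha2` are reported as well.
#' @export
fit_size_model_tau <- function(series, geom = device_geometry(),
                               fluid = fluid_properties(),
                               fix_alpha2 = NULL, use_means = TRUE) {
  stopifnot(inherits(series, "size_series"))
  d <- if (use_means) series_means(series) else as.data.frame(series)
  x <- d$qr; y <- d$dh
  free_a2 <- is.null(fix_alpha2)
  if (length(x) < (if (free_a2) 4L else 3L)) {
    .stopf("need >= %d points (got %d)", if (free_a2) 4L else 3L, length(x))
  }
  tau <- mixing_time(focused_width(geom, x), fluid)
  dh0_0 <- min(y)
  a2_0 <- if (free_a2) 1 else fix_alpha2
  a1_0 <- max(y[which.min(x)] - dh0_0, 1) / max(tau)^a2_0
  df <- data.frame(tau = tau, y = y)
  fit <- tryCatch({
    if (free_a2) {
      minpack.lm::nlsLM(y ~ a1 * tau^a2 + dh0, data = df,
                        start = list(a1 = a1_0, a2 = a2_0, dh0 = dh0_0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ a1 * tau^fix_alpha2 + dh0, data = df,
                        start = list(a1 = a1_0, dh0 = dh0_0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) .stopf("mixing-time size-model fit failed: %s",
                                conditionMessage(e)))
  cf <- coef(fit)
  a1 <- cf[["a1"]]
  a2 <- if (free_a2) cf[["a2"]] else fix_alpha2
  ## tau_mix = Ctau * (1 + Q_R)^-2  =>  beta1 = alpha1 * Ctau^alpha2
  Ctau <- (geom$width_um * .UM_TO_M / 1.5)^2 / (4 * fluid$D_m)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(cf)) else sqrt(diag(V))
  names(se) <- names(cf)
  yhat <- as.numeric(predict(fit))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  out <- .new_size_model_fit(
    c(beta1 = a1 * Ctau^a2, beta2 = 2 * a2, D_H0 = cf[["dh0"]]),
    c(beta1 = NA_real_, beta2 = if (free_a2) 2 * se[["a2"]] else 0,
      D_H0 = se[["dh0"]]),
    r2 = r2, beta2_fixed = !free_a2,
    corr_b1_dh0 = if (!is.null(V) && all(diag(V) > 0))
      stats::cov2cor(V)["a1", "dh0"] else NA_real_,
    n = length(x), data = d, fitted = yhat, parameterization = "tau")
  out$alpha1 <- a1
  out$se_alpha1 <- se[["a1"]]
  out
}

#' @export
print.size_model_fit <- function(x, ...) {
  form <- if (x$parameterization == "tau") {
    "D_H = alpha1 * tau_mix^alpha2 + D_H0"
  } else {
    "D_H = beta1 * (1 + Q_R)^(-beta2) + D_H0"
  }
  cat("Empirical size-model fit: ", form, "\n", sep = "")
  cat(sprintf("  beta1 = %.4g +/- %.2g nm\n", x$beta1, x$se_beta1))
  cat(sprintf("  beta2 = %.4g +/- %.2g%s\n", x$beta2, x$se_beta2,
              if (x$beta2_fixed) " (fixed)" else ""))
  cat(sprintf("  D_H0  = %.4g +/- %.2g nm\n", x$D_H0, x$se_DH0))
  cat(sprintf("  R^2 = %.3f on %d points (corr(beta1, D_H0) = %.2f)\n",
              x$r2, x$n_points, x$corr_beta1_DH0))
  invisible(x)
}

#' Correlation suite for size versus flow rate ratio
#'
#' Kendall's tau (tau-b, normal-approximation p unless `exact = TRUE`)
#' and Spearman's rho of `D_H` versus `Q_R` assess the monotonic trend
#' without assuming a functional form; Pearson's r of `D_H` versus
#' `1/Q_R` and versus `1/Q_R^2` probe the near-linear dependencies
#' suggested by the focused-width and mixing-time scalings.  Run on
#' replicate-level points.
#'
#' @param series A [size_series()].
#' @param exact Use exact p-values for the rank tests (only sensible for
#'   small tie-free samples).
#' @return Object of class `correlation_report` with coefficients and
#'   two-sided p-values; all `NA` (with `degenerate = TRUE`) when either
#'   variable is constant.
#' @export
correlation_suite <- function(series, exact = FALSE) {
  stopifnot(inherits(series, "size_series"))
  x <- series$qr; y <- series$dh
  if (length(x) < 3) .stopf("need >= 3 points")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(kendall_tau = NA_real_, kendall_p = NA_real_,
                          spearman_rho = NA_real_, spearman_p = NA_real_,
                          pearson_r_invQ = NA_real_, pearson_p_invQ = NA_real_,
                          pearson_r_invQ2 = NA_real_, pearson_p_invQ2 = NA_real_,
                          n_points = length(x), degenerate = TRUE),
                     class = "correlation_report"))
  }
  kt <- suppressWarnings(cor.test(x, y, method = "kendall", exact = exact))
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  p1 <- cor.test(1 / x, y, method = "pearson")
  p2 <- cor.test(1 / x^2, y, method = "pearson")
  structure(list(kendall_tau = unname(kt$estimate), kendall_p = kt$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 pearson_r_invQ = unname(p1$estimate), pearson_p_invQ = p1$p.value,
                 pearson_r_invQ2 = unname(p2$estimate), pearson_p_invQ2 = p2$p.value,
                 n_points = length(x), degenerate = FALSE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlations of D_H with Q_R (%d points):\n", x$n_points))
  cat(sprintf("  Kendall tau        %.3f (p = %.3g)\n", x$kendall_tau, x$kendall_p))
  cat(sprintf("  Spearman rho       %.3f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  cat(sprintf("  Pearson r vs 1/Q   %.3f (p = %.3g)\n", x$pearson_r_invQ, x$pearson_p_invQ))
  cat(sprintf("  Pearson r vs 1/Q^2 %.3f (p = %.3g)\n", x$pearson_r_invQ2, x$pearson_p_invQ2))
  invisible(x)
}

#' ANCOVA comparison of two size series
#'
#' Fits the linear model `D_H ~ predictor * group` on the pooled
#' replicate-level data of two series, with the predictor being `1/Q_R`
#' or `1/Q_R^2`.  The interaction coefficient tests whether the slopes
#' differ; the group main effect tests whether the intercepts differ.
#'
#' @param series_a,series_b Two [size_series()] objects.
#' @param predictor `"invQ"` for `1/Q_R` or `"invQ2"` for `1/Q_R^2`.
#' @return Object of class `ancova_report` with `slope_p`, `intercept_p`,
#'   the estimated slope/intercept differences, and the underlying `lm`
#'   fit.
#' @export
ancova_compare <- function(series_a, series_b, predictor = c("invQ", "invQ2")) {
  stopifnot(inherits(series_a, "size_series"), inherits(series_b, "size_series"))
  predictor <- match.arg(predictor)
  tr <- function(q) if (predictor == "invQ") 1 / q else 1 / q^2
  la <- attr(series_a, "label"); lb <- attr(series_b, "label")
  if (is.null(la) || !nzchar(la) || identical(la, lb)) { la <- "A"; lb <- "B" }
  df <- data.frame(x = c(tr(series_a$qr), tr(series_b$qr)),
                   dh = c(series_a$dh, series_b$dh),
                   group = factor(rep(c(la, lb),
                                      c(nrow(series_a), nrow(series_b)))))
  fit <- lm(dh ~ x * group, data = df)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 4) .stopf("singular ANCOVA design")
  grp_row <- grep("^group", rownames(cf))[1]
  int_row <- grep(":", rownames(cf))[1]
  structure(list(slope_p = cf[int_row, 4], intercept_p = cf[grp_row, 4],
                 slope_diff = cf[int_row, 1], intercept_diff = cf[grp_row, 1],
                 predictor = predictor, group_labels = levels(df$group),
                 model = fit),
            class = "ancova_report")
}

#' @export
print.ancova_report <- function(x, ...) {
  cat(sprintf("ANCOVA (%s vs %s, predictor %s):\n",
              x$group_labels[1], x$group_labels[2],
              if (x$predictor == "invQ") "1/Q_R" else "1/Q_R^2"))
  cat(sprintf("  slope difference     %.4g (p = %.3g)\n", x$slope_diff, x$slope_p))
  cat(sprintf("  intercept difference %.4g (p = %.3g)\n", x$intercept_diff, x$intercept_p))
  invisible(x)
}
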