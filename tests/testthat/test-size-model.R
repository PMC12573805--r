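test_that("noiseless size-model fits recover the generator truth exactly", {
  s <- gen_size_series(beta1 = 2000, beta2 = 2, dh0 = 134, noise_sd = 0)
  free <- fit_size_model(s)
  expect_equal(free$beta1, 2000, tolerance = 1e-6)
  expect_equal(free$beta2, 2, tolerance = 1e-7)
  expect_equal(free$D_H0, 134, tolerance = 1e-6)
  expect_equal(free$r2, 1, tolerance = 1e-12)
  fixed <- fit_size_model(s, fix_beta2 = 2)
  expect_equal(fixed$D_H0, 134, tolerance = 1e-8)
  expect_true(fixed$beta2_fixed)
  expect_identical(fixed$beta2, 2)
})

test_that("fixed and free exponents agree on well-determined data", {
  set.seed(5)
  s <- gen_size_series(noise_sd = 1, qr = c(4, 6, 8, 10, 15, 20, 30))
  free <- fit_size_model(s)
  fixed <- fit_size_model(s, fix_beta2 = 2)
  expect_lt(abs(free$D_H0 - fixed$D_H0), free$se_DH0)
  expect_gte(fixed$r2, free$r2 - 0.05)
})

test_that("mixing-time and flow-rate-ratio parameterizations agree", {
  s <- gen_size_series(noise_sd = 0)
  f_qr <- fit_size_model(s)
  f_tau <- fit_size_model_tau(s)
  expect_equal(f_tau$D_H0, f_qr$D_H0, tolerance = 1e-3)
  expect_equal(f_tau$beta2, f_qr$beta2, tolerance = 1e-4)
  expect_equal(f_tau$alpha2, f_qr$beta2 / 2, tolerance = 1e-4)
  # beta1 translated through tau_mix(Q_R) matches as well
  expect_equal(f_tau$beta1, f_qr$beta1, tolerance = 1e-3)
  # an alpha2 = 1 truth is a beta2 = 2 truth
  f_tau1 <- fit_size_model_tau(s, fix_alpha2 = 1)
  expect_equal(f_tau1$beta2, 2)
  expect_equal(f_tau1$D_H0, 134, tolerance = 1e-6)
  # fitted curve is monotone in Q_R because tau_mix is
  expect_true(all(diff(f_tau$fitted[order(f_tau$data$qr)]) < 0))
})

test_that("degenerate constant series warns instead of failing", {
  s <- size_series(c(8, 10, 15, 20, 30), rep(150, 5))
  expect_warning(fit <- fit_size_model(s, fix_beta2 = 2), "degenerate")
  expect_equal(fit$beta1, 0)
  expect_equal(fit$D_H0, 150)
})

test_that("beta1 and D_H0 estimates are strongly correlated by design", {
  set.seed(9)
  s <- gen_size_series(noise_sd = 4)
  fit <- fit_size_model(s, fix_beta2 = 2)
  expect_gt(abs(fit$corr_beta1_DH0), 0.5)
})

test_that("monotone data give tau = rho = -1 and the tau-b oracle holds", {
  s <- size_series(c(8, 10, 15, 20, 30), c(160, 150, 145, 140, 134))
  cs <- correlation_suite(s)
  expect_equal(cs$kendall_tau, -1)
  expect_equal(cs$spearman_rho, -1)
  expect_gt(cs$pearson_r_invQ, 0.9)

  # brute-force concordant/discordant pair counting with tie correction
  tau_oracle <- function(x, y) {
    n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
      if (a == 0 && b == 0) next
      if (a == 0) tx <- tx + 1
      else if (b == 0) ty <- ty + 1
      else if (a == b) C <- C + 1
      else D <- D + 1
    }
    (C - D) / sqrt((C + D + tx) * (C + D + ty))
  }
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    x <- sample(1:5, n, replace = TRUE) # ties on purpose
    y <- round(rnorm(n, 150, 10))
    if (sd(x) == 0 || sd(y) == 0) next
    cs <- correlation_suite(size_series(x, y))
    expect_equal(cs$kendall_tau, tau_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("constant input flags degenerate correlations", {
  s <- size_series(c(8, 10, 15), rep(140, 3))
  cs <- correlation_suite(s)
  expect_true(cs$degenerate)
  expect_true(is.na(cs$kendall_tau))
})

test_that("ANCOVA separates formulations with different slopes", {
  # identical series: estimated differences are zero
  s1 <- gen_size_series(seed = 4, label = "A")
  s1b <- s1; attr(s1b, "label") <- "B"
  same <- ancova_compare(s1, s1b, "invQ")
  expect_equal(same$slope_diff, 0, tolerance = 1e-10)
  expect_equal(same$intercept_diff, 0, tolerance = 1e-10)
  expect_gt(same$slope_p, 0.99)

  # slope difference ~5x the residual SD is detected at n = 15/group
  set.seed(31)
  hits <- 0
  for (r in 1:50) {
    a <- gen_size_series(beta1 = 2000, dh0 = 134, noise_sd = 4)
    b <- gen_size_series(beta1 = 4500, dh0 = 134, noise_sd = 4, label = "B")
    if (ancova_compare(a, b, "invQ")$slope_p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.9)
  # the quadratic predictor variant runs too
  a <- gen_size_series(seed = 8)
  b <- gen_size_series(beta1 = 4500, seed = 9, label = "B")
  expect_s3_class(ancova_compare(a, b, "invQ2"), "ancova_report")
})

test_that("weighted and replicate-level fitting modes work", {
  set.seed(12)
  s <- gen_size_series(noise_sd = 4)
  frep <- fit_size_model(s, fix_beta2 = 2, use_means = FALSE)
  expect_equal(frep$n_points, nrow(s))
  fw <- fit_size_model(s, fix_beta2 = 2, weight_sem = TRUE)
  expect_true(is.finite(fw$D_H0))
  expect_lt(abs(fw$D_H0 - 134), 15)
})
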