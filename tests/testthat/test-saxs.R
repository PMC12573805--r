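q110 <- function(a_nm) 2 * pi * sqrt(2) / (a_nm * 10)

test_that("pattern reader handles comments, commas and shuffled rows", {
  f <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.02, 0.5, length.out = 40)
  I <- 100 / (1 + (q * 40)^2) + 3
  writeLines(c("# synthetic test pattern", "# q  I",
               sprintf("%.15g, %.15g", q, I)), f)
  pat <- read_pattern(f)
  expect_s3_class(pat, "scattering_pattern")
  expect_equal(pat$q, q)
  expect_equal(pat$intensity, I)

  # shuffled rows come back sorted to the same pattern
  f2 <- withr::local_tempfile(fileext = ".dat")
  ord <- sample(length(q))
  writeLines(sprintf("%.15g %.15g", q[ord], I[ord]), f2)
  pat2 <- read_pattern(f2)
  expect_equal(pat2$q, pat$q)
  expect_equal(pat2$intensity, pat$intensity)

  f3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.1 5", "0.1 6", "0.2 7"), f3)
  expect_error(read_pattern(f3), "duplicated")
  f4 <- withr::local_tempfile(fileext = ".dat")
  writeLines("0.1 5", f4)
  expect_error(read_pattern(f4), "fewer than 2")
})

test_that("Pn3m reflection table and position ratios", {
  rs <- reflection_ratios("pn3m", 6)
  expect_equal(rs$root_sums, c(sqrt(2), sqrt(3), 2, sqrt(6), sqrt(8), 3))
  expect_equal(rs$ratios, rs$root_sums / sqrt(2))
  # squared ratios are N/2 for the allowed N
  expect_equal(rs$ratios^2 * 2, c(2, 3, 4, 6, 8, 9))
  expect_equal(reflection_ratios("pn3m", 1)$ratios, 1)
  expect_error(reflection_ratios("ia3d", 6), "not implemented")
  expect_error(reflection_ratios("pn3m", 9), "tabulated")
})

test_that("lattice-parameter regression round-trips and is low-leverage", {
  a <- 6.7
  qs <- q110(a) / sqrt(2) * reflection_ratios("pn3m", 6)$root_sums
  fit <- fit_lattice_parameter(qs)
  expect_equal(fit$a_nm, a, tolerance = 1e-12)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-15)
  expect_equal(fit$n_peaks, 6L)
  # +1% on one peak moves a by far less than 1%
  qs2 <- qs; qs2[1] <- qs2[1] * 1.01
  expect_lt(abs(fit_lattice_parameter(qs2)$a_nm - a) / a, 0.01)
  # trailing truncation (only the first two reflections visible)
  fit2 <- fit_lattice_parameter(qs[1:2])
  expect_equal(fit2$a_nm, a, tolerance = 1e-12)
  # gap assignment via mask
  fit3 <- fit_lattice_parameter(qs[c(1, 3, 5)], mask = c(1, 3, 5))
  expect_equal(fit3$a_nm, a, tolerance = 1e-12)
  expect_error(fit_lattice_parameter(c(-0.1, 0.2)), "positive")
})

test_that("peak detection finds all six reflections and nothing else", {
  pat <- gen_saxs_pattern(a_nm = 6.7, xi_nm = 81)
  truth <- attr(pat, "truth")$q_hkl
  pk <- detect_peaks(pat)
  expect_length(pk, 6)
  dq <- diff(pat$q)[1]
  expect_true(all(abs(pk - truth) < dq))

  set.seed(11)
  noisy <- scattering_pattern(
    pat$q, pat$intensity * (1 + rnorm(length(pat$q), sd = 0.02)))
  pk2 <- detect_peaks(noisy)
  expect_length(pk2, 6)
  expect_true(all(abs(pk2 - truth) / truth < 0.005))

  flat <- scattering_pattern(seq(0.05, 0.5, length.out = 200), rep(7, 200))
  expect_length(detect_peaks(flat), 0)
})

test_that("Lorentzian fit recovers width, offset and the xi = pi/k bound", {
  k_true <- 3.879e-3
  pat <- gen_saxs_pattern(a_nm = 6.7, xi_nm = pi / k_true * 0.1, n_peaks = 1)
  fit <- fit_lorentzian(pat)
  expect_lt(abs(fit$k - k_true) / k_true, 1e-3)
  expect_equal(fit$xi_nm, 81.0, tolerance = 1e-3)
  expect_equal(fit$q0, attr(pat, "truth")$q_hkl[1], tolerance = 1e-6)
  # adding a constant offset only moves B
  shifted <- scattering_pattern(pat$q, pat$intensity + 25)
  fit2 <- fit_lorentzian(shifted)
  expect_equal(fit2$B - fit$B, 25, tolerance = 1e-3)
  expect_equal(fit2$k, fit$k, tolerance = 1e-6)
  # halving the width doubles the domain-size bound
  pat3 <- gen_saxs_pattern(a_nm = 6.7, xi_nm = 2 * pi / k_true * 0.1,
                           n_peaks = 1)
  fit3 <- fit_lorentzian(pat3)
  expect_equal(fit3$xi_nm / fit$xi_nm, 2, tolerance = 1e-3)
})

test_that("noiseless Lorentzian parameters match generator truth to 1e-6", {
  pat <- gen_saxs_pattern(a_nm = 6.7, xi_nm = 81, n_peaks = 1,
                          peak_height = 500, background = 20, n_q = 3000)
  tr <- attr(pat, "truth")
  fit <- fit_lorentzian(pat)
  expect_equal(fit$k, tr$k, tolerance = 1e-6)
  expect_equal(fit$q0, tr$q_hkl[1], tolerance = 1e-6)
  expect_equal(fit$B, 20, tolerance = 1e-4)
  expect_equal(fit$A, 500 * tr$k^2, tolerance = 1e-5)
})

test_that("Lorentzian width recovery under 1% Gaussian noise", {
  k_true <- pi / 810
  errs <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    pat <- gen_saxs_pattern(a_nm = 6.7, xi_nm = 81, n_peaks = 1)
    noisy <- scattering_pattern(
      pat$q,
      pat$intensity + rnorm(length(pat$q), sd = 0.01 * max(pat$intensity)))
    errs[s] <- abs(fit_lorentzian(noisy)$k - k_true) / k_true
  }
  expect_true(all(errs < 0.05))
})

test_that("bilayer thickness root-solve matches the nodal-surface relation", {
  res <- bilayer_thickness(6.7, 0.74)
  expect_equal(res$delta_nm, 2.87, tolerance = 2e-3)
  expect_true(res$x > 0 && res$x < 0.39)
  # forward/inverse round-trip at 1e-10 relative
  for (phi in c(0.05, 0.3, 0.5, 0.74, 0.9)) {
    r <- bilayer_thickness(6.7, phi)
    expect_equal(bilayer_volume_fraction(r$delta_nm, 6.7), phi,
                 tolerance = 1e-10)
  }
  # phi -> 0 gives delta -> 0
  expect_lt(bilayer_thickness(6.7, 1e-8)$delta_nm, 1e-6)
  expect_error(bilayer_thickness(6.7, 1.05), "attainable")
  expect_error(bilayer_thickness(6.7, 0), "attainable")
})

test_that("the bisection bracket contains exactly one sign change", {
  # dense scan oracle for root uniqueness on the physical branch
  for (phi in c(0.01, 0.2, 0.5, 0.74, 0.97)) {
    x <- seq(1e-4, 0.39, by = 1e-4)
    g <- 2 * 1.919 * x + (4 * pi * (-2) / 3) * x^3 - phi
    expect_equal(sum(diff(sign(g)) != 0), 1)
  }
})

test_that("weight-to-volume conversion and d-spacing utilities", {
  expect_equal(weight_to_volume_fraction(0.5, 1, 1), 0.5)
  expect_equal(weight_to_volume_fraction(0.72, 0.903, 1.0), 0.740,
               tolerance = 1e-3)
  expect_equal(weight_to_volume_fraction(0.72, 0.94, 1.0), 0.732,
               tolerance = 1e-3)
  expect_equal(d_spacing(0.045), 13.96, tolerance = 1e-3)
  expect_equal(d_spacing(2 * pi), 0.1)
  q <- c(0.02, 0.13, 0.4)
  expect_equal(d_spacing(q) * q, rep(2 * pi * 0.1, 3)) # d in nm, q in 1/A
  expect_error(d_spacing(0), "q must be > 0")
  # sanity: the first reflection of a 6.7 nm lattice sits inside the
  # instrument window 0.0125-0.75 1/A
  expect_true(q110(6.7) > 0.0125 && q110(6.7) < 0.75)
})
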