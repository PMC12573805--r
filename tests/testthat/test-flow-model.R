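test_that("flow partitioning satisfies the junction identities exactly", {
  cases <- list(c(100, 0, 100, 0), # Q_T, Q_R, Q_m, Q_s
                c(100, 8, 100 / 9, 100 * 8 / 18),
                c(100, 30, 100 / 31, 100 * 30 / 62))
  for (cs in cases) {
    fc <- make_flow_condition(cs[1], cs[2])
    expect_equal(fc$Q_m, cs[3])
    expect_equal(fc$Q_s, cs[4])
    expect_equal(fc$Q_T, fc$Q_m + 2 * fc$Q_s)
    expect_equal(fc$Dil_R, cs[2])
    if (fc$Q_m > 0) expect_equal(2 * fc$Q_s / fc$Q_m, cs[2])
  }
  expect_error(make_flow_condition(-1, 5), "Q_T")
  expect_error(make_flow_condition(100, -0.1), "Q_R")
})

test_that("recomputing (Q_T, Q_R) from the partition is the identity", {
  for (qr in c(0, 0.5, 3, 8, 15, 30, 100)) {
    fc <- make_flow_condition(73, qr)
    expect_equal(fc$Q_m + 2 * fc$Q_s, 73)
    if (qr > 0) expect_equal(2 * fc$Q_s / fc$Q_m, qr)
  }
})

test_that("focused width follows the 1.5(1+Q_R) squeeze law", {
  geom <- device_geometry()
  expect_equal(focused_width(geom, 0), 100 / 1.5)
  expect_equal(focused_width(geom, 8), 100 / 13.5)
  expect_equal(focused_width(geom, 30), 100 / 46.5)
  qr <- 0:100
  w <- focused_width(geom, qr)
  expect_true(all(diff(w) < 0))
  # exact inversion of the squeeze law on the whole grid
  expect_equal(w * 1.5 * (1 + qr), rep(100, length(qr)))
  expect_true(all(w <= geom$width_um / 1.5))
})

test_that("mixing time is diffusive and matches the ~21 to ~2 ms window", {
  fl <- fluid_properties()
  expect_identical(mixing_time(0, fl), 0)
  t8 <- mixing_time(focused_width(device_geometry(), 8), fl)
  t30 <- mixing_time(focused_width(device_geometry(), 30), fl)
  expect_equal(round(1000 * t8), 21)
  expect_equal(round(1000 * t30), 2)
  expect_error(mixing_time(5, fluid_properties(D_m = 1)), NA)
  expect_error(fluid_properties(D_m = -1), "positive")
})

test_that("mixing time scales as (1+Q_R)^-2 through the focused width", {
  geom <- device_geometry()
  fl <- fluid_properties()
  qr <- 0:100
  tm <- mixing_time(focused_width(geom, qr), fl)
  expect_equal(tm * (1 + qr)^2, rep(tm[1], length(qr)))
})

test_that("residence time is channel volume over flow rate", {
  geom <- device_geometry()
  expect_equal(residence_time(geom, 100), 0.486)
  expect_equal(residence_time(geom, 200), residence_time(geom, 100) / 2)
  # comparison-device arithmetic: short wide channel at high flow
  other <- device_geometry(width_um = 150, height_um = 150, length_mm = 35)
  expect_equal(residence_time(other, 440), 0.10739, tolerance = 1e-4)
  expect_error(residence_time(geom, 0), "Q_T")
})

test_that("residence/mixing ratio spans the laminar operating window", {
  geom <- device_geometry()
  fl <- fluid_properties()
  ratio <- function(qr) {
    residence_time(geom, 100) / mixing_time(focused_width(geom, qr), fl)
  }
  expect_lt(22, ratio(8))    # brackets [22, 270] from below at Q_R = 8
  expect_gt(ratio(30), 270)  # and from above at Q_R = 30
  expect_equal(ratio(8), 23.135, tolerance = 1e-3)
  expect_equal(ratio(30), 274.48, tolerance = 1e-3)
})

test_that("Reynolds number is ~17 at the working point and linear in Q_T", {
  geom <- device_geometry()
  fl <- fluid_properties(density = 1000, viscosity = 1.0e-3)
  re <- reynolds_number(geom, 100, fl)
  expect_equal(re, 50 / 3, tolerance = 1e-12)
  expect_equal(round(re), 17)
  expect_equal(reynolds_number(geom, 0, fl), 0)
  expect_equal(reynolds_number(geom, 250, fl), 2.5 * re)
  # rectangular channel uses the hydraulic diameter
  rect <- device_geometry(width_um = 200, height_um = 100, length_mm = 81)
  v <- (100 * 1e-9 / 60) / (200e-6 * 100e-6)
  expect_equal(reynolds_number(rect, 100, fl),
               1000 * v * (2 * 200e-6 * 100e-6 / 300e-6) / 1e-3)
})

test_that("dilution maps precursor concentrations to final ones", {
  expect_equal(final_concentration(c(1.0, 1.5, 2.0), 30),
               c(1, 1.5, 2) / 31)
  expect_equal(round(final_concentration(c(1.0, 1.5, 2.0), 30), 3),
               c(0.032, 0.048, 0.065))
  expect_equal(final_concentration(0.7, 0), 0.7)
  expect_error(final_concentration(-1, 5), ">= 0")
})

test_that("post-dilution volume standardises the precursor fraction", {
  expect_equal(postdilution_volume(123, 30, 30), 0)
  expect_equal(postdilution_volume(100, 8, 30), 100 * 22 / 9)
  expect_equal(postdilution_volume(90, 15, 30), 90 * 15 / 16)
  # volume conservation: precursor fraction hits 1/(1+target) exactly
  for (qr in c(8, 10, 15, 20)) {
    V <- 100
    add <- postdilution_volume(V, qr, 30)
    precursor <- V / (1 + qr)
    expect_equal(precursor / (V + add), 1 / 31)
  }
  expect_error(postdilution_volume(100, 30, 8), "concentrate")
})

test_that("Damkohler number and regime classification", {
  expect_equal(damkohler(0.021, 0.021), 1)
  expect_equal(damkohler(0.002, 0.021), 2 / 21)
  expect_error(damkohler(0, 1), "> 0")
  expect_identical(damkohler_regime(c(0.095, 1, 4)),
                   c("nucleation-dominated", "balanced", "transport-controlled"))
})

test_that("nucleation-rate scaling is the exp(-(ln S)^-2) law", {
  expect_equal(nucleation_rate_scaling(exp(1)), exp(-1))
  expect_lt(nucleation_rate_scaling(1 + 1e-8), 1e-10) # S -> 1+ limit
  s <- seq(1.01, 100, length.out = 200)
  j <- nucleation_rate_scaling(s)
  expect_true(all(diff(j) > 0))
  expect_true(all(j >= 0 & j < 1))
  expect_error(nucleation_rate_scaling(1), "S > 1")
  expect_error(nucleation_rate_scaling(0.5), "S > 1")
  st <- supersaturation_state(2, 1)
  expect_equal(st$S, 2)
  expect_equal(st$J_rel, nucleation_rate_scaling(2))
  expect_true(is.na(supersaturation_state(1, 2)$J_rel))
})

test_that("lipid partition between cubosome and same-size vesicle", {
  # shell-geometry oracle computed from the sphere/shell volume balance
  r <- 35; delta <- 2.87; phi <- 0.74
  oracle <- (phi * r^3) / (phi * r^3 + (r^3 - (r - delta)^3))
  expect_equal(lipid_partition_fraction(70, 2.87, 0.74), oracle)
  expect_equal(oracle, 0.7657, tolerance = 1e-4)
  # delta -> diameter/2 at phi = 1: both particles fully lipid
  expect_equal(lipid_partition_fraction(70, 35 - 1e-9, 1), 0.5,
               tolerance = 1e-6)
  phis <- seq(0.1, 1, by = 0.1)
  fr <- vapply(phis, function(p) lipid_partition_fraction(70, 2.87, p),
               numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_error(lipid_partition_fraction(70, 40, 0.74), "delta")
})
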