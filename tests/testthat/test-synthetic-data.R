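test_that("static spectrum matches the closed-form Lorentzian", {
  ax <- test_axis(4096)
  sp <- simulate_static_spectrum(peak_set(-84, 0.1, 1), ax)
  # height at center 2A/(pi w); the grid may straddle the center slightly
  expect_equal(max(sp$intensity), 2 / (pi * 0.1), tolerance = 1e-3)
  expect_equal(ax$ppm[which.max(sp$intensity)], -84, tolerance = 1e-3)
  # numerical integral over a wide axis recovers the area within 1%
  wide <- frequency_axis(-80, -88, 16384)
  spw <- simulate_static_spectrum(peak_set(-84, 0.1, 1), wide)
  expect_equal(trapz_area(wide$ppm, spw$intensity), 1, tolerance = 0.01)
  # empty peak set gives a flat zero spectrum
  flat <- simulate_static_spectrum(empty <- peak_set(numeric(0),
                                                     numeric(0),
                                                     numeric(0)), ax)
  expect_true(all(flat$intensity == 0))
  # peaks outside coverage are rejected
  expect_error(simulate_static_spectrum(peak_set(-83.31, 0.5, 1), ax),
               "coverage")
})

test_that("spectrum simulation is reproducible under a fixed seed", {
  ax <- test_axis()
  pk <- peak_set(-84, 0.1, 1)
  a <- simulate_static_spectrum(pk, ax, noise_sd = 0.1, seed = 42)
  b <- simulate_static_spectrum(pk, ax, noise_sd = 0.1, seed = 42)
  c <- simulate_static_spectrum(pk, ax, noise_sd = 0.1, seed = 43)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("exchange lineshape reduces to independent Lorentzians at k = 0", {
  ax <- test_axis(4096)
  r2 <- c(40, 80)
  m <- two_site_model(c(-83.7, -84.3), r2, c(0.4, 0.6), k_ex = 0)
  sp <- simulate_exchange_spectrum(m, ax)
  f <- ax$spectrometer_freq
  # FWHM in Hz = R2/pi, converted to ppm, with population-weighted areas
  ref <- mixture_profile(ax$ppm,
                         peak_set(c(-83.7, -84.3),
                                  r2 / pi / f, c(0.4, 0.6)))
  expect_equal(sp$intensity, ref, tolerance = 1e-9)
})

test_that("fast exchange collapses to a single population-weighted peak", {
  ax <- test_axis(4096)
  m <- two_site_model(c(-83.7, -84.3), c(40, 40), c(0.5, 0.5), k_ex = 1e6)
  sp <- simulate_exchange_spectrum(m, ax)
  expect_equal(ax$ppm[which.max(sp$intensity)], -84, tolerance = 2e-3)
  m2 <- two_site_model(c(-83.7, -84.3), c(40, 40), c(0.25, 0.75),
                       k_ex = 1e6)
  sp2 <- simulate_exchange_spectrum(m2, ax)
  expect_equal(ax$ppm[which.max(sp2$intensity)],
               0.25 * -83.7 + 0.75 * -84.3, tolerance = 2e-3)
})

test_that("matrix lineshape matches the closed two-site form in all regimes", {
  ax <- test_axis(2048)
  shifts <- c(-83.7, -84.3)
  dw <- 2 * pi * ax$spectrometer_freq * abs(diff(shifts))  # rad/s
  for (kex in c(0.01 * dw, dw, 100 * dw)) {
    for (p in list(c(0.5, 0.5), c(0.3, 0.7))) {
      m <- two_site_model(shifts, c(50, 120), p, k_ex = kex)
      sp <- simulate_exchange_spectrum(m, ax)
      cf <- two_site_lineshape(ax$ppm, shifts, c(50, 120), p, kex)
      expect_lt(max(abs(sp$intensity - cf)) / max(abs(cf)), 1e-6)
    }
  }
})

test_that("total exchange-spectrum intensity is conserved across k_ex", {
  ax <- frequency_axis(-80, -88, 8192)
  areas <- vapply(c(0, 10, 1e3, 1e5), function(kex) {
    m <- two_site_model(c(-83.7, -84.3), c(40, 60), c(0.5, 0.5),
                        k_ex = kex)
    trapz_area(ax$ppm, simulate_exchange_spectrum(m, ax)$intensity)
  }, numeric(1))
  expect_true(all(abs(areas - areas[1]) / areas[1] < 0.01))
})

test_that("saturation series follows the two-site transfer decay", {
  s <- simulate_saturation_series(r1 = 2.7, k = 1.2,
                                  times = c(0, 0.5, 10))
  expect_equal(s$on_intensity[1], 1)                 # t = 0
  expect_equal(s$on_intensity[3], 2.7 / 3.9, tolerance = 1e-6)
  s0 <- simulate_saturation_series(r1 = 2.7, k = 0,
                                   times = seq(0, 2, 0.5))
  expect_true(all(s0$on_intensity == s0$i0))          # no transfer
})

test_that("relaxation series match their closed forms", {
  ir <- simulate_relaxation_series("inversion_recovery", rate = 2,
                                   times = c(0, log(2) / 2, 5))
  expect_equal(ir$intensity[1], -1)                   # perfect inversion
  expect_equal(ir$intensity[2], 0, tolerance = 1e-12) # null point
  cp <- simulate_relaxation_series("cpmg", rate = 4, times = c(0, 1 / 4))
  expect_equal(cp$intensity[2], exp(-1), tolerance = 1e-12)
})

test_that("dose-response generator hits 4PL anchor points", {
  concs <- 10^seq(-9, -4, length.out = 11)  # includes the EC50 exactly
  d <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs)
  expect_equal(d$response[which.min(abs(d$conc_M - 1e-6))],
               (0.3 + 0.9) / 2, tolerance = 1e-9)
  y10 <- fourpl(1e-5, 0.3, 0.9, log10(1e-6), 1)
  expect_equal(y10, 0.3 + (0.9 - 0.3) * 10 / 11, tolerance = 1e-12)
  a <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs, noise_sd = 0.02,
                              n_outliers = 1, seed = 5)
  b <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs, noise_sd = 0.02,
                              n_outliers = 1, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$outlier_truth), 1)
})

test_that("competition assay reduces to tracer-only binding at zero competitor", {
  cc <- c(0, 10^seq(-10, -5, length.out = 11))
  curve <- simulate_competition_assay(ki = 5e-8, kd = 7.9e-9, lo = 5e-9,
                                      ro = 8e-9, competitor_concs = cc)
  expect_equal(curve$response[1], bound_tracer(5e-9, 8e-9, 7.9e-9),
               tolerance = 1e-9)
  # overwhelming competitor displaces everything
  huge <- simulate_competition_assay(ki = 5e-8, kd = 7.9e-9, lo = 5e-9,
                                     ro = 8e-9, competitor_concs = 1e6 * 5e-8)
  expect_lt(huge$response[1], 1e-12)
})

test_that("ensemble scenarios follow their class templates", {
  fa <- generate_ensemble_scenario("full_agonist", seed = 1)
  truth_fa <- fa$truth[!fa$truth$is_contaminant, ]
  expect_equal(nrow(truth_fa), 1)
  expect_lt(truth_fa$fwhm_ppm, 0.12)   # below the partial template range
  apo <- generate_ensemble_scenario("apo", seed = 1)
  truth_apo <- apo$truth[!apo$truth$is_contaminant, ]
  expect_equal(nrow(truth_apo), 2)
  expect_true(all(truth_apo$fwhm_ppm >= 0.12))
  a <- generate_ensemble_scenario("apo", seed = 2)
  b <- generate_ensemble_scenario("apo", seed = 2)
  c <- generate_ensemble_scenario("apo", seed = 3)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_false(identical(a$spectrum$intensity, c$spectrum$intensity))
  expect_error(generate_ensemble_scenario("mystery_ligand", seed = 1),
               "unknown ligand class")
})
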