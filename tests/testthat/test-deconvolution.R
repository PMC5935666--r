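test_that("axis calibration applies the additive reference offset", {
  ax <- frequency_axis(-118, -121, 4096)
  sp <- simulate_static_spectrum(peak_set(-119.400, 0.02, 1), ax,
                                 noise_sd = 0.05, seed = 1)
  cal <- calibrate_axis(sp, reference_raw_position = -119.400)
  expect_lt(abs(cal$meta$calibration_offset_ppm - (-0.122)), 2e-3)
  # the calibrated reference peak sits exactly on the defined shift
  i <- which.max(cal$intensity)
  expect_identical(cal$axis$ppm[i], -119.522)
  # already-calibrated spectrum: identity
  cal2 <- calibrate_axis(cal, reference_raw_position = -119.522)
  expect_equal(cal2$axis$ppm, cal$axis$ppm)
  # all shifts move by the same offset
  expect_equal(cal$axis$ppm - sp$axis$ppm,
               rep(cal$meta$calibration_offset_ppm, length(ax$ppm)))
})

test_that("calibration rejects a missing reference peak", {
  ax <- frequency_axis(-118, -121, 4096)
  sp <- simulate_static_spectrum(peak_set(-119.4, 0.02, 1), ax,
                                 noise_sd = 0.05, seed = 2)
  expect_error(calibrate_axis(sp, reference_raw_position = -120.5),
               "not found")
})

test_that("calibration can locate the reference in a separate channel", {
  sc <- generate_ensemble_scenario("apo", seed = 9)
  cal <- calibrate_axis(sc$spectrum, reference = sc$reference)
  # calibration undoes the injected raw offset (up to grid resolution)
  expect_lt(abs(cal$meta$calibration_offset_ppm + sc$raw_offset), 3e-3)
})

test_that("noise estimation is robust and rejects signal windows", {
  ax <- test_axis(8192)
  sp <- simulate_static_spectrum(peak_set(-84.5, 0.02, 0.3), ax,
                                 noise_sd = 1.0, seed = 3)
  est <- estimate_noise(sp, c(-83.35, -84.0))  # 4000+ signal-free points
  expect_gt(est, 0.95); expect_lt(est, 1.05)
  flat <- new_spectrum(ax, rep(0, 8192))
  expect_equal(estimate_noise(flat, c(-83.4, -84.0)), 0)
  big <- simulate_static_spectrum(peak_set(-83.7, 0.02, 5), ax,
                                  noise_sd = 0.05, seed = 4)
  expect_error(estimate_noise(big, c(-83.6, -83.8)), "signal")
  expect_error(estimate_noise(sp, c(-83.300, -83.302)), "fewer than 50")
})

test_that("noise-free mixture fit recovers parameters to optimizer tolerance", {
  sp <- simulate_static_spectrum(peak_set(-84, 0.08, 1), test_axis())
  fit <- fit_lorentzian_mixture(sp, 1, noise_sd = 1e-12)
  expect_equal(fit$peaks$center_ppm, -84, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm_ppm, 0.08, tolerance = 1e-6)
  expect_equal(fit$peaks$area, 1, tolerance = 1e-6)
  expect_lt(abs(fit$peaks$phase_rad), 1e-4)
})

test_that("mixture fit recovers one noisy peak within stated tolerances", {
  sp <- one_peak_spectrum(snr = 50, seed = 7)
  fit <- fit_lorentzian_mixture(sp, 1, seed = 7)
  expect_lt(abs(fit$peaks$center_ppm - (-84)), 0.002)
  expect_lt(abs(fit$peaks$area - 1) / 1, 0.03)
  expect_lt(abs(fit$peaks$fwhm_ppm - 0.08) / 0.08, 0.05)
})

test_that("mixture fit resolves two well-separated noisy peaks", {
  fx <- two_peak_spectrum(snr = 30, seed = 11)
  fit <- fit_lorentzian_mixture(fx$spectrum, 2, seed = 11)
  got <- sort(fit$peaks$center_ppm)
  want <- sort(fx$truth$center_ppm)
  expect_true(all(abs(got - want) < 0.005))
})

test_that("per-peak phases stay within pi/50 of the global phase", {
  fx <- two_peak_spectrum(snr = 30, seed = 13)
  fit <- fit_lorentzian_mixture(fx$spectrum, 2, seed = 13)
  expect_true(all(abs(fit$peaks$phase_rad - fit$global_phase) <=
                    pi / 50 + 1e-9))
})

test_that("model selection chooses the generating peak count", {
  # one peak, generous candidate space
  d1 <- deconvolve(one_peak_spectrum(snr = 50, seed = 21), max_peaks = 4,
                   seed = 21)
  expect_equal(d1$selected_n, 1)
  expect_equal(nrow(d1$criterion_table), 4)
  # two peaks separated by 3x FWHM
  fx <- two_peak_spectrum(snr = 30, seed = 22, sep = 0.24)
  d2 <- deconvolve(fx$spectrum, max_peaks = 3, seed = 22)
  expect_equal(d2$selected_n, 2)
  # unresolvable pair at FWHM/10 and SNR 10 collapses to one peak
  pku <- peak_set(c(-84, -84.008), c(0.08, 0.08), c(0.5, 0.5))
  spu <- simulate_static_spectrum(pku, test_axis(),
                                  noise_sd = (2 / (pi * 0.08)) / 10,
                                  seed = 23)
  d3 <- deconvolve(spu, max_peaks = 3, seed = 23)
  expect_equal(d3$selected_n, 1)
})

test_that("raw RSS is non-increasing while the criterion penalizes size", {
  d <- deconvolve(one_peak_spectrum(snr = 50, seed = 31), max_peaks = 4,
                  seed = 31)
  tab <- d$criterion_table
  expect_true(all(diff(tab$rss) < 1e-3 * tab$rss[1]))  # up to optimizer slack
  expect_equal(which.min(tab$criterion), 1)
  expect_gt(tab$criterion[4], tab$criterion[1])
})

test_that("fitted areas of a noise-free spectrum match the total integral", {
  # wide axis so the Lorentzian tails hold < 1% of the area
  ax <- frequency_axis(-80, -88, 8192)
  pk <- peak_set(c(-83.8, -84.2), c(0.08, 0.1), c(0.6, 0.4))
  sp <- simulate_static_spectrum(pk, ax)
  d <- fit_lorentzian_mixture(sp, 2, noise_sd = 1e-10)
  expect_equal(sum(d$peaks$area), trapz_area(ax$ppm, sp$intensity),
               tolerance = 0.01)
})

test_that("deconvolution is invariant under intensity rescaling", {
  sp <- one_peak_spectrum(snr = 50, seed = 51)
  d1 <- deconvolve(sp, max_peaks = 2, seed = 51)
  sp2 <- sp; sp2$intensity <- sp$intensity * 100
  d2 <- deconvolve(sp2, max_peaks = 2, seed = 51)
  expect_equal(d2$selected_n, d1$selected_n)
  expect_equal(d2$peaks$center_ppm, d1$peaks$center_ppm, tolerance = 1e-4)
  expect_equal(d2$peaks$area / 100, d1$peaks$area, tolerance = 1e-3)
})

test_that("fitted linewidth of an exchange-free peak reflects R2", {
  ax <- test_axis(2048)
  r2 <- 80
  m <- exchange_model(-84, r2, 1, matrix(0, 1, 1))
  sp <- simulate_exchange_spectrum(m, ax)
  fit <- fit_lorentzian_mixture(sp, 1, noise_sd = 1e-10)
  chk <- linewidth_consistency(fit$peaks$fwhm_ppm, ax$spectrometer_freq,
                               t2 = 1 / r2)
  expect_equal(chk$ratio, 1, tolerance = 0.03)
})

test_that("contaminant flagging excludes the free-label peak from fractions", {
  pk <- peak_set(c(-83.3, -84.0), c(0.012, 0.1), c(0.05, 1))
  ax <- frequency_axis(-82.8, -85, 2048)
  sp <- simulate_static_spectrum(pk, ax, noise_sd = 0.02, seed = 61)
  d <- deconvolve(sp, max_peaks = 3, contaminant_position = -83.3,
                  seed = 61)
  expect_true(any(d$peaks$is_contaminant))
  incl <- d$peaks[!d$peaks$is_contaminant, ]
  expect_equal(sum(incl$area_fraction), 1, tolerance = 1e-9)
})
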