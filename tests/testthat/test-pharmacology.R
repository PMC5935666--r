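test_that("4PL fit is an exact round trip on noise-free data", {
  concs <- 10^seq(-9, -4, length.out = 12)
  d <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs)
  fit <- fit_4pl(d$conc_M, d$response)
  expect_equal(fit$bottom, 0.3, tolerance = 1e-6)
  expect_equal(fit$top, 0.9, tolerance = 1e-6)
  expect_equal(fit$ec50, 1e-6, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_error(fit_4pl(concs, rep(0.5, 12)), "dose dependence")
})

test_that("4PL EC50 recovery is stable across noisy replicates", {
  concs <- 10^seq(-9, -4, length.out = 12)
  err <- vapply(1:100, function(s) {
    d <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs,
                                noise_sd = 0.01, n_replicates = 2,
                                seed = s)
    fit_4pl(d$conc_M, d$response)$logec50 - log10(1e-6)
  }, numeric(1))
  expect_true(all(abs(err) < 0.15))
})

test_that("ROUT flags nothing on clean duplicate-well curves at Q = 1%", {
  concs <- 10^seq(-9, -4, length.out = 12)
  n_flagged <- vapply(1:100, function(s) {
    d <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs,
                                noise_sd = 0.01, n_replicates = 2,
                                seed = s)
    rout_outliers(d$conc_M, d$response, q = 1)$n_flagged
  }, integer(1))
  expect_lte(sum(n_flagged > 0), 2)  # <= 2% false-flag runs
})

test_that("ROUT detects a single gross outlier", {
  concs <- 10^seq(-9, -4, length.out = 12)
  hits <- vapply(1:50, function(s) {
    d <- with_outlier(concs, s)
    res <- rout_outliers(d$conc_M, d$response, q = 1)
    all(which(d$outlier_truth) %in% which(res$data$outlier))
  }, logical(1))
  expect_gte(sum(hits), 48)
})

test_that("ROUT at Q = 0 flags nothing", {
  concs <- 10^seq(-9, -4, length.out = 12)
  d <- with_outlier(concs, 7)
  expect_equal(rout_outliers(d$conc_M, d$response, q = 0)$n_flagged, 0)
})

test_that("bound tracer solves the two-species equilibrium", {
  lb <- bound_tracer(lo = 5e-9, ro = 8e-9, kd = 7.9e-9)
  expect_equal(lb, 2.13e-9, tolerance = 5e-3)
  # cross-check by fixed-point mass-action iteration
  b <- 0
  for (i in 1:2000) b <- (8e-9 - b) * (5e-9 - b) / 7.9e-9 * 0.5 + b * 0.5
  expect_equal(lb, b, tolerance = 1e-6)
  # mass conservation and the equilibrium relation hold to 1e-10
  free_r <- 8e-9 - lb; free_l <- 5e-9 - lb
  expect_equal(free_r * free_l / lb, 7.9e-9, tolerance = 1e-10)
  # stoichiometric limit and empty-assay limit
  expect_equal(bound_tracer(5e-9, 8e-9, 1e-20), 5e-9, tolerance = 1e-6)
  expect_equal(bound_tracer(0, 8e-9, 7.9e-9), 0)
})

test_that("corrected Cheng-Prusoff matches direct arithmetic", {
  ki <- ki_from_ic50(ic50 = 100e-9, lo = 5e-9, ro = 8e-9, kd = 7.9e-9,
                     lb = 2.131e-9)
  # independent evaluation of the printed equation
  lb <- 2.131e-9
  expected <- lb * 100e-9 * 7.9e-9 /
    (5e-9 * 8e-9 + lb * (8e-9 - 5e-9 + lb - 7.9e-9))
  expect_equal(ki, expected, tolerance = 1e-12)
  expect_equal(ki, 49.4e-9, tolerance = 5e-3)
  # linear in IC50
  expect_equal(ki_from_ic50(200e-9, 5e-9, 8e-9, 7.9e-9, lb = 2.131e-9),
               2 * ki, tolerance = 1e-12)
})

test_that("exact IC50 inversion round-trips the competitive equilibrium", {
  lo <- 5e-9; ro <- 8e-9
  for (ki in c(1e-9, 1e-8, 1e-7, 1e-6)) {
    for (kd in c(5e-9, 2e-8, 5e-8)) {
      concs <- 10^seq(log10(ki) - 3, log10(ki) + 4, length.out = 400)
      curve <- simulate_competition_assay(ki, kd, lo, ro, concs)
      ic50 <- ic50_from_curve(curve)
      exact <- ki_from_ic50_exact(ic50, lo, ro, kd)
      # exact inversion recovers the generating Ki (interpolation-limited)
      expect_lt(abs(exact - ki) / ki, 0.01)
      # the published compact correction is an approximation: never more
      # accurate than the exact inversion on this grid
      approx_ki <- ki_from_ic50(ic50, lo, ro, kd)
      expect_gte(abs(approx_ki - ki) / ki, abs(exact - ki) / ki)
    }
  }
})

test_that("occupancy prediction follows the binding quadratic", {
  # high-affinity agonist at NMR sample concentrations is saturating
  occ <- predict_occupancy(ptot = 150e-6, ltot = 187.5e-6, ki = 4e-9)
  expect_gt(occ$occupancy, 0.99)
  expect_equal(predict_occupancy(150e-6, 0, 4e-9)$occupancy, 0)
  expect_lt(predict_occupancy(150e-6, 187.5e-6, 1e4)$occupancy, 1e-6)
  # monotone: increasing in ltot, decreasing in ki
  occs_l <- vapply(c(10e-6, 50e-6, 150e-6, 300e-6), function(l)
    predict_occupancy(150e-6, l, 1e-6)$occupancy, numeric(1))
  expect_true(all(diff(occs_l) > 0))
  occs_k <- vapply(c(1e-9, 1e-7, 1e-5, 1e-3), function(k)
    predict_occupancy(150e-6, 187.5e-6, k)$occupancy, numeric(1))
  expect_true(all(diff(occs_k) < 0))
})

test_that("endpoint interpolation uses the fit or falls back to data", {
  concs <- 10^seq(-9, -4, length.out = 12)
  d <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs)
  fit <- fit_4pl(d$conc_M, d$response)
  mid <- trfret_at_free_ligand(fit, 1e-6)
  expect_equal(mid$response, 0.6, tolerance = 1e-5)
  expect_false(mid$substituted)
  top <- trfret_at_free_ligand(fit, 10)
  expect_equal(top$response, 0.9, tolerance = 1e-3)
  sub <- trfret_at_free_ligand(NULL, 1.1e-6, data = d)
  expect_true(sub$substituted)
  expect_equal(sub$response,
               d$response[which.min(abs(log10(d$conc_M) - log10(1.1e-6)))])
})

test_that("shift-function correlation computes OLS and R^2", {
  x <- c(-84.2, -84.0, -83.8, -83.6, -83.4)
  fit <- correlate_shift_function(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # R^2 is invariant under affine rescaling of either axis
  y <- c(0.1, 0.5, 0.2, 0.9, 0.4)
  r2 <- correlate_shift_function(x, y)$r_squared
  expect_equal(correlate_shift_function(3 * x - 5, y)$r_squared, r2)
  expect_equal(correlate_shift_function(x, -2 * y + 7)$r_squared, r2)
  expect_error(correlate_shift_function(rep(-84, 5), y), "zero variance")
  expect_error(correlate_shift_function(x[1:2], y[1:2]), "at least 3")
})

test_that("independent endpoints show no spurious correlation", {
  set.seed(99)
  x <- rnorm(17, -83.8, 0.3)
  r2s <- vapply(1:1000, function(i)
    correlate_shift_function(x, rnorm(17))$r_squared, numeric(1))
  expect_lt(median(r2s), 0.1)
})
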