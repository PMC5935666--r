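# Shared fixtures and small independent oracles.

# Trapezoid-rule integral on a (possibly decreasing) ppm grid, oriented so
# a positive-intensity spectrum has positive area.
trapz_area <- function(x, y) {
  abs(sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# Standard narrow test window: 1.4 ppm around -84, 1024 points.
test_axis <- function(n = 1024) frequency_axis(-83.3, -84.7, n)

# One-peak fixture at a stated signal-to-noise ratio (height / noise sd).
one_peak_spectrum <- function(snr, seed, center = -84, fwhm = 0.08,
                              area = 1, axis = test_axis()) {
  pk <- peak_set(center, fwhm, area)
  height <- 2 * area / (pi * fwhm)
  simulate_static_spectrum(pk, axis, noise_sd = height / snr, seed = seed)
}

# Duplicate-well dose-response fixture (the assay's plate design) carrying
# exactly one injected 10-sigma outlier.
with_outlier <- function(concs, seed, n_replicates = 2) {
  d <- simulate_dose_response(0.3, 0.9, 1e-6, 1, concs, noise_sd = 0.01,
                              n_replicates = n_replicates, seed = seed)
  set.seed(seed + 5000)
  i <- sample(nrow(d), 1)
  d$response[i] <- d$response[i] + 10 * 0.01
  d$outlier_truth[i] <- TRUE
  d
}

# Resolved two-peak fixture: separation 5x FWHM.
two_peak_spectrum <- function(snr, seed, sep = 0.4, fwhm = 0.08,
                              areas = c(0.55, 0.45), axis = test_axis()) {
  pk <- peak_set(c(-84 + sep / 2, -84 - sep / 2), c(fwhm, fwhm), areas)
  height <- 2 * max(areas) / (pi * fwhm)
  list(spectrum = simulate_static_spectrum(pk, axis,
                                           noise_sd = height / snr,
                                           seed = seed),
       truth = pk)
}
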