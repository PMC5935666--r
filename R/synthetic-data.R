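#' Simulate a static (exchange-free) spectrum from a peak table
#'
#' Forward model of the fitted lineshape: a sum of phased Lorentzians plus
#' iid Gaussian noise on the frequency-domain points.
#'
#' @param peaks an [peak_set()].
#' @param axis an [frequency_axis()].
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed; identical seeds give identical spectra.
#' @param baseline constant offset added to every point.
#' @param meta extra metadata stored on the spectrum.
#' @return an `fl_spectrum`.
#' @export
simulate_static_spectrum <- function(peaks, axis, noise_sd = 0, seed = NULL,
                                     baseline = 0, meta = list()) {
  stopifnot(inherits(axis, "fl_axis"), noise_sd >= 0)
  rng <- range(axis$ppm)
  if (nrow(peaks) > 0) {
    tol <- 1e-9 * max(1, abs(rng[1]))
    lo <- peaks$center_ppm - 5 * peaks$fwhm_ppm
    hi <- peaks$center_ppm + 5 * peaks$fwhm_ppm
    if (any(lo < rng[1] - tol) || any(hi > rng[2] + tol))
      stop("peak outside axis coverage (center +/- 5 FWHM must fit)")
  }
  y <- mixture_profile(axis$ppm, peaks, baseline)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  meta$noise_sd <- noise_sd
  new_spectrum(axis, y, meta)
}

#' Simulate an N-site chemical-exchange spectrum
#'
#' Frequency-domain lineshape from the exchange-coupled transverse
#' magnetization equations: per grid point
#' \deqn{S(\omega) \propto -\mathrm{Re}\,[\,\mathbf{1}^T
#'   (i\,\Delta\Omega(\omega) - R_2 + K)^{-1} \mathbf{p}\,]}
#' with offsets in rad/s obtained from ppm via the spectrometer frequency.
#' The noise-free profile integrates to 1 over the ppm axis regardless of
#' the exchange rates (conservation of magnetization).
#'
#' @param model an [exchange_model()].
#' @param axis an [frequency_axis()].
#' @param noise_sd,seed as in [simulate_static_spectrum()].
#' @param scale multiply the normalized profile by this total area.
#' @return an `fl_spectrum`.
#' @export
simulate_exchange_spectrum <- function(model, axis, noise_sd = 0,
                                       seed = NULL, scale = 1) {
  stopifnot(inherits(model, "fl_exchange_model"), inherits(axis, "fl_axis"),
            noise_sd >= 0)
  if (is.na(axis$spectrometer_freq))
    stop("axis lacks a spectrometer frequency; Hz conversion impossible")
  f <- axis$spectrometer_freq
  w_site <- 2 * pi * f * model$site_shifts
  w <- 2 * pi * f * axis$ppm
  n <- length(w_site)
  B <- diag(1i * w_site - model$site_r2, nrow = n) + model$rate_matrix
  p <- model$populations
  s <- tryCatch({
    # Eigen-decomposition of the omega-independent part turns the per-point
    # solve into a vectorized sum of simple poles.
    eg <- eigen(B)
    cj <- as.vector(matrix(1, 1, n) %*% eg$vectors) *
      as.vector(solve(eg$vectors, p))
    vapply(w, function(wk) sum(cj / (eg$values - 1i * wk)), complex(1))
  }, error = function(e) {
    vapply(w, function(wk) {
      A <- B - diag(1i * wk, nrow = n)
      out <- tryCatch(sum(solve(A, p)), error = function(e2)
        stop("singular exchange matrix at some frequency; ",
             "non-physical parameters", call. = FALSE))
      out
    }, complex(1))
  })
  y <- -Re(s) / pi * (2 * pi * f) * scale
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  new_spectrum(axis, y, list(noise_sd = noise_sd, r1 = model$r1))
}

#' Simulate a saturation-transfer time series
#'
#' Two-site saturation transfer with complete, instantaneous saturation of
#' the partner resonance: the observed intensity decays as
#' \deqn{I(t) = I_0\left[\frac{R_1}{R_1+k} +
#'   \frac{k}{R_1+k} e^{-(R_1+k)t}\right].}
#' An off-resonance control channel (constant at `i0` plus noise) is
#' generated alongside, mirroring the paired on/off acquisition scheme.
#'
#' @param r1 longitudinal relaxation rate (1/s), > 0.
#' @param k exchange rate toward the saturated site (1/s), >= 0.
#' @param i0 initial (unsaturated) intensity.
#' @param times saturation durations in seconds, >= 0.
#' @param noise_sd,seed noise model as elsewhere.
#' @return object of class `fl_saturation_series` with fields `times`,
#'   `on_intensity`, `off_intensity`, `r1`, `i0`.
#' @export
simulate_saturation_series <- function(r1, k, i0 = 1,
                                       times = seq(0, 1.6, length.out = 12),
                                       noise_sd = 0, seed = NULL) {
  stopifnot(r1 > 0, k >= 0, all(times >= 0), i0 > 0, noise_sd >= 0)
  on <- i0 * forsen_hoffman_intensity(times, r1, k)
  off <- rep(i0, length(times))
  if (noise_sd > 0) {
    eps <- with_seed(seed, stats::rnorm(2 * length(times), 0, noise_sd))
    on <- on + eps[seq_along(times)]
    off <- off + eps[length(times) + seq_along(times)]
  }
  structure(list(times = times, on_intensity = on, off_intensity = off,
                 r1 = r1, i0 = i0, true_k = k),
            class = "fl_saturation_series")
}

#' Simulate a relaxation time series
#'
#' @param kind `"inversion_recovery"` (T1) or `"cpmg"` (T2).
#' @param rate relaxation rate (1/s), > 0.
#' @param i0 equilibrium intensity.
#' @param times delays in seconds.
#' @param imperfection inversion efficiency in \[0, 1\]; 1 means perfect
#'   inversion, so I(0) = -i0.
#' @param noise_sd,seed noise model.
#' @return object of class `fl_relaxation_series`.
#' @export
simulate_relaxation_series <- function(kind = c("inversion_recovery", "cpmg"),
                                       rate, i0 = 1,
                                       times = seq(0, 2, length.out = 12),
                                       imperfection = 1,
                                       noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate > 0, i0 > 0, all(times >= 0),
            imperfection >= 0, imperfection <= 1, noise_sd >= 0)
  y <- switch(kind,
    inversion_recovery = i0 * (1 - (1 + imperfection) * exp(-rate * times)),
    cpmg = i0 * exp(-rate * times))
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  structure(list(times = times, intensity = y, kind = kind,
                 true_rate = rate, i0 = i0),
            class = "fl_relaxation_series")
}

#' Simulate a four-parameter logistic dose-response table
#'
#' @param bottom,top,ec50,hill 4PL truth; `ec50` in molar.
#' @param concentrations tested concentrations (M), > 0.
#' @param noise_sd response noise.
#' @param n_outliers number of points displaced by 12 x `noise_sd`
#'   (or 20% of the dynamic range when noise is zero); displaced indices
#'   are recorded in the `outlier_truth` column, never hidden.
#' @param n_replicates technical replicates per concentration.
#' @param seed integer seed.
#' @return data.frame of class `fl_dose_response` with columns `conc_M`,
#'   `response`, `replicate`, `outlier_truth`.
#' @export
simulate_dose_response <- function(bottom, top, ec50, hill,
                                   concentrations, noise_sd = 0,
                                   n_outliers = 0, n_replicates = 1,
                                   seed = NULL) {
  stopifnot(all(concentrations > 0), ec50 > 0, noise_sd >= 0,
            n_outliers >= 0, n_replicates >= 1)
  conc <- rep(concentrations, each = n_replicates)
  repl <- rep(seq_len(n_replicates), times = length(concentrations))
  y <- fourpl(conc, bottom, top, log10(ec50), hill)
  out <- with_seed(seed, {
    yy <- y
    if (noise_sd > 0) yy <- yy + stats::rnorm(length(yy), 0, noise_sd)
    flag <- rep(FALSE, length(yy))
    if (n_outliers > 0) {
      idx <- sample(length(yy), n_outliers)
      bump <- if (noise_sd > 0) 12 * noise_sd else 0.2 * abs(top - bottom)
      yy[idx] <- yy[idx] + sample(c(-1, 1), n_outliers, replace = TRUE) * bump
      flag[idx] <- TRUE
    }
    list(y = yy, flag = flag)
  })
  df <- data.frame(conc_M = conc, response = out$y, replicate = repl,
                   outlier_truth = out$flag)
  class(df) <- c("fl_dose_response", "data.frame")
  df
}

# Exact three-species competitive equilibrium: receptor R binds tracer L
# (Kd) and competitor I (Ki). Returns bound tracer [RL] at total
# concentrations ro, lo, io. Monotone root in free receptor.
competitive_bound <- function(lo, ro, kd, ki, io, rel_tol = 1e-12) {
  stopifnot(lo >= 0, ro > 0, kd > 0, ki > 0, io >= 0)
  if (lo == 0) return(0)
  f <- function(r) r * (1 + lo / (kd + r) + io / (ki + r)) - ro
  fit <- tryCatch(
    stats::uniroot(f, lower = 0, upper = ro, tol = ro * rel_tol),
    error = function(e) stop("competitive equilibrium failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  r <- fit$root
  free_l <- lo / (1 + r / kd)
  r * free_l / kd
}

#' Simulate a competitive tracer-displacement curve
#'
#' Bound-tracer signal versus competitor concentration from the exact
#' three-species mass-action equilibrium (no logistic approximation), so
#' that a Cheng-Prusoff round trip tests the equation rather than the
#' simulator.
#'
#' @param ki competitor inhibition constant (M).
#' @param kd tracer dissociation constant (M).
#' @param lo,ro total tracer and receptor concentrations (M).
#' @param competitor_concs competitor concentrations (M, >= 0 allowed for
#'   the no-competitor control).
#' @param noise_sd,seed noise on the bound-tracer readout.
#' @return data.frame of class `fl_competition_curve` with columns
#'   `conc_M`, `response`; attribute `lb` holds the no-competitor bound
#'   tracer from the two-species quadratic.
#' @export
simulate_competition_assay <- function(ki, kd, lo, ro, competitor_concs,
                                       noise_sd = 0, seed = NULL) {
  stopifnot(ki > 0, kd > 0, lo > 0, ro > 0, all(competitor_concs >= 0),
            noise_sd >= 0)
  b <- vapply(competitor_concs, function(io)
    competitive_bound(lo, ro, kd, ki, io), numeric(1))
  if (noise_sd > 0)
    b <- b + with_seed(seed, stats::rnorm(length(b), 0, noise_sd))
  df <- data.frame(conc_M = competitor_concs, response = b)
  class(df) <- c("fl_competition_curve", "data.frame")
  attr(df, "lb") <- bound_tracer(lo, ro, kd)
  attr(df, "constants") <- list(ki = ki, kd = kd, lo = lo, ro = ro)
  df
}

# Ligand-class peak templates: centers/widths chosen to emulate the
# observed ensemble map. Full agonists: one narrow upfield peak. Inverse
# agonists: a narrow downfield peak plus a broad minor one. Apo, partial
# agonists and antagonists: two broad peaks at intermediate shifts.
scenario_templates <- function() {
  list(
    full_agonist = function() {
      peak_set(center_ppm = stats::runif(1, -84.30, -84.05),
               fwhm_ppm = stats::runif(1, 0.035, 0.060),
               area = 1)
    },
    partial_agonist = function() {
      a <- stats::runif(1, 0.35, 0.65)
      peak_set(center_ppm = c(stats::runif(1, -83.70, -83.55),
                              stats::runif(1, -84.05, -83.90)),
               fwhm_ppm = stats::runif(2, 0.12, 0.22),
               area = c(a, 1 - a))
    },
    antagonist = function() {
      a <- stats::runif(1, 0.40, 0.70)
      peak_set(center_ppm = c(stats::runif(1, -83.60, -83.45),
                              stats::runif(1, -83.95, -83.80)),
               fwhm_ppm = stats::runif(2, 0.13, 0.24),
               area = c(a, 1 - a))
    },
    inverse_agonist = function() {
      a <- stats::runif(1, 0.55, 0.75)
      peak_set(center_ppm = c(stats::runif(1, -83.25, -83.05),
                              stats::runif(1, -83.80, -83.60)),
               fwhm_ppm = c(stats::runif(1, 0.045, 0.085),
                            stats::runif(1, 0.15, 0.25)),
               area = c(a, 1 - a))
    },
    apo = function() {
      a <- stats::runif(1, 0.40, 0.60)
      peak_set(center_ppm = c(stats::runif(1, -83.62, -83.50),
                              stats::runif(1, -84.02, -83.88)),
               fwhm_ppm = stats::runif(2, 0.15, 0.25),
               area = c(a, 1 - a))
    }
  )
}

#' Generate a ligand-class scenario: spectrum plus ground truth
#'
#' Draws a peak ensemble from the class template, optionally adds the
#' sharp free-label contaminant peak near -83.3 ppm, simulates the main
#' spectrum at an arbitrary (uncalibrated) axis offset, and simulates the
#' coaxial KF reference channel whose single peak sits at the same raw
#' offset from the defined reference shift.
#'
#' @param ligand_class one of `"full_agonist"`, `"partial_agonist"`,
#'   `"antagonist"`, `"inverse_agonist"`, `"apo"`.
#' @param seed integer seed (required: scenarios are reproducible draws).
#' @param axis main-channel axis; default covers -80 to -88 ppm.
#' @param noise_sd frequency-domain noise (main channel); the reference
#'   channel uses the same value.
#' @param include_btfa add the free-BTFA contaminant peak at -83.3 ppm.
#' @param raw_offset calibration error in ppm applied to both channels
#'   (drawn uniformly in +/- 0.15 ppm when `NULL`).
#' @param label sample label stored in metadata.
#' @return list with `spectrum`, `reference` (KF channel `fl_spectrum`),
#'   `truth` (the generating `fl_peaks`, positions on the calibrated
#'   scale), `raw_offset`, `ligand_class`, `label`.
#' @export
generate_ensemble_scenario <- function(ligand_class, seed,
                                       axis = frequency_axis(),
                                       noise_sd = 0.03,
                                       include_btfa = TRUE,
                                       raw_offset = NULL,
                                       label = ligand_class) {
  templates <- scenario_templates()
  if (!ligand_class %in% names(templates))
    stop("unknown ligand class: ", ligand_class)
  with_seed(seed, {
    truth <- templates[[ligand_class]]()
    if (include_btfa) {
      btfa <- peak_set(center_ppm = -83.3, fwhm_ppm = 0.012,
                       area = 0.03, is_contaminant = TRUE)
      truth <- rbind(truth, btfa)
      class(truth) <- c("fl_peaks", "data.frame")
    }
    if (is.null(raw_offset)) raw_offset <- stats::runif(1, -0.15, 0.15)
    raw <- truth
    raw$center_ppm <- raw$center_ppm + raw_offset
    spec <- simulate_static_spectrum(
      raw, axis, noise_sd = noise_sd, seed = NULL,
      meta = list(label = label, ligand_class = ligand_class,
                  temperature_K = 298.2, d2o_fraction = 0.1))
    kf_defined <- -119.522
    kf_axis <- frequency_axis(kf_defined + 1.5, kf_defined - 1.5, n = 4096,
                              spectrometer_freq = axis$spectrometer_freq)
    kf_peak <- peak_set(center_ppm = kf_defined + raw_offset,
                        fwhm_ppm = 0.02, area = 1)
    ref <- simulate_static_spectrum(
      kf_peak, kf_axis, noise_sd = noise_sd, seed = NULL,
      meta = list(label = paste0(label, "_KF"), channel = "reference"))
    spec$meta$reference_raw_position <- kf_defined + raw_offset
    list(spectrum = spec, reference = ref, truth = truth,
         raw_offset = raw_offset, ligand_class = ligand_class,
         label = label)
  })
}
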