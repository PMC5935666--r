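#' Two-site saturation-transfer decay
#'
#' Relative intensity of the observed resonance while its exchange partner
#' is held saturated, with the longitudinal rate fixed:
#' \deqn{I(t)/I_0 = \frac{R_1}{R_1+k} + \frac{k}{R_1+k}e^{-(R_1+k)t}.}
#'
#' @param t saturation durations (s), >= 0.
#' @param r1 longitudinal relaxation rate (1/s), > 0.
#' @param k exchange rate toward the saturated site (1/s), >= 0.
#' @return relative intensity in (0, 1].
#' @export
forsen_hoffman_intensity <- function(t, r1, k) {
  stopifnot(r1 > 0, k >= 0, all(t >= 0))
  s <- r1 + k
  r1 / s + (k / s) * exp(-s * t)
}

#' Fit the exchange rate from a saturation-transfer series
#'
#' Single-free-parameter least squares: `i0` and `r1` are fixed from the
#' series (the off-resonance control defines `i0` when present), and only
#' the exchange rate k is estimated. The 95% confidence interval comes
#' from the F-statistic profile of the residual sum of squares,
#' \eqn{SSR(k) \le SSR_{min}\,(1 + F_{0.95}(1, n-1)/(n-1))}. A series
#' whose profile at k = 0 already falls inside the threshold is flagged
#' below the detectability limit.
#'
#' @param series an `fl_saturation_series`, >= 4 time points.
#' @param k_max search upper bound (1/s).
#' @return object of class `fl_exchange_fit`: `k`, `ci95`, `converged`,
#'   `below_detectability`, `ssr`.
#' @export
fit_saturation_transfer <- function(series, k_max = 100) {
  stopifnot(inherits(series, "fl_saturation_series"))
  t <- series$times
  if (length(t) < 4) stop("need at least 4 time points")
  if (max(t) < 1 / series$r1)
    stop("durations must span at least 1/R1 seconds")
  i0 <- if (!is.null(series$off_intensity) &&
            length(series$off_intensity) > 0)
    mean(series$off_intensity) else series$i0
  r1 <- series$r1
  y <- series$on_intensity
  ssr <- function(k) sum((y - i0 * forsen_hoffman_intensity(t, r1, k))^2)
  opt <- stats::optimize(ssr, c(0, k_max), tol = 1e-10)
  khat <- opt$minimum
  smin <- opt$objective
  if (ssr(0) <= smin + 1e-12 * max(smin, 1)) { khat <- 0; smin <- ssr(0) }
  n <- length(t)
  thresh <- smin * (1 + stats::qf(0.95, 1, n - 1) / (n - 1)) +
    1e-14 * sum(y^2)  # guards the noise-free SSR ~ 0 case
  g <- function(k) ssr(k) - thresh
  lo <- 0
  below <- g(0) <= 0
  if (!below)
    lo <- stats::uniroot(g, c(0, khat), tol = 1e-10)$root
  hi <- khat
  if (g(k_max) > 0) {
    upper_bracket <- if (khat < k_max) c(max(khat, 1e-12), k_max) else
      c(k_max * 0.99, k_max)
    hi <- stats::uniroot(g, upper_bracket, tol = 1e-10)$root
  } else hi <- k_max
  structure(list(k = khat, ci95 = c(lo, hi), converged = TRUE,
                 below_detectability = below, ssr = smin,
                 r1 = r1, i0 = i0, n = n),
            class = "fl_exchange_fit")
}

#' @export
print.fl_exchange_fit <- function(x, ...) {
  cat(sprintf("<fl_exchange_fit> k = %.4g 1/s (95%% CI %.4g-%.4g)%s\n",
              x$k, x$ci95[1], x$ci95[2],
              if (x$below_detectability) " [below detectability]" else ""))
  invisible(x)
}

#' Minimal detectable exchange rate of the saturation-transfer design
#'
#' The steady-state depletion of the observed peak is k/(R1+k); exchange
#' is taken as detectable when that depletion exceeds `z` times the
#' fractional noise. Inverting gives the smallest detectable rate
#' \eqn{k = s R_1 / (1 - s)} with \eqn{s = z \cdot noise}. `max_time` is
#' checked so the design actually reaches steady state.
#'
#' @param r1 longitudinal rate (1/s).
#' @param noise_fraction rms noise as a fraction of the initial intensity.
#' @param z detection multiple (default 3).
#' @param max_time longest saturation duration (s); optional design check.
#' @return minimal detectable k (1/s); `Inf` when `z * noise_fraction >= 1`.
#' @export
detectability_limit <- function(r1, noise_fraction, z = 3,
                                max_time = NULL) {
  stopifnot(r1 > 0, noise_fraction >= 0, z > 0)
  s <- z * noise_fraction
  if (s >= 1) return(Inf)
  k <- s * r1 / (1 - s)
  if (!is.null(max_time) && (r1 + k) * max_time < 3)
    warning("longest duration does not reach steady state; ",
            "the limit is optimistic")
  k
}

#' Steady-state CEST profile of a two-site exchange model
#'
#' For each saturation offset, the partner site is saturated with
#' efficiency equal to its normalized Lorentzian lineshape at the offset,
#' and the observed site settles to
#' \eqn{1 - \mathrm{eff} \cdot k/(R_1+k)}. With exchange present the
#' profile mirrors the partner lineshape (minimum at the partner center).
#'
#' @param model a two-site [exchange_model()].
#' @param observed_site index (1 or 2) of the monitored resonance.
#' @param saturation_offsets offsets in ppm.
#' @param spectrometer_freq MHz, for the rad/s linewidth conversion.
#' @return data.frame with `offset_ppm` and relative `intensity`.
#' @export
cest_profile <- function(model, observed_site, saturation_offsets,
                         spectrometer_freq = 658.8462650) {
  stopifnot(inherits(model, "fl_exchange_model"),
            length(model$site_shifts) == 2, observed_site %in% 1:2)
  partner <- 3 - observed_site
  k <- model$rate_matrix[partner, observed_site]  # observed -> partner
  hw_ppm <- model$site_r2[partner] / (2 * pi * spectrometer_freq)  # HWHM
  d <- saturation_offsets - model$site_shifts[partner]
  eff <- hw_ppm^2 / (d^2 + hw_ppm^2)
  data.frame(offset_ppm = saturation_offsets,
             intensity = 1 - eff * k / (model$r1 + k))
}

#' Fit a relaxation rate from a recovery or decay series
#'
#' Nonlinear least squares of the matching closed form (see
#' [simulate_relaxation_series()]); for inversion recovery the amplitude
#' and inversion efficiency are co-estimated, for CPMG the amplitude.
#' Asymptotic 95% confidence interval on the rate.
#'
#' @param series an `fl_relaxation_series` (or a list with `times`,
#'   `intensity`), >= 4 points.
#' @param kind defaults to the series' own kind.
#' @return list: `rate` (1/s), `ci95`, `T` (= 1/rate, s), `fit`.
#' @export
fit_relaxation <- function(series, kind = NULL) {
  kind <- kind %||% series$kind
  kind <- match.arg(kind, c("inversion_recovery", "cpmg"))
  t <- series$times
  y <- series$intensity
  stopifnot(length(t) == length(y), all(is.finite(y)))
  if (length(t) < 4) stop("need at least 4 points")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop("constant series carries no decay information")
  df <- data.frame(t = t, y = y)
  fit <- if (kind == "inversion_recovery") {
    i0_0 <- max(abs(y))
    minpack.lm::nlsLM(y ~ i0 * (1 - (1 + eff) * exp(-rate * t)), data = df,
                      start = list(i0 = i0_0, eff = 1,
                                   rate = 1 / max(stats::median(t), 1e-6)),
                      lower = c(1e-12, 0, 1e-9), upper = c(Inf, 1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ i0 * exp(-rate * t), data = df,
                      start = list(i0 = max(y),
                                   rate = 1 / max(stats::median(t), 1e-6)),
                      lower = c(1e-12, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- stats::coef(fit)[["rate"]]
  se <- tryCatch(summary(fit)$coefficients["rate", "Std. Error"],
                 error = function(e) NA_real_)
  ci <- est + c(-1, 1) * stats::qt(0.975, length(t) -
                                     length(stats::coef(fit))) *
    (if (is.finite(se)) se else 0)
  list(rate = est, ci95 = ci, T = 1 / est, kind = kind, fit = fit)
}

#' Linewidth versus T2 consistency check
#'
#' A pure Lorentzian of transverse lifetime T2 has FWHM = 1/(pi T2) Hz;
#' this converts a fitted ppm linewidth to Hz and reports the ratio to the
#' T2 prediction.
#'
#' @param fwhm_ppm fitted linewidth (ppm).
#' @param spectrometer_freq MHz (Hz per ppm).
#' @param t2 transverse lifetime (s).
#' @return list: `fwhm_hz`, `predicted_fwhm_hz`, `ratio`.
#' @export
linewidth_consistency <- function(fwhm_ppm, spectrometer_freq, t2) {
  stopifnot(fwhm_ppm > 0, spectrometer_freq > 0, t2 > 0)
  fwhm_hz <- fwhm_ppm * spectrometer_freq
  predicted <- 1 / (pi * t2)
  list(fwhm_hz = fwhm_hz, predicted_fwhm_hz = predicted,
       ratio = fwhm_hz / predicted)
}
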