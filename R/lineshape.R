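#' Phased Lorentzian profile
#'
#' Absorptive/dispersive mixture of a single resonance:
#' \deqn{I(\delta) = \cos\phi \, \frac{A}{\pi}\frac{w/2}{(\delta-\delta_0)^2
#'   + (w/2)^2} + \sin\phi \, \frac{A}{\pi}\frac{\delta-\delta_0}
#'   {(\delta-\delta_0)^2 + (w/2)^2}}
#' so that at \eqn{\phi = 0} the integral over an infinite axis equals the
#' area \eqn{A} and the height at the center is \eqn{2A/(\pi w)}.
#'
#' @param ppm evaluation points (ppm).
#' @param center,fwhm,area,phase Lorentzian parameters; `fwhm` in ppm > 0.
#' @return numeric vector of intensities.
#' @export
lorentzian <- function(ppm, center, fwhm, area, phase = 0) {
  hw <- fwhm / 2
  d <- ppm - center
  den <- d^2 + hw^2
  (area / pi) * (cos(phase) * hw + sin(phase) * d) / den
}

# Sum of phased Lorentzians plus a constant baseline.
mixture_profile <- function(ppm, peaks, baseline = 0) {
  y <- rep(baseline, length(ppm))
  if (nrow(peaks) == 0) return(y)
  for (i in seq_len(nrow(peaks))) {
    y <- y + lorentzian(ppm, peaks$center_ppm[i], peaks$fwhm_ppm[i],
                        peaks$area[i], peaks$phase_rad[i])
  }
  y
}

#' Closed-form two-site exchange lineshape
#'
#' Analytic solution of the coupled two-site transverse-magnetization
#' equations (explicit 2x2 determinant inverse), kept as an independent
#' cross-check of the general matrix lineshape in
#' [simulate_exchange_spectrum()]. The returned profile is normalized so
#' that its integral over the ppm axis equals 1 (total magnetization).
#'
#' @param ppm evaluation grid (ppm).
#' @param shifts length-2 site shifts (ppm).
#' @param r2 length-2 transverse rates (1/s).
#' @param populations length-2 fractions summing to 1.
#' @param k_ex overall exchange rate `k_AB + k_BA` (1/s).
#' @param spectrometer_freq 19F frequency (MHz), i.e. Hz per ppm.
#' @return numeric intensity per grid point (intensity per ppm).
#' @export
two_site_lineshape <- function(ppm, shifts, r2, populations, k_ex,
                               spectrometer_freq = 658.8462650) {
  stopifnot(length(shifts) == 2, length(r2) == 2, length(populations) == 2,
            k_ex >= 0, abs(sum(populations) - 1) < 1e-8)
  pA <- populations[1]; pB <- populations[2]
  kAB <- k_ex * pB
  kBA <- k_ex * pA
  wA <- 2 * pi * spectrometer_freq * shifts[1]
  wB <- 2 * pi * spectrometer_freq * shifts[2]
  w  <- 2 * pi * spectrometer_freq * ppm
  # M v = p with M = [[i(wA-w) - r2A - kAB, kBA], [kAB, i(wB-w) - r2B - kBA]]
  m11 <- 1i * (wA - w) - r2[1] - kAB
  m22 <- 1i * (wB - w) - r2[2] - kBA
  det <- m11 * m22 - kAB * kBA
  # 1' M^{-1} p expanded by cofactors
  s <- ((m22 - kAB) * pA + (m11 - kBA) * pB) / det
  -Re(s) / pi * (2 * pi * spectrometer_freq)
}
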