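#' Frequency axis for a 1D 19F spectrum
#'
#' A chemical-shift grid together with the spectrometer's 19F basic
#' transmitter frequency. The grid is stored monotone decreasing (downfield
#' to upfield, the conventional plotting order); the MHz value doubles as
#' the Hz-per-ppm conversion factor.
#'
#' @param from,to window limits in ppm (any order; stored decreasing).
#' @param n number of grid points.
#' @param spectrometer_freq 19F basic transmitter frequency in MHz.
#'   Default is a 16.4 T instrument's 19F frequency.
#' @return object of class `fl_axis` with fields `ppm` and
#'   `spectrometer_freq`.
#' @export
frequency_axis <- function(from = -80, to = -88, n = 16384,
                           spectrometer_freq = 658.8462650) {
  stopifnot(is.numeric(from), is.numeric(to), from != to,
            n >= 2, spectrometer_freq > 0)
  ppm <- seq(max(from, to), min(from, to), length.out = n)
  structure(list(ppm = ppm, spectrometer_freq = spectrometer_freq),
            class = "fl_axis")
}

#' @export
print.fl_axis <- function(x, ...) {
  cat(sprintf("<fl_axis> %d points, %.4f to %.4f ppm @ %.7f MHz\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              x$spectrometer_freq))
  invisible(x)
}

axis_step <- function(axis) abs(axis$ppm[1] - axis$ppm[2])

#' Assemble a spectrum object
#'
#' @param axis an [frequency_axis()].
#' @param intensity numeric vector, one value per grid point.
#' @param meta named list of acquisition metadata (temperature_K,
#'   d2o_fraction, label, reference_raw_position, ...).
#' @return object of class `fl_spectrum`.
#' @export
new_spectrum <- function(axis, intensity, meta = list()) {
  stopifnot(inherits(axis, "fl_axis"),
            length(intensity) == length(axis$ppm),
            all(is.finite(intensity)))
  structure(list(axis = axis, intensity = as.numeric(intensity),
                 meta = meta),
            class = "fl_spectrum")
}

#' @export
print.fl_spectrum <- function(x, ...) {
  lab <- if (!is.null(x$meta$label)) paste0(" [", x$meta$label, "]") else ""
  cat(sprintf("<fl_spectrum>%s %d points, %.4f to %.4f ppm\n", lab,
              length(x$intensity), x$axis$ppm[1],
              x$axis$ppm[length(x$axis$ppm)]))
  invisible(x)
}

#' Construct a peak table
#'
#' The parametric summary every downstream stage consumes: one row per
#' Lorentzian component.
#'
#' @param center_ppm peak centers (ppm).
#' @param fwhm_ppm full widths at half maximum (ppm, > 0).
#' @param area integrated areas (intensity x ppm, >= 0).
#' @param phase_rad per-peak phase (radians).
#' @param is_contaminant logical flag marking peaks (e.g. free label) to be
#'   excluded from ensemble metrics.
#' @return data.frame of class `fl_peaks`.
#' @export
peak_set <- function(center_ppm, fwhm_ppm, area,
                     phase_rad = 0, is_contaminant = FALSE) {
  n <- length(center_ppm)
  stopifnot(length(fwhm_ppm) == n, length(area) == n,
            all(fwhm_ppm > 0), all(area >= 0))
  df <- data.frame(center_ppm = as.numeric(center_ppm),
                   fwhm_ppm   = as.numeric(fwhm_ppm),
                   area       = as.numeric(area),
                   phase_rad  = rep_len(as.numeric(phase_rad), n),
                   is_contaminant = rep_len(as.logical(is_contaminant), n))
  class(df) <- c("fl_peaks", "data.frame")
  df
}

empty_peak_set <- function() {
  df <- data.frame(center_ppm = numeric(0), fwhm_ppm = numeric(0),
                   area = numeric(0), phase_rad = numeric(0),
                   is_contaminant = logical(0))
  class(df) <- c("fl_peaks", "data.frame")
  df
}

#' N-site chemical exchange model
#'
#' Site chemical shifts, transverse relaxation rates, stationary
#' populations and a first-order exchange-rate matrix. The rate matrix `K`
#' follows the kinetic convention: `K[i, j]` (i != j) is the rate constant
#' for site j -> site i in 1/s, diagonal entries make each column sum to
#' zero, and stationarity requires `K %*% populations == 0`.
#'
#' @param site_shifts chemical shifts per site (ppm).
#' @param site_r2 transverse relaxation rates per site (1/s).
#' @param populations stationary fractions, summing to 1.
#' @param rate_matrix exchange-rate matrix (1/s), see Details.
#' @param r1 longitudinal relaxation rate (1/s).
#' @return object of class `fl_exchange_model`.
#' @export
exchange_model <- function(site_shifts, site_r2, populations, rate_matrix,
                           r1 = 2.7) {
  n <- length(site_shifts)
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(length(site_r2) == n, length(populations) == n,
            all(dim(rate_matrix) == c(n, n)),
            all(site_r2 > 0), all(populations >= 0), r1 > 0)
  if (abs(sum(populations) - 1) > 1e-8)
    stop("populations must sum to 1")
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal exchange rates must be >= 0")
  if (any(abs(colSums(rate_matrix)) > 1e-8 * max(1, max(abs(rate_matrix)))))
    stop("rate_matrix columns must sum to zero")
  flux <- rate_matrix %*% populations
  if (any(abs(flux) > 1e-6 * max(1, max(abs(rate_matrix)))))
    stop("rate_matrix is not stationary for the given populations")
  structure(list(site_shifts = as.numeric(site_shifts),
                 site_r2 = as.numeric(site_r2),
                 populations = as.numeric(populations),
                 rate_matrix = rate_matrix, r1 = r1),
            class = "fl_exchange_model")
}

#' Two-site exchange model from an overall exchange rate
#'
#' Convenience constructor: `k_ex` is the sum of the forward and backward
#' rate constants; detailed balance splits it as `k_AB = p_B * k_ex`,
#' `k_BA = p_A * k_ex`.
#'
#' @param shifts length-2 chemical shifts (ppm).
#' @param r2 length-2 transverse rates (1/s).
#' @param populations length-2 fractions summing to 1.
#' @param k_ex overall exchange rate (1/s), >= 0.
#' @param r1 longitudinal rate (1/s).
#' @export
two_site_model <- function(shifts, r2, populations, k_ex, r1 = 2.7) {
  stopifnot(length(shifts) == 2, k_ex >= 0)
  pA <- populations[1]; pB <- populations[2]
  kAB <- k_ex * pB   # A -> B
  kBA <- k_ex * pA   # B -> A
  K <- matrix(c(-kAB, kAB, kBA, -kBA), nrow = 2)
  exchange_model(shifts, r2, populations, K, r1 = r1)
}
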