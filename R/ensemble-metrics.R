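#' Mean-weighted chemical shift of a peak ensemble
#'
#' Area-weighted average of the fitted peak centers, the single-number
#' summary used to order and correlate whole spectra.
#'
#' @param peaks an `fl_peaks` table.
#' @param exclude_contaminant drop peaks flagged `is_contaminant`.
#' @return shift in ppm.
#' @export
mean_weighted_shift <- function(peaks, exclude_contaminant = TRUE) {
  if (nrow(peaks) == 0) stop("empty peak set")
  if (exclude_contaminant) peaks <- peaks[!peaks$is_contaminant, ,
                                          drop = FALSE]
  tot <- sum(peaks$area)
  if (!(tot > 0)) stop("total included peak area must be positive")
  sum(peaks$area * peaks$center_ppm) / tot
}

#' Major peaks by area fraction
#'
#' Retains peaks whose share of the total non-contaminant area strictly
#' exceeds `min_fraction` (default 5%, the inclusion rule for the
#' shift-vs-linewidth ensemble map).
#'
#' @param peaks an `fl_peaks` table.
#' @param min_fraction strict lower bound on the area fraction.
#' @return the retained `fl_peaks` rows (possibly none), with an
#'   `area_fraction` column over non-contaminant peaks.
#' @export
major_peaks <- function(peaks, min_fraction = 0.05) {
  keep <- !peaks$is_contaminant
  pk <- peaks[keep, , drop = FALSE]
  tot <- sum(pk$area)
  pk$area_fraction <- if (tot > 0) pk$area / tot else rep(0, nrow(pk))
  out <- pk[pk$area_fraction > min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster the shift-linewidth peak map by bivariate kernel density
#'
#' Gaussian-kernel density on a grid over the (chemical shift, FWHM)
#' plane; clusters are the basins of attraction of density modes above a
#' floor (a fraction of the global maximum), and each point is labeled by
#' hill-climbing on the grid to its mode. Points whose climb ends below
#' the floor are merged into the nearest retained mode.
#'
#' @param shift,fwhm coordinates of the peak map (ppm), >= 2 points.
#' @param bandwidth length-2 per-dimension Gaussian bandwidths; normal
#'   reference rule when `NULL`.
#' @param grid_n grid points per dimension.
#' @param floor_fraction mode floor as a fraction of the density maximum.
#' @param labels optional point labels carried through.
#' @return object of class `fl_cluster_map`: `points` (shift, fwhm, label,
#'   cluster), `density` (list x, y, z), `modes` (grid coordinates),
#'   `n_clusters`, `bandwidth`.
#' @export
cluster_peak_map <- function(shift, fwhm, bandwidth = NULL, grid_n = 80,
                             floor_fraction = 0.05, labels = NULL) {
  n <- length(shift)
  stopifnot(length(fwhm) == n)
  if (n < 2) stop("need at least 2 points to cluster")
  bw_rule <- function(v) {
    h <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
    if (!is.finite(h) || h <= 0)
      h <- 1.06 * stats::sd(v) * n^(-1 / 5) * 4  # nrd-scale fallback
    if (!is.finite(h) || h <= 0) h <- 1e-3 * max(abs(v), 1)
    h
  }
  if (is.null(bandwidth)) bandwidth <- c(bw_rule(shift), bw_rule(fwhm))
  stopifnot(length(bandwidth) == 2, all(bandwidth > 0))
  lims <- c(range(shift) + c(-1.5, 1.5) * bandwidth[1],
            range(fwhm) + c(-1.5, 1.5) * bandwidth[2])
  dens <- MASS::kde2d(shift, fwhm, h = bandwidth, n = grid_n, lims = lims)
  z <- dens$z
  floor_z <- floor_fraction * max(z)

  nx <- nrow(z); ny <- ncol(z)
  neighbor_best <- function(i, j) {
    best <- c(i, j); bz <- z[i, j]
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny && z[ii, jj] > bz) {
        bz <- z[ii, jj]; best <- c(ii, jj)
      }
    }
    best
  }
  climb <- function(i, j) {
    repeat {
      nb <- neighbor_best(i, j)
      if (nb[1] == i && nb[2] == j) return(c(i, j))
      i <- nb[1]; j <- nb[2]
    }
  }
  # modes: grid local maxima above the floor
  mode_cells <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    nb <- neighbor_best(i, j)
    if (nb[1] == i && nb[2] == j && z[i, j] >= floor_z)
      mode_cells[[length(mode_cells) + 1]] <- c(i, j)
  }
  if (length(mode_cells) == 0) mode_cells <- list(which(z == max(z),
                                                        arr.ind = TRUE)[1, ])
  modes <- do.call(rbind, mode_cells)
  mode_xy <- cbind(dens$x[modes[, 1]], dens$y[modes[, 2]])
  # persistence merge: two modes are the same cluster when the density
  # along the straight line between them never dips below `merge_ratio`
  # of the lower mode (shallow saddles are sampling artifacts)
  merge_ratio <- 0.5
  nm <- nrow(mode_xy)
  saddle_min <- function(a, b) {
    s <- seq(0, 1, length.out = 50)
    xs <- mode_xy[a, 1] + s * (mode_xy[b, 1] - mode_xy[a, 1])
    ys <- mode_xy[a, 2] + s * (mode_xy[b, 2] - mode_xy[a, 2])
    min(vapply(seq_along(s), function(k)
      z[which.min(abs(dens$x - xs[k])), which.min(abs(dens$y - ys[k]))],
      numeric(1)))
  }
  group <- seq_len(nm)
  if (nm > 1) {
    heights <- z[modes]
    for (a in seq_len(nm - 1)) for (b in (a + 1):nm) {
      if (saddle_min(a, b) > merge_ratio * min(heights[a], heights[b]))
        group[group == group[b]] <- group[a]
    }
  }

  assign_point <- function(px, py) {
    i <- which.min(abs(dens$x - px)); j <- which.min(abs(dens$y - py))
    top <- climb(i, j)
    hit <- which(modes[, 1] == top[1] & modes[, 2] == top[2])
    if (length(hit) == 1) return(group[hit])
    # climbed to a sub-floor mode: merge to nearest retained mode
    d <- (mode_xy[, 1] - dens$x[top[1]])^2 / bandwidth[1]^2 +
      (mode_xy[, 2] - dens$y[top[2]])^2 / bandwidth[2]^2
    group[which.min(d)]
  }
  cl <- vapply(seq_len(n), function(k) assign_point(shift[k], fwhm[k]),
               integer(1))
  used <- sort(unique(cl))
  relabel <- match(cl, used)
  pts <- data.frame(shift = shift, fwhm = fwhm,
                    label = labels %||% as.character(seq_len(n)),
                    cluster = relabel)
  structure(list(points = pts,
                 density = dens,
                 modes = data.frame(shift = mode_xy[used, 1],
                                    fwhm = mode_xy[used, 2]),
                 n_clusters = length(used),
                 bandwidth = bandwidth,
                 floor_fraction = floor_fraction),
            class = "fl_cluster_map")
}

#' @export
print.fl_cluster_map <- function(x, ...) {
  cat(sprintf("<fl_cluster_map> %d points, %d cluster(s), bandwidth (%.4g, %.4g)\n",
              nrow(x$points), x$n_clusters, x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}

#' Region partition of the analysis window
#'
#' Ordered ppm cut points defining contiguous regions that tile the
#' window. Default boundaries place the two middle regions around the two
#' apo peak positions of the synthetic scenarios.
#'
#' @param boundaries ppm cut points, length >= 3 (R regions need R+1).
#' @return object of class `fl_regions` (boundaries sorted downfield to
#'   upfield, i.e. decreasing ppm).
#' @export
region_partition <- function(boundaries = c(-82.8, -83.45, -83.78,
                                            -84.08, -84.8)) {
  b <- sort(as.numeric(boundaries), decreasing = TRUE)
  if (length(b) < 3 || anyDuplicated(b)) stop("need >= 3 distinct cut points")
  structure(list(boundaries = b), class = "fl_regions")
}

#' Fraction of total peak area per region
#'
#' Per region, the summed area of non-contaminant peaks whose center lies
#' in the region, divided by the total included area. A center exactly on
#' a boundary belongs to the upfield (more negative) region.
#'
#' @param peaks an `fl_peaks` table.
#' @param partition an [region_partition()].
#' @return named numeric vector of fractions summing to 1.
#' @export
region_fractions <- function(peaks, partition) {
  stopifnot(inherits(partition, "fl_regions"))
  b <- partition$boundaries
  pk <- peaks[!peaks$is_contaminant, , drop = FALSE]
  if (nrow(pk) == 0 || sum(pk$area) <= 0)
    stop("no included peak area")
  if (any(pk$center_ppm > b[1] | pk$center_ppm < b[length(b)]))
    stop("peak center outside the tiled window")
  nr <- length(b) - 1
  fr <- numeric(nr)
  for (r in seq_len(nr)) {
    # region r: (b[r+1], b[r]]; a center equal to b[r+1] (its upfield
    # boundary) falls in region r+1, except the last region keeps its edge
    inside <- pk$center_ppm <= b[r] & pk$center_ppm > b[r + 1]
    if (r == nr) inside <- inside | pk$center_ppm == b[r + 1]
    fr[r] <- sum(pk$area[inside])
  }
  fr <- fr / sum(pk$area)
  names(fr) <- paste0("region_", seq_len(nr))
  fr
}

#' Solvent-exposure slope from a D2O titration
#'
#' Least-squares line through chemical shift versus %D2O. An upfield
#' (negative) change of at least `threshold` ppm per 100% D2O classifies
#' the probe as solvent-exposed; a downfield change indicates an
#' interaction perturbed by deuteration ("protected/interacting");
#' anything else is "protected".
#'
#' @param d2o_percent D2O levels in percent (>= 2 distinct values).
#' @param shift_ppm observed shifts (or shift changes) in ppm.
#' @param threshold exposure threshold in ppm per 100% D2O.
#' @return list with `slope_per_100` (signed total change per 100% D2O,
#'   ppm), `classification`, and the `lm` fit.
#' @export
d2o_exposure_analysis <- function(d2o_percent, shift_ppm,
                                  threshold = 0.08) {
  stopifnot(length(d2o_percent) == length(shift_ppm))
  if (length(unique(d2o_percent)) < 2)
    stop("need at least 2 distinct D2O levels")
  fit <- stats::lm(shift_ppm ~ d2o_percent)
  total <- unname(stats::coef(fit)[2]) * 100
  classification <- if (-total >= threshold) "solvent-exposed"
  else if (total > 1e-9) "protected/interacting"
  else "protected"
  list(slope_per_100 = total, classification = classification, fit = fit)
}
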