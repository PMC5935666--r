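#' Write a spectrum as two-column CSV plus a JSON metadata sidecar
#'
#' @param spectrum an `fl_spectrum`.
#' @param path output CSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fl_spectrum"))
  df <- data.frame(ppm = spectrum$axis$ppm,
                   intensity = spectrum$intensity)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- spectrum$meta
  meta$spectrometer_freq <- spectrum$axis$spectrometer_freq
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files must hold two numeric columns (ppm, intensity); a JSON
#' sidecar `<path>.meta.json` written by [write_spectrum()] restores the
#' metadata (in particular the spectrometer frequency; without it, stages
#' needing a ppm-to-Hz conversion refuse to run). Ascending-ppm input is
#' reversed to the canonical decreasing order. JCAMP-DX support covers
#' `##XYDATA=(X++(Y..Y))` blocks in plain (AFFN) form.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"jcamp-dx"`.
#' @return an `fl_spectrum`.
#' @export
read_spectrum <- function(path, dialect = c("csv", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "jcamp-dx") return(read_jcamp(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("too few rows for a spectrum: ", path)
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1, " of ", path)
  ppm <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  nn <- which(!is.finite(ppm) | !is.finite(y))
  if (length(nn) > 0)
    stop("non-numeric data at line ", nn[1] + 1, " of ", path)
  meta <- list()
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  freq <- meta$spectrometer_freq %||% NA_real_
  meta$spectrometer_freq <- NULL
  if (ppm[1] < ppm[length(ppm)]) {
    ppm <- rev(ppm); y <- rev(y)
    meta$axis_reversed_on_read <- TRUE
  }
  if (any(diff(ppm) >= 0)) stop("ppm axis is not strictly monotone")
  axis <- structure(list(ppm = ppm, spectrometer_freq = freq),
                    class = "fl_axis")
  new_spectrum(axis, y, meta)
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0) stop("no XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  if (is.na(end)) end <- length(lines) + 1
  data_lines <- lines[(start[1] + 1):(end - 1)]
  yf <- as.numeric(field("YFACTOR") %||% "1")
  vals <- lapply(strsplit(trimws(data_lines), "[[:space:]]+"), as.numeric)
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1))))
    stop("non-AFFN (compressed) XYDATA is not supported: ", path)
  y <- unlist(lapply(vals, function(v) v[-1])) * yf
  np <- as.numeric(field("NPOINTS") %||% length(y))
  firstx <- as.numeric(field("FIRSTX")) * 1  # already in X units per spec
  lastx <- as.numeric(field("LASTX"))
  if (is.na(firstx) || is.na(lastx))
    stop("JCAMP-DX file lacks FIRSTX/LASTX: ", path)
  ppm <- seq(firstx, lastx, length.out = np)  # FIRSTX/LASTX are in X units
  if (length(y) != np) stop("NPOINTS does not match XYDATA length in ", path)
  freq <- as.numeric(field("\\.OBSERVE FREQUENCY") %||% NA)
  if (ppm[1] < ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  axis <- structure(list(ppm = ppm, spectrometer_freq = freq),
                    class = "fl_axis")
  new_spectrum(axis, y, list(source = "jcamp-dx", title = field("TITLE")))
}

#' Write a deconvolution peak table as CSV
#'
#' Columns: `center_ppm`, `fwhm_ppm`, `area`, `area_fraction`,
#' `phase_rad`, `is_contaminant`.
#'
#' @param result an `fl_deconvolution` (or an `fl_peaks` table).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(result, path) {
  pk <- if (inherits(result, "fl_deconvolution")) result$peaks else result
  if (is.null(pk$area_fraction)) {
    tot <- sum(pk$area[!pk$is_contaminant])
    pk$area_fraction <- ifelse(pk$is_contaminant, NA_real_, pk$area / tot)
  }
  cols <- c("center_ppm", "fwhm_ppm", "area", "area_fraction",
            "phase_rad", "is_contaminant")
  utils::write.csv(as.data.frame(pk)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON fit report for a deconvolution
#' @param result an `fl_deconvolution`.
#' @param path output JSON path.
#' @export
write_fit_report <- function(result, path) {
  stopifnot(inherits(result, "fl_deconvolution"))
  jsonlite::write_json(list(
    selected_n = result$selected_n,
    criterion = result$criterion %||% NA,
    criterion_table = result$criterion_table,
    noise_sd = result$noise_sd,
    rss = result$rss,
    global_phase = result$global_phase,
    baseline = result$baseline,
    converged = result$converged),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a time series (saturation or relaxation) as tidy CSV
#' @param series an `fl_saturation_series` or `fl_relaxation_series`.
#' @param path output CSV path.
#' @export
write_series <- function(series, path) {
  df <- if (inherits(series, "fl_saturation_series")) {
    rbind(data.frame(time_s = series$times,
                     intensity = series$on_intensity, channel = "on"),
          data.frame(time_s = series$times,
                     intensity = series$off_intensity, channel = "off"))
  } else {
    data.frame(time_s = series$times, intensity = series$intensity,
               channel = series$kind)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a saturation-transfer series from tidy CSV
#'
#' Expects columns `time_s`, `intensity`, `channel` with channel values
#' `on` and (optionally) `off`.
#'
#' @param path CSV path.
#' @param r1 fixed longitudinal rate for downstream fitting (1/s).
#' @param i0 initial intensity; defaults to the off-channel mean.
#' @return an `fl_saturation_series`.
#' @export
read_saturation_series <- function(path, r1 = 2.7, i0 = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "intensity", "channel") %in% names(df)))
  on <- df[df$channel == "on", ]
  off <- df[df$channel == "off", ]
  if (nrow(on) == 0) stop("no on-resonance channel in ", path)
  i0 <- i0 %||% (if (nrow(off) > 0) mean(off$intensity) else
    max(on$intensity))
  structure(list(times = on$time_s, on_intensity = on$intensity,
                 off_intensity = if (nrow(off) > 0) off$intensity else NULL,
                 r1 = r1, i0 = i0),
            class = "fl_saturation_series")
}
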