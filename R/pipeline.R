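#' Default pipeline configuration
#'
#' The bundled synthetic study: 16 ligand scenarios drawn from the class
#' templates (plus apo), deconvolution settings, region boundaries,
#' kinetics constants and pharmacology constants. Class-linked functional
#' endpoints emulate coactivator recruitment rising toward upfield
#' ensembles and corepressor recruitment rising toward downfield ones.
#'
#' @param seed integer seed driving every random stage.
#' @return a named list (`fl_config`).
#' @export
default_config <- function(seed) {
  if (missing(seed) || is.null(seed))
    stop("pipeline configuration requires an explicit seed")
  list(
    seed = as.integer(seed),
    scenarios = data.frame(
      label = c(paste0("full_", 1:5), paste0("partial_", 1:4),
                paste0("antag_", 1:2), paste0("inverse_", 1:3),
                paste0("apo_", 1:2)),
      ligand_class = c(rep("full_agonist", 5), rep("partial_agonist", 4),
                       rep("antagonist", 2), rep("inverse_agonist", 3),
                       rep("apo", 2)),
      stringsAsFactors = FALSE),
    axis = list(from = -82, to = -86, n = 4096),
    noise_sd = 0.03,
    deconvolution = list(max_peaks = 4, criterion = "BIC", restarts = 3,
                         max_fwhm = 0.8),
    contaminant_position = -83.3,
    regions = c(-81.5, -83.45, -83.78, -84.08, -86.5),
    kde_bandwidth = c(0.25, 0.08),
    kinetics = list(r1_default = 2.7,
                    conditions = data.frame(
                      label = c("pioglitazone_like", "ciglitazone_like",
                                "slow_like"),
                      k = c(1.2, 1.4, 0.4),
                      r1 = c(2.7, 2.7, 2.7))),
    pharmacology = list(lo = 5e-9, ro = 8e-9, kd = 7.9e-9, q = 1),
    # class-linked endpoint means (coactivator, corepressor)
    endpoints = list(
      full_agonist = c(coact = 1.0, corep = 0.15),
      partial_agonist = c(coact = 0.55, corep = 0.35),
      antagonist = c(coact = 0.35, corep = 0.45),
      inverse_agonist = c(coact = 0.15, corep = 0.95),
      apo = c(coact = 0.30, corep = 0.55)),
    endpoint_noise_sd = 0.05
  )
}

#' Run the full synthetic-study pipeline
#'
#' Chains simulate -> calibrate -> deconvolve -> ensemble metrics ->
#' exchange kinetics -> functional correlation, writing every artifact
#' into `out_dir` with a provenance record (config fingerprint, seed,
#' package version). Deterministic stages are byte-reproducible for a
#' fixed config and seed.
#'
#' @param config a list from [default_config()] (possibly modified).
#' @param out_dir run directory, created if needed.
#' @return (invisibly) a list with the in-memory results: `metrics`,
#'   `cluster_map`, `exchange_fits`, `correlations`, `region_fractions`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed)) stop("config must carry a seed")
  if (!is.null(config$deconvolution$max_peaks) &&
      config$deconvolution$max_peaks < 1)
    stop("max_peaks must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = fnv1a_hash(config), seed = config$seed,
               package = "fluorens",
               version = as.character(utils::packageVersion("fluorens")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- "simulate+deconvolve"
  res <- tryCatch({
    axis <- frequency_axis(config$axis$from, config$axis$to, config$axis$n)
    sc <- config$scenarios
    metrics <- vector("list", nrow(sc))
    peaks_dir <- file.path(out_dir, "peaks")
    dir.create(peaks_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(sc))) {
      scen <- generate_ensemble_scenario(
        sc$ligand_class[i], seed = config$seed + i, axis = axis,
        noise_sd = config$noise_sd, label = sc$label[i])
      cal <- calibrate_axis(scen$spectrum, reference = scen$reference)
      write_spectrum(cal, file.path(out_dir,
                                    paste0(sc$label[i], "_spectrum.csv")))
      dec <- deconvolve(cal,
                        max_peaks = config$deconvolution$max_peaks,
                        criterion = config$deconvolution$criterion,
                        restarts = config$deconvolution$restarts,
                        max_fwhm = config$deconvolution$max_fwhm,
                        contaminant_position = config$contaminant_position,
                        seed = config$seed + 1000 + i)
      write_peaks(dec, file.path(peaks_dir,
                                 paste0(sc$label[i], "_peaks.csv")))
      mj <- major_peaks(dec$peaks)
      fr <- region_fractions(dec$peaks, region_partition(config$regions))
      metrics[[i]] <- data.frame(
        label = sc$label[i], ligand_class = sc$ligand_class[i],
        mean_shift_ppm = mean_weighted_shift(dec$peaks),
        n_peaks = dec$selected_n, n_major_peaks = nrow(mj),
        major_shift = mj$center_ppm[which.max(mj$area)],
        major_fwhm = mj$fwhm_ppm[which.max(mj$area)],
        t(fr))
      logf("scenario %s: %d peak(s) selected, %d major",
           sc$label[i], dec$selected_n, nrow(mj))
    }
    metrics <- do.call(rbind, metrics)

    stage <- "cluster"
    pts <- do.call(rbind, lapply(seq_len(nrow(metrics)), function(i) {
      pk <- utils::read.csv(file.path(peaks_dir,
                                      paste0(metrics$label[i],
                                             "_peaks.csv")))
      class(pk) <- c("fl_peaks", "data.frame")
      mj <- major_peaks(pk)
      if (nrow(mj) == 0) return(NULL)
      data.frame(label = metrics$label[i],
                 ligand_class = metrics$ligand_class[i],
                 shift = mj$center_ppm, fwhm = mj$fwhm_ppm)
    }))
    cmap <- cluster_peak_map(pts$shift, pts$fwhm,
                             bandwidth = config$kde_bandwidth,
                             labels = pts$label)
    cmap$points$ligand_class <- pts$ligand_class
    metrics$cluster_id <- cmap$points$cluster[
      match(metrics$label, cmap$points$label)]

    stage <- "kinetics"
    cond <- config$kinetics$conditions
    exch <- do.call(rbind, lapply(seq_len(nrow(cond)), function(j) {
      ser <- simulate_saturation_series(
        r1 = cond$r1[j], k = cond$k[j],
        times = seq(0, 1.6, length.out = 12),
        noise_sd = 0.01, seed = config$seed + 2000 + j)
      fit <- fit_saturation_transfer(ser)
      data.frame(label = cond$label[j], true_k = cond$k[j], k = fit$k,
                 ci_low = fit$ci95[1], ci_high = fit$ci95[2],
                 below_detectability = fit$below_detectability)
    }))

    stage <- "correlate"
    endpoints <- with_seed(config$seed + 3000, {
      do.call(rbind, lapply(seq_len(nrow(metrics)), function(i) {
        mu <- config$endpoints[[metrics$ligand_class[i]]]
        data.frame(label = metrics$label[i],
                   coactivator = mu["coact"] +
                     stats::rnorm(1, 0, config$endpoint_noise_sd),
                   corepressor = mu["corep"] +
                     stats::rnorm(1, 0, config$endpoint_noise_sd))
      }))
    })
    m <- merge(metrics, endpoints, by = "label")
    co <- correlate_shift_function(m$mean_shift_ppm, m$coactivator)
    cr <- correlate_shift_function(m$mean_shift_ppm, m$corepressor)
    correlations <- data.frame(
      endpoint = c("coactivator", "corepressor"),
      slope = c(co$slope, cr$slope),
      intercept = c(co$intercept, cr$intercept),
      r_squared = c(co$r_squared, cr$r_squared),
      n = c(co$n, cr$n))

    utils::write.csv(m, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(cmap$points, file.path(out_dir, "cluster_map.csv"),
                     row.names = FALSE)
    utils::write.csv(exch, file.path(out_dir, "exchange_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    list(metrics = m, cluster_map = cmap, exchange_fits = exch,
         correlations = correlations)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

#' Summarize a completed run directory
#'
#' Writes one summary CSV per figure-analogue: the shift-linewidth cluster
#' map, the shift-function correlations, and the per-region area
#' fractions. Regeneration is idempotent; an incomplete run produces a
#' partial report listing the gaps.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param report_dir output directory (default `<run_dir>/report`).
#' @return character vector of written files (invisibly); attribute
#'   `gaps` lists missing inputs.
#' @export
write_report <- function(run_dir, report_dir = file.path(run_dir, "report")) {
  if (!dir.exists(run_dir) || length(list.files(run_dir)) == 0)
    stop("run directory is missing or empty: ", run_dir)
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0); gaps <- character(0)
  copy_summary <- function(src, dst) {
    p <- file.path(run_dir, src)
    if (file.exists(p)) {
      df <- utils::read.csv(p)
      utils::write.csv(df, file.path(report_dir, dst), row.names = FALSE)
      written <<- c(written, file.path(report_dir, dst))
    } else gaps <<- c(gaps, src)
  }
  copy_summary("cluster_map.csv", "summary_cluster_map.csv")
  copy_summary("correlations.csv", "summary_correlations.csv")
  mp <- file.path(run_dir, "metrics.csv")
  if (file.exists(mp)) {
    m <- utils::read.csv(mp)
    rc <- grep("^region_", names(m), value = TRUE)
    utils::write.csv(m[, c("label", "ligand_class", rc)],
                     file.path(report_dir, "summary_region_fractions.csv"),
                     row.names = FALSE)
    written <- c(written, file.path(report_dir,
                                    "summary_region_fractions.csv"))
  } else gaps <- c(gaps, "metrics.csv")
  if (length(gaps) > 0)
    warning("partial report; missing: ", paste(gaps, collapse = ", "))
  attr(written, "gaps") <- gaps
  invisible(written)
}
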