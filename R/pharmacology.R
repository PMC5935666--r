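#' Four-parameter logistic (variable-slope) response
#'
#' @param conc concentration (M), > 0.
#' @param bottom,top lower/upper plateaus.
#' @param logec50 log10 of the half-maximal concentration (log10 M).
#' @param hill Hill slope.
#' @return response value(s).
#' @export
fourpl <- function(conc, bottom, top, logec50, hill) {
  bottom + (top - bottom) / (1 + 10^((logec50 - log10(conc)) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least squares with multistart on log EC50 (grid across the tested
#' range) to avoid the usual local minima; asymptotic 95% confidence
#' intervals.
#'
#' @param conc,response paired observations; >= 5 distinct concentrations.
#' @param n_starts number of log EC50 starting values.
#' @return object of class `fl_4pl`: `bottom`, `top`, `logec50`, `hill`,
#'   `ec50`, `ci95` (matrix), `rss`, `converged`, `data`.
#' @export
fit_4pl <- function(conc, response, n_starts = 5) {
  stopifnot(length(conc) == length(response), all(conc > 0))
  if (length(unique(conc)) < 5)
    stop("need at least 5 distinct concentrations")
  if (diff(range(response)) == 0)
    stop("no dose dependence: responses are constant")
  lc <- log10(conc)
  df <- data.frame(lc = lc, y = response)
  starts <- seq(min(lc), max(lc), length.out = n_starts)
  best <- NULL; best_rss <- Inf
  for (s0 in starts) {
    for (h0 in c(1, -1)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^((logec50 - lc) * hill)),
          data = df,
          start = list(bottom = min(response), top = max(response),
                       logec50 = s0, hill = h0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (rss < best_rss) { best <- fit; best_rss <- rss }
      }
    }
  }
  if (is.null(best)) stop("4PL fit failed for every start")
  co <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  tq <- stats::qt(0.975, length(conc) - 4)
  ci <- cbind(low = co - tq * se, high = co + tq * se)
  structure(list(bottom = co[["bottom"]], top = co[["top"]],
                 logec50 = co[["logec50"]], hill = co[["hill"]],
                 ec50 = 10^co[["logec50"]], ci95 = ci, rss = best_rss,
                 converged = TRUE,
                 ec50_in_range = co[["logec50"]] >= min(lc) &&
                   co[["logec50"]] <= max(lc),
                 data = data.frame(conc_M = conc, response = response)),
            class = "fl_4pl")
}

#' @export
print.fl_4pl <- function(x, ...) {
  cat(sprintf(
    "<fl_4pl> bottom %.4g, top %.4g, EC50 %.4g M, hill %.3g (rss %.4g)\n",
    x$bottom, x$top, x$ec50, x$hill, x$rss))
  invisible(x)
}

#' Predicted 4PL response
#' @param fit an `fl_4pl`.
#' @param conc concentrations (M).
#' @export
predict_4pl <- function(fit, conc) {
  fourpl(conc, fit$bottom, fit$top, fit$logec50, fit$hill)
}

# Robust 4PL via iteratively reweighted least squares with Lorentzian
# weights; the residual scale (RSDR) is the 68.27th percentile of absolute
# residuals with a small-sample df correction.
robust_4pl <- function(conc, response, iters = 10) {
  fit <- fit_4pl(conc, response)
  n <- length(conc); p <- 4
  rsdr <- NA_real_
  for (it in seq_len(iters)) {
    res <- response - predict_4pl(fit, conc)
    rsdr <- unname(stats::quantile(abs(res), 0.6827)) * n / (n - p)
    if (!(rsdr > 0)) break
    w <- 1 / (1 + (res / rsdr)^2)
    df <- data.frame(lc = log10(conc), y = response, w = w)
    refit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((logec50 - lc) * hill)),
        data = df, weights = w,
        start = list(bottom = fit$bottom, top = fit$top,
                     logec50 = fit$logec50, hill = fit$hill),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(refit)) break
    co <- stats::coef(refit)
    fit$bottom <- co[["bottom"]]; fit$top <- co[["top"]]
    fit$logec50 <- co[["logec50"]]; fit$hill <- co[["hill"]]
    fit$ec50 <- 10^fit$logec50
  }
  res <- response - predict_4pl(fit, conc)
  rsdr <- unname(stats::quantile(abs(res), 0.6827)) * n / (n - p)
  list(fit = fit, rsdr = rsdr, residuals = res)
}

# Analytic 4PL gradient wrt (bottom, top, logec50, hill) at log10 conc.
grad_4pl <- function(lc, bottom, top, logec50, hill) {
  u <- 10^((logec50 - lc) * hill)
  d <- 1 + u
  cbind(u / d, 1 / d,
        -(top - bottom) * u * log(10) * hill / d^2,
        -(top - bottom) * u * log(10) * (logec50 - lc) / d^2)
}

#' ROUT-style outlier detection for dose-response fits
#'
#' Robust-regression-then-FDR outlier flagging. A Lorentzian-loss
#' (robust) 4PL fit supplies the resistant reference curve and the RSDR
#' (68.27th percentile of absolute residuals with an n/(n-4) degrees-of-
#' freedom correction). Each point is then scored by its leave-one-out
#' studentized residual: the curve is refit without the point (started
#' from the robust estimates), the residual scale comes from that fit's
#' RSS, and the prediction variance includes the point's leverage from
#' the analytic 4PL Jacobian. Two-sided t p-values are flagged by
#' Benjamini-Hochberg at FDR `q` percent. At n around 12-24 a scale
#' estimated from the robust fit's own residuals collapses too easily
#' (redescending loss chases a subset), so the deletion-based scale is
#' what keeps the false-flag rate at the nominal Q. The final fit is
#' ordinary least squares on the retained points; flagged points are
#' reported, never dropped from the output table.
#'
#' @param conc,response observations; >= 8 points.
#' @param q FDR in percent (default 1, i.e. Q = 1%); `q = 0` flags
#'   nothing.
#' @return object of class `fl_rout`: `data` (with `outlier` flags),
#'   `fit` (clean least-squares `fl_4pl`), `robust_fit`, `rsdr`,
#'   `n_flagged`.
#' @export
rout_outliers <- function(conc, response, q = 1) {
  stopifnot(length(conc) == length(response), q >= 0)
  n <- length(conc)
  p <- 4
  if (n < 8) stop("need at least 8 points for outlier detection")
  rob <- tryCatch(robust_4pl(conc, response), error = function(e) NULL)
  if (is.null(rob)) {
    warning("robust fit failed; falling back to plain 4PL with no flags")
    fit <- fit_4pl(conc, response)
    return(structure(list(
      data = data.frame(conc_M = conc, response = response,
                        outlier = FALSE),
      fit = fit, rsdr = NA_real_, n_flagged = 0L), class = "fl_rout"))
  }
  flags <- rep(FALSE, n)
  if (q > 0) {
    lc <- log10(conc)
    fit <- rob$fit
    dfree <- n - 1 - p
    tv <- numeric(n)
    for (i in seq_len(n)) {
      df <- data.frame(lc = lc[-i], y = response[-i])
      del <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^((logec50 - lc) * hill)),
          data = df,
          start = list(bottom = fit$bottom, top = fit$top,
                       logec50 = fit$logec50, hill = fit$hill),
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(del)) next
      co <- stats::coef(del)
      sig <- sqrt(sum(stats::residuals(del)^2) / dfree)
      J <- grad_4pl(lc[-i], co[["bottom"]], co[["top"]],
                    co[["logec50"]], co[["hill"]])
      gi <- grad_4pl(lc[i], co[["bottom"]], co[["top"]],
                     co[["logec50"]], co[["hill"]])
      lev <- tryCatch(drop(gi %*% solve(crossprod(J), t(gi))),
                      error = function(e) p / (n - 1))
      pred <- fourpl(conc[i], co[["bottom"]], co[["top"]],
                     co[["logec50"]], co[["hill"]])
      tv[i] <- abs(response[i] - pred) / (sig * sqrt(1 + max(lev, 0)))
    }
    pv <- 2 * stats::pt(-tv, df = dfree)
    ord <- order(pv)
    ok <- pv[ord] <= (q / 100) * seq_len(n) / n
    if (any(ok)) flags[ord[seq_len(max(which(ok)))]] <- TRUE
  }
  clean_fit <- fit_4pl(conc[!flags], response[!flags])
  structure(list(
    data = data.frame(conc_M = conc, response = response, outlier = flags),
    fit = clean_fit, robust_fit = rob$fit, rsdr = rob$rsdr,
    n_flagged = sum(flags), q = q), class = "fl_rout")
}

#' Bound tracer without competitor (two-species equilibrium)
#'
#' Physical root of the receptor-tracer quadratic:
#' \deqn{L_b = \frac{(R_o + L_o + K_d) - \sqrt{(R_o + L_o + K_d)^2 -
#'   4 R_o L_o}}{2}.}
#'
#' @param lo total tracer (M).
#' @param ro total receptor (M).
#' @param kd tracer dissociation constant (M).
#' @return bound tracer Lb (M).
#' @export
bound_tracer <- function(lo, ro, kd) {
  stopifnot(lo >= 0, ro > 0, kd >= 0)
  s <- ro + lo + kd
  (s - sqrt(s^2 - 4 * ro * lo)) / 2
}

#' Inhibition constant from IC50 (corrected Cheng-Prusoff)
#'
#' \deqn{K_i = \frac{L_b \cdot IC_{50} \cdot K_d}
#'   {L_o R_o + L_b (R_o - L_o + L_b - K_d)}}
#' where Lb is the bound tracer with no competitor (computed from the
#' two-species quadratic unless a measured value is supplied).
#'
#' @param ic50 competitor concentration at 50% tracer displacement (M).
#' @param lo,ro,kd assay constants (M).
#' @param lb bound tracer without competitor (M); computed when `NULL`.
#' @return Ki (M).
#' @export
ki_from_ic50 <- function(ic50, lo, ro, kd, lb = NULL) {
  stopifnot(ic50 > 0, lo > 0, ro > 0, kd > 0)
  if (is.null(lb)) lb <- bound_tracer(lo, ro, kd)
  den <- lo * ro + lb * (ro - lo + lb - kd)
  if (!(den > 0))
    stop("assay outside the equation's validity (non-positive denominator)")
  lb * ic50 * kd / den
}

#' Exact IC50-to-Ki inversion for a competitive binding assay
#'
#' Closed-form species balance at the 50%-displacement point: with bound
#' tracer at Lb/2, the free protein is
#' \eqn{P_{50} = K_d (L_b/2)/(L_o - L_b/2)}, the protein-inhibitor complex
#' is \eqn{PI_{50} = R_o - P_{50} - L_b/2}, and
#' \eqn{K_i = (IC_{50} - PI_{50}) P_{50} / PI_{50}.}
#' This is the exact mass-action inversion of the three-species
#' equilibrium; [ki_from_ic50()] implements the compact published
#' correction, which approximates it (the approximation degrades as
#' tracer Kd grows relative to the receptor concentration). Keeping both
#' lets the package report what the original analysis reported while
#' quantifying the correction's accuracy.
#'
#' @inheritParams ki_from_ic50
#' @return Ki (M).
#' @export
ki_from_ic50_exact <- function(ic50, lo, ro, kd, lb = NULL) {
  stopifnot(ic50 > 0, lo > 0, ro > 0, kd > 0)
  if (is.null(lb)) lb <- bound_tracer(lo, ro, kd)
  p50 <- kd * (lb / 2) / (lo - lb / 2)
  pi50 <- ro - p50 - lb / 2
  if (!(pi50 > 0) || !(ic50 > pi50))
    stop("assay outside the inversion's validity (no inhibitor bound)")
  (ic50 - pi50) * p50 / pi50
}

#' Extract the IC50 from a competition curve
#'
#' Concentration at which the bound-tracer response crosses half of its
#' no-competitor value, by monotone log-concentration interpolation.
#'
#' @param curve an `fl_competition_curve` (or data.frame with `conc_M`,
#'   `response`).
#' @param lb no-competitor bound tracer; taken from the curve attribute or
#'   its zero-concentration point when `NULL`.
#' @return IC50 (M).
#' @export
ic50_from_curve <- function(curve, lb = NULL) {
  lb <- lb %||% attr(curve, "lb") %||% curve$response[curve$conc_M == 0][1]
  if (is.null(lb) || is.na(lb)) stop("no-competitor bound tracer unknown")
  pos <- curve$conc_M > 0
  x <- log10(curve$conc_M[pos])
  y <- curve$response[pos]
  half <- lb / 2
  if (!(min(y) <= half && max(y) >= half))
    stop("curve does not cross half-displacement")
  o <- order(y)
  10^stats::approx(y[o], x[o], xout = half, ties = "ordered")$y
}

#' Receptor occupancy at NMR sample conditions
#'
#' Two-species quadratic with total receptor `ptot`, total ligand `ltot`
#' and constant `ki`; returns the occupied fraction and the free-ligand
#' concentration used downstream for endpoint interpolation.
#'
#' @param ptot total receptor (M).
#' @param ltot total ligand (M), >= 0.
#' @param ki ligand constant (M).
#' @return list: `occupancy` (0-1), `bound` (M), `free_ligand` (M).
#' @export
predict_occupancy <- function(ptot, ltot, ki) {
  stopifnot(ptot > 0, ltot >= 0, ki > 0)
  if (ltot == 0)
    return(list(occupancy = 0, bound = 0, free_ligand = 0))
  s <- ptot + ltot + ki
  bound <- (s - sqrt(s^2 - 4 * ptot * ltot)) / 2
  list(occupancy = bound / ptot, bound = bound,
       free_ligand = ltot - bound)
}

#' Assay endpoint at the free NMR ligand concentration
#'
#' Evaluates the fitted 4PL at the calculated free-ligand concentration.
#' When the upstream fit failed (`fit = NULL`), the measured response
#' nearest in log concentration is substituted and flagged.
#'
#' @param fit an `fl_4pl`, or `NULL` for a failed fit.
#' @param free_ligand free-ligand concentration (M).
#' @param data measured curve (needed on the substitution path).
#' @return list: `response`, `substituted` (logical).
#' @export
trfret_at_free_ligand <- function(fit, free_ligand, data = NULL) {
  stopifnot(free_ligand > 0)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    return(list(response = predict_4pl(fit, free_ligand),
                substituted = FALSE))
  }
  if (is.null(data)) stop("failed fit and no measured data to substitute")
  i <- which.min(abs(log10(data$conc_M) - log10(free_ligand)))
  list(response = data$response[i], substituted = TRUE)
}

#' Linear correlation of ensemble shift with a functional endpoint
#'
#' Ordinary least-squares line; R^2 is the squared Pearson correlation.
#'
#' @param x mean-weighted shifts (ppm) per condition.
#' @param y functional endpoint per condition.
#' @return list of class `fl_correlation`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
correlate_shift_function <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 n = length(x), fit = fit),
            class = "fl_correlation")
}

#' @export
print.fl_correlation <- function(x, ...) {
  cat(sprintf("<fl_correlation> slope %.4g, R^2 %.3f (n = %d)\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}
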