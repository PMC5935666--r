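---
title: "Methods: quantifying conformational ensembles from 1D 19F NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying conformational ensembles from 1D 19F NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorens)
```

## The measurement and its model

A trifluoromethyl probe attached to one site of a protein gives a single
¹⁹F resonance whose position and width report the local conformational
ensemble. Conformations with lifetimes above the shift-difference time
scale (here seconds, versus shift differences of 50–600 Hz) appear as
separate peaks; µs–ms interconversion broadens them; fast averaging
leaves one narrow line. `fluorens` treats a processed 1D spectrum as a
sum of phased Lorentzians,

$$ I(\delta) = b + \sum_i \frac{A_i}{\pi}
   \frac{\cos\phi_i\, w_i/2 + \sin\phi_i\,(\delta - \delta_i)}
        {(\delta-\delta_i)^2 + (w_i/2)^2}, $$

with a constant baseline $b$, areas $A_i \ge 0$, widths $w_i$ (FWHM, ppm)
and per-peak phases $\phi_i$ constrained to within π/50 rad of a single
global phase — enough freedom to absorb imperfect phasing of broad
signals without letting dispersive components masquerade as extra peaks.

**Assumptions.** Frequency-domain noise is iid Gaussian (reasonable for
processed spectra away from artifacts); the baseline is flat; lineshapes
are Lorentzian. Intermediate exchange and field inhomogeneity make real
peaks non-Lorentzian, so fitted models on real data are summaries rather
than literal site counts; the package applies no correction for this.

## Objective deconvolution

`deconvolve()` fits mixtures with 1…`max_peaks` components and selects
the count by an information criterion computed from the Gaussian
log-likelihood at the estimated noise floor:
$\mathrm{RSS}/\hat\sigma^2 + \text{penalty}$, with penalty $p\log N$
(BIC, default), $2p$ (AIC) or AICc, where $p = 4n + 2$. BIC is the
default because it is conservative about adding peaks, which matches the
parsimonious reading a spectroscopist would defend; the criterion is a
user choice because no single statistic is canonical for this task. Ties
go to the smaller model.

The noise floor comes from a signal-free window (`estimate_noise()`,
MAD × 1.4826, rejected if any point sits more than 6 robust SDs from the
window median) or, absent a window, from first differences
(`mad(diff(y))/sqrt(2)`), which is immune to smooth signal.

Numerical choices that matter:

- **Bounds.** FWHM is kept between 2 grid steps (no delta spikes on
  single noise points) and `max_fwhm` (default half the window). The
  bundled pipeline tightens `max_fwhm` to 0.8 ppm (~530 Hz at 16.4 T)
  because fitted "peaks" wider than that are baseline undulation
  absorbers, not resonances, and they distort area fractions and the
  cluster map.
- **Initialization.** Local maxima of a lightly smoothed spectrum above
  5× noise, with non-maximum suppression so one jagged peak top cannot
  fill several slots. When the model asks for more components than there
  are maxima — the partially-overlapped-peaks case — the widest feature
  is split into flanking halves rather than seeding duplicates, which is
  what lets two broad peaks 1.5 widths apart be resolved reliably.
- **Multistart.** Up to `restarts` refits from jittered starts, stopping
  early once the reduced chi-square reaches 1.05; noise-free and
  well-initialized fits therefore pay no restart cost.
- **Degenerate inputs.** A flat spectrum fails with "no dose
  dependence"-style errors rather than returning a zero-width peak; an
  empty peak table is rejected by every metric that needs area.

Unit recovery behaviour (measured in the test suite): with signal-to-noise
50 a single peak's center is recovered to better than 0.002 ppm and its
area to 3%; two peaks five widths apart at SNR 30 are both located to
0.005 ppm; a pair separated by a tenth of a width at SNR 10 is reported —
correctly — as one peak. Model selection picks the generating count in at
least 95 of 100 seeded fixtures for each of those three scenarios.

## Axis calibration

`calibrate_axis()` shifts the whole ppm axis by a constant so the
internal KF reference (coaxial insert) lands exactly on its defined
shift, −119.522 ppm at 298.2 K for this instrument's ¹⁹F transmitter
frequency (658.8462650 MHz, which is also the Hz-per-ppm factor). The
reference peak must be a local maximum at least 5× the noise floor within
0.5 ppm of its stated raw position; otherwise calibration refuses rather
than silently shifting to noise.

## Exchange simulation and kinetics

`simulate_exchange_spectrum()` evaluates the N-site exchange lineshape
$S(\omega) \propto -\mathrm{Re}[\mathbf 1^\top (i\Delta\Omega(\omega) -
R_2 + K)^{-1}\mathbf p]$ per grid point, with the rate matrix $K$ in the
kinetic convention (columns sum to zero, $K\mathbf p = 0$ at
stationarity). The implementation diagonalizes the frequency-independent
part once and sums simple poles, falling back to per-point solves if the
matrix is defective. An algebraically independent closed-form two-site
lineshape (`two_site_lineshape()`, explicit 2×2 determinant inverse) is
kept as the cross-check; the two agree to 10⁻⁶ relative error across
slow, intermediate and fast regimes, and the integrated intensity is
invariant to the exchange rate (conservation of magnetization).

Saturation transfer assumes complete, instantaneous saturation of the
partner resonance (the actual selective-pulse efficiency is hardware
dependent and not modeled), giving

$$ I(t)/I_0 = \frac{R_1}{R_1+k} + \frac{k}{R_1+k}e^{-(R_1+k)t}. $$

`fit_saturation_transfer()` estimates only $k$; $I_0$ comes from the
off-resonance control channel and $R_1$ is fixed from an independent
inversion-recovery measurement (defaults 2.7 s⁻¹, with a per-condition
override such as 2.4 s⁻¹), mirroring how such fits are done with a single
free parameter. The 95% CI is the F-statistic profile of the SSR — the
natural interval for a 1-parameter least-squares fit; a series whose
profile already includes $k = 0$ is flagged "below detectability".
`detectability_limit()` inverts the steady-state depletion
$k/(R_1+k) = z\cdot\text{noise}$ (default $z = 3$): at 2% noise and
$R_1 = 2.7$ s⁻¹ rates below ≈0.17 s⁻¹ are invisible, consistent with the
empirical ~0.4 s⁻¹ practical limit once real saturation efficiency is
less than complete.

CEST profiles use the partner site's normalized Lorentzian as the
saturation efficiency per offset, so with exchange present the profile
mirrors the partner lineshape with minimum $1 - k/(R_1+k)$ at its center.

## Ensemble metrics and clustering

The mean-weighted shift is $\sum A_i\delta_i / \sum A_i$ over all
non-contaminant fitted peaks — sub-5% peaks are included because the 5%
rule is an inclusion filter for the linewidth map, not for whole-spectrum
summaries. The free-label contaminant peak (sharp, near −83.3 ppm) is
flagged by position and excluded from every ensemble metric.

`cluster_peak_map()` estimates a bivariate Gaussian KDE over
(shift, FWHM) points, finds density modes above a floor (5% of the
maximum), and labels points by hill-climbing to their mode. Two modes are
merged when the density saddle between them stays above 50% of the lower
mode: at n ≈ 30–100 a Silverman-bandwidth KDE of even a single Gaussian
cluster is frequently multimodal, and this persistence rule removes those
sampling artifacts while leaving genuinely separated clusters (saddle
near zero) intact. Bandwidths default to the normal reference rule per
dimension; the bundled study pins them to physical scales (0.25 ppm in
shift, 0.08 ppm in width) because the reference rule over-smooths
strongly multimodal maps. Remaining limitation: one or two stray points
far from all clusters can still form a small mode of their own.

Region fractions tile the window with ordered ppm cut points; a center
exactly on a boundary goes to the upfield (more negative) region. The
default four regions bracket the two apo peak positions of the synthetic
templates. D₂O titrations are summarized by the least-squares slope of
shift versus %D₂O: an upfield change of at least 0.08 ppm per 100% D₂O
classifies the probe as solvent-exposed, a downfield change as
"protected/interacting" (deuteration perturbing a contact), anything else
as protected.

## Pharmacology

Dose–response curves use the variable-slope 4PL with multistart on
log EC₅₀. Outlier handling follows the robust-fit-then-FDR idea: a
Lorentzian-loss (IRLS) 4PL supplies the resistant curve and the RSDR
(68.27th percentile of |residuals| × n/(n−4)); the flagging decision then
uses leave-one-out studentized residuals — refit without the point, scale
from that fit's RSS, prediction variance including the point's leverage
from the analytic 4PL Jacobian — with Benjamini–Hochberg at Q (default
1%). The deletion-based decision stage is deliberate: at n ≈ 12–24 a
redescending robust loss occasionally collapses its own residual scale by
chasing a subset of points, which inflates false flags severalfold, while
deleted residuals keep the false-flag rate at the nominal Q without
losing power (measured: ≤2% of clean duplicate-well curves flagged,
100/100 detection of a 10σ point). Flagged points are reported and
excluded from the final least-squares fit, never dropped from tables.
Biphasic curves are handled by a concentration mask (refit without the
top concentrations), not by automatic detection.

Competitive binding: the forward simulator solves the exact three-species
mass action equilibrium (monotone root in free receptor, relative
tolerance 10⁻¹²). `ki_from_ic50()` implements the compact corrected
Cheng–Prusoff equation exactly as it is used in practice,

$$ K_i = \frac{L_b\,IC_{50}\,K_d}{L_oR_o + L_b(R_o - L_o + L_b - K_d)}, $$

with $L_b$ computed from the two-species quadratic unless a measured
value is supplied. This equation is an approximate depletion correction:
`ki_from_ic50_exact()` implements the exact 50%-point inversion
($P_{50} = K_d(L_b/2)/(L_o - L_b/2)$, $PI_{50} = R_o - P_{50} - L_b/2$,
$K_i = (IC_{50}-PI_{50})P_{50}/PI_{50}$), which round-trips the exact
simulator to interpolation precision across $K_i$ 1 nM–1 µM and $K_d$
5–50 nM. At the assay's own constants ($L_o$ 5 nM, $R_o$ 8 nM, $K_d$
7.9 nM) the compact equation overestimates $K_i$ by roughly 15–20%, and
by much more when $K_d$ exceeds $R_o$; both routes are exported so users
can report the published convention while knowing its error.

Occupancy at NMR sample conditions is the two-species quadratic
(e.g. 150 µM receptor, 187.5 µM of a 4 nM ligand is >99% occupied); the
free-ligand concentration it returns feeds the endpoint interpolation
(4PL value at the free concentration, or the nearest measured point,
flagged, when a fit failed). Shift–function association is ordinary least
squares with R² = squared Pearson correlation.

## The synthetic-data generator

Because the study's raw spectra are not deposited, every input is
generated with known ground truth. Class templates emulate the observed
ensemble map: full agonists give one narrow upfield peak (FWHM
0.035–0.06 ppm near −84.2 ppm); apo, partial agonists and antagonists
give two broad peaks (0.12–0.25 ppm) at intermediate shifts; inverse
agonists give a narrow downfield peak plus a broad minor one. Each
scenario adds the sharp free-BTFA contaminant at −83.3 ppm and a KF
reference channel sharing the scenario's raw calibration offset (drawn
within ±0.15 ppm). Defaults: 16k-point grid over −80…−88 ppm (resolving
0.01-ppm lines at 658.8 MHz; the bundled study uses 4096 points over
−82…−86 for speed), frequency-domain noise SD 0.03 (SNR ≈ 50 for broad
peaks), inversion-recovery imperfection 1 (perfect inversion, exposed
because real pulses are not perfect), dose–response plates as 12-point
serial dilutions in duplicate with optional injected gross outliers
(12× noise, recorded in `outlier_truth`).

What the generator does **not** emulate: non-Lorentzian lineshapes from
intermediate exchange or field inhomogeneity, baseline roll, temperature
drift, partial saturation, ligand-depletion kinetics during titration,
and correlated plate noise. Passing tests therefore demonstrate that the
analysis recovers what its own model class generates at realistic noise —
the right first bar for a reimplementation — but not robustness to every
artifact of real spectra.

The bundled 16-scenario study (`run_pipeline(default_config(seed))`)
chains simulate → calibrate → deconvolve → metrics → cluster → kinetics →
correlate, with class-linked coactivator/corepressor endpoint means so
that the expected signature — coactivator recruitment rising toward
upfield mean shifts, corepressor toward downfield — is recoverable from
the pipeline's own measurements. Problem sizes throughout the tests
(4096-point spectra, 100-seed recovery batteries, 12×2-well plates) were
chosen so each suite answers its statistical question in minutes on one
core.

## Design decisions at genuinely open points

- **Selection criterion**: configurable, BIC default (see above); the
  original fitting program's statistic is not public.
- **Command-line interface**: none. The package is driven from R; the
  readers/writers and `run_pipeline()`/`write_report()` are the
  integration surface, and `scripts/acceptance.R` shows headless use.
- **$L_b$** is computed from the quadratic by default (a measured
  override exists) — whether the original analysis measured or computed
  it is not stated.
- **Mean-weighted shift** includes sub-5% peaks and excludes the
  contaminant; both behaviours are toggleable.
- **Saturation efficiency** is assumed complete; mapping a shaped pulse's
  power to a partial efficiency needs hardware calibration that no
  published number replaces.

## Known limitations

Constant baseline only; no J-coupling or multiplet models; two-site
exchange only for saturation-transfer and CEST interpretation (the
lineshape simulator itself is N-site); KDE cluster count has no
uncertainty attached; the compact Kᵢ correction's bias is documented but
not corrected in the default reporting path, since matching the published
convention is the point of that function.
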