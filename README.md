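# fluorens

Quantitative analysis of protein conformational ensembles from 1D ¹⁹F NMR.

A single trifluoromethyl probe (e.g. BTFA attached to a cysteine on the
switch helix of a nuclear-receptor ligand-binding domain) reports the
conformational ensemble of the surrounding surface: long-lived
conformations appear as distinct Lorentzian peaks, µs–ms dynamics broaden
them, and fast averaging collapses them to one narrow line. `fluorens`
implements the full analysis chain for such spectra:

- **Axis calibration** against an internal KF reference in a coaxial
  insert (defined shift −119.522 ppm at a ¹⁹F transmitter frequency of
  658.8462650 MHz).
- **Objective deconvolution**: Lorentzian mixtures (center, FWHM, area,
  phase within π/50 rad of a global phase) fit by bounded
  Levenberg–Marquardt, with the number of peaks selected statistically
  (BIC by default) — no operator decides how many conformations there are.
- **Ensemble metrics**: area-weighted mean chemical shift, the >5 %-area
  major-peak rule, the FWHM-vs-shift map with bivariate-KDE mode
  clustering, region area fractions, and D₂O solvent-exposure slopes.
- **Exchange kinetics**: Bloch–McConnell multi-site lineshape simulation,
  saturation-transfer (Forsén–Hoffman) exchange-rate fits with a single
  free parameter and F-profile 95 % CIs, CEST profiles, T₁/T₂ fits, and
  the FWHM = 1/(πT₂) consistency check.
- **Pharmacology**: variable-slope 4PL dose–response fits, ROUT-style
  robust outlier detection, competitive-binding Kᵢ via the corrected
  Cheng–Prusoff equation
  Kᵢ = Lb·IC₅₀·K_d / [Lo·Ro + Lb(Ro − Lo + Lb − K_d)]
  (plus an exact mass-action inversion for comparison), receptor-occupancy
  prediction, and shift-vs-function linear correlations (R²).
- **Synthetic data**: every input above can be generated with known ground
  truth (class-templated ensembles, exchange-broadened spectra,
  saturation/relaxation series, dose–response plates with injected
  outliers), so the whole pipeline is testable end to end.

## Worked example

```r
library(fluorens)

# a partial-agonist-like scenario: two broad peaks + free-label contaminant
scen <- generate_ensemble_scenario("partial_agonist", seed = 42)
cal  <- calibrate_axis(scen$spectrum, reference = scen$reference)
dec  <- deconvolve(cal, max_peaks = 4, contaminant_position = -83.3,
                   seed = 42)
dec
#> <fl_deconvolution> 3 peak(s), rss 14.95, noise 0.03028
#>   center_ppm   fwhm_ppm       area    phase_rad is_contaminant area_fraction
#> 1  -83.29975 0.01214298 0.02996043 -0.011405193           TRUE            NA
#> 2  -83.55938 0.20309818 0.62426132  0.002591869          FALSE     0.6242867
#> 3  -84.00663 0.18332510 0.37569803 -0.003541739          FALSE     0.3757133

mean_weighted_shift(dec$peaks)   # area-weighted ensemble position, ppm
#> [1] -83.72742

# exchange rate from a saturation-transfer series (fixed R1 = 2.7 1/s)
ser <- simulate_saturation_series(r1 = 2.7, k = 1.2,
                                  times = seq(0, 1.6, length.out = 12),
                                  noise_sd = 0.01, seed = 1)
fit_saturation_transfer(ser)
#> <fl_exchange_fit> k = 1.18 1/s (95% CI 1.15-1.21)
```

The deconvolution reports the two broad sub-ensembles (62 % and 38 % of
the protein signal) and flags the sharp free-BTFA contaminant near
−83.3 ppm; the saturation-transfer fit recovers the seconds-scale
interconversion rate between conformations with its 95 % confidence
interval.

The bundled 16-ligand synthetic study chains every stage:

```r
res <- run_pipeline(default_config(seed = 11), "study_run")
res$correlations
#>      endpoint      slope intercept r_squared  n
#> 1 coactivator -1.0705765 -89.17918 0.9027806 16
#> 2 corepressor  0.9643445  81.28833 0.8922677 16
```

Coactivator recruitment rises toward upfield (more negative) mean shifts
and corepressor recruitment toward downfield ones — the functional
signature of the agonist/inverse-agonist ensemble axis.

## Glossary conventions

The ppm axis decreases left to right; "upfield" means more negative ppm
(rightward in conventional plots). FWHM of a pure Lorentzian relates to
the transverse lifetime by FWHM(Hz) = 1/(πT₂) = R₂/π.

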