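Package: fluorens
Title: Ligand-Dependent Conformational Ensemble Analysis from 1D 19F NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise ligand-dependent protein conformational
    ensembles from one-dimensional fluorine-19 NMR spectra. Provides
    Lorentzian mixture deconvolution with objective (information-criterion)
    model selection, axis calibration against an internal potassium fluoride
    reference, Bloch-McConnell multi-site chemical-exchange lineshape
    simulation, saturation-transfer exchange-rate estimation with profile
    confidence intervals, T1/T2 relaxation fitting, ensemble descriptors
    (mean-weighted chemical shift, kernel-density peak clustering, region
    area fractions, D2O solvent-exposure slopes), and ligand pharmacology
    (four-parameter logistic dose-response fits, ROUT outlier detection,
    competitive-binding Ki via the corrected Cheng-Prusoff equation, and
    receptor occupancy prediction). A synthetic-data module generates every
    input the pipeline consumes so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
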