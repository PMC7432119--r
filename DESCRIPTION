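Package: mrscorr
Title: Statistical Correlations from Spectral Overlap in MRS Metabolite Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how spectral overlap and baseline modelling induce
    purely statistical correlations among fitted metabolite amplitudes in 1D
    magnetic resonance spectra. Provides Lorentzian spectrum synthesis, linear
    and bounded nonlinear least-squares fitting with an optional penalized
    spline baseline, analytic amplitude covariance sigma^2 (B'B)^-1 and
    Fisher-information covariance, a closed-form two-singlet correlation
    oracle, and seeded Monte Carlo experiments: a two-singlet
    overlap-correlation study and a paired line-broadening/baseline
    perturbation study on synthetic spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
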