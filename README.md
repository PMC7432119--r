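# mrscorr

Overlapping resonances in 1D magnetic resonance spectra make fitted
metabolite amplitudes *statistically* correlated even when the underlying
metabolites are biologically unrelated. `mrscorr` is an R package for
quantifying that effect — for spectroscopists and methodologists who need to
know how much of an observed "metabolite correlation" is an artifact of
spectral overlap or of baseline modelling, before giving it a neurochemical
interpretation.

## The model

Linear-combination spectral fitting solves, in the least-squares sense,

```
spec = basis %*% conc + noise
```

where `basis` holds one sampled unit-amplitude lineshape per component and
`conc` are the fitted amplitudes ("concentrations"). With white noise of
variance σ², the amplitude estimates have covariance

```
COV(conc) = σ² (Bᵀ B)⁻¹
```

so any overlap between basis columns (a non-diagonal Gram matrix) couples
the estimates. For two equal-width absorption Lorentzians separated by Δ Hz
the amplitude correlation has the continuum closed form

```
ρ(Δ) = − fwhm² / (Δ² + fwhm²)
```

−1 at complete overlap, 0 at infinite separation. When center frequencies
are fitted alongside amplitudes (the usual practice), the coupling is
stronger; the package computes the exact value for any parameterization from
the Fisher information matrix, and verifies everything by seeded Monte Carlo
with real nonlinear fits.

A second, subtler mechanism is the baseline: a flexible baseline model
overlapping several peaks couples their estimates *positively* — when the
baseline is overestimated, all peaks riding on it are underestimated
together. The package's paired line-broadening experiment reproduces this on
synthetic data: broadening the lines of the same spectrum (at constant SNR)
shifts signal into the baseline's territory and biases all overlapped
amplitudes downward, jointly.

## What's in the package

* `spectral_axis()`, `lorentzian()`, `spectrum_model()`, `synthesize()`,
  `apply_line_broadening()`, `add_noise()` — declarative spectrum synthesis.
* `fit_linear()`, `fit_nonlinear()`, `fit_with_baseline()` — least-squares
  fitting (bounded Levenberg–Marquardt, optional penalized-spline baseline),
  with residual-based σ̂² and full parameter covariance.
* `analytic_covariance()`, `closed_form_pair_correlation()`,
  `fisher_covariance()` — the covariance/correlation theory.
* `run_overlap_mc()`, `run_broadening_experiment()`,
  `summarize_experiment()` — seeded, bit-reproducible Monte Carlo studies.
* `run_cli()` (plus the `inst/scripts/mrscorr` wrapper) — `simulate`, `fit`,
  `mc-overlap`, `broadening-exp`, `cov-analytic` subcommands over JSON
  configs and CSV spectra.

## Worked example

Two unit-height Lorentzian singlets, 8 Hz linewidth. First the analytic
answer at one separation, then the Monte Carlo experiment across three:

```r
library(mrscorr)

axis  <- spectral_axis(2048, 2000, 4.7, 297.2)
model <- two_singlet_model(separation_hz = 8, fwhm = 8)
analytic_covariance(basis_matrix(model, axis), sigma_sq = 0.05^2)
#> <covariance_report> 2 parameter(s), sigma^2 = 0.0025
#> correlation:
#>       peak1 peak2
#> peak1   1.0  -0.5
#> peak2  -0.5   1.0
#> CRLB (SD):
#>    peak1    peak2
#> 0.022761 0.022761

run_overlap_mc(overlap_mc_config(separations = c(40, 8, 4),
                                 n_reps = 1000, seed = 1))
#> <overlap_mc_result> fit mode 'amp_freq', 1000 replicate(s), snr 20
#>  separation_hz correlation    ci_lo    ci_hi  boot_se n_converged n_reps
#>             40    0.006155 -0.05516  0.06656 0.031240        1000   1000
#>              8   -0.634167 -0.66879 -0.59519 0.018928        1000   1000
#>              4   -0.978049 -0.98049 -0.97516 0.001373        1000   1000
```

Reading: at 40 Hz separation (5 linewidths) the two amplitude estimates are
essentially independent; at one linewidth they are strongly anticorrelated
(−0.63 with amplitude+frequency fitting, vs the −0.50 amplitudes-only
analytic value); at half a linewidth the fit can barely tell the peaks apart
and the estimates are nearly perfectly anticorrelated. None of this reflects
any relationship between the underlying signals — it is pure estimation
geometry, and it is what a naive across-subject correlation analysis of
overlapped metabolites would inherit.

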