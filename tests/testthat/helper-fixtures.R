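# shared fixtures: small axes and models built in code

default_axis <- function() spectral_axis(2048, 2000, 4.7, 297.2)

# dense grid used for continuum-limit checks: >= 100 points per fwhm,
# spanning >= 40 fwhm
dense_axis <- function(fwhm = 8, points_per_fwhm = 100, span_fwhm = 40) {
  n <- points_per_fwhm * span_fwhm
  spectral_axis(n, span_fwhm * fwhm, 4.7, 297.2)
}

random_model <- function(k, axis, seed) {
  set.seed(seed)
  f <- axis_hz(axis)
  span <- diff(range(f))
  comps <- lapply(seq_len(k), function(j) {
    lorentzian(stats::runif(1, f[1] + span / 4, f[length(f)] - span / 4),
               stats::runif(1, 4, 20), stats::runif(1, 0.5, 2),
               label = paste0("p", j), unit = "hz")
  })
  spectrum_model(comps)
}
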