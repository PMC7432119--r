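test_that("axis grid is uniform with spacing spectral_width/n_points", {
  ax <- spectral_axis(2048, 2000, 4.7, 297.2)
  f <- axis_hz(ax)
  expect_length(f, 2048)
  expect_equal(unique(round(diff(f), 12)), 2000 / 2048)  # 0.9765625 Hz
  expect_true(all(diff(f) > 0))

  ax2 <- spectral_axis(2, 10, 0, 100)
  expect_equal(diff(axis_hz(ax2)), 5)
})

test_that("ppm <-> Hz conversion is an exact bijection on the axis", {
  ax <- spectral_axis(1024, 1500, 4.7, 297.2)
  expect_equal(ppm_to_hz(5.7, ax), 297.2)  # 1 ppm above carrier
  f <- axis_hz(ax)
  expect_equal(ppm_to_hz(hz_to_ppm(f, ax), ax), f, tolerance = 1e-14)
})

test_that("axis constructor rejects invalid parameters", {
  expect_error(spectral_axis(1, 2000), "n_points")
  expect_error(spectral_axis(128, -5), "spectral_width")
  expect_error(spectral_axis(128, 2000, 4.7, 0), "transmitter")
})

test_that("unit Lorentzian profile obeys the half-height definition", {
  ax <- dense_axis()
  f <- axis_hz(ax)
  fwhm <- 8
  prof <- lorentzian_profile(ax, 0, fwhm)
  at <- function(x) prof[which.min(abs(f - x))]
  expect_equal(at(0), 1.0, tolerance = 1e-10)
  expect_equal(at(fwhm / 2), 0.5, tolerance = 1e-3)
  expect_equal(at(-fwhm / 2), 0.5, tolerance = 1e-3)
  # closed form 1/(1 + (2*delta/fwhm)^2) at one linewidth off center
  expect_equal(at(fwhm), 0.2, tolerance = 1e-3)
  expect_equal(at(-fwhm), 0.2, tolerance = 1e-3)
})

test_that("off-axis center warns and truncates", {
  ax <- spectral_axis(128, 100, 0, 100)
  expect_warning(p <- lorentzian_profile(ax, 500, 8), "outside the axis")
  expect_length(p, 128)
})

test_that("synthesis is exactly linear in component amplitudes", {
  ax <- default_axis()
  for (seed in 1:5) {
    m <- random_model(3, ax, seed)
    y1 <- synthesize(m, ax)$real
    m2 <- m
    scl <- c(2, -0.5, 3)
    for (j in 1:3) m2$components[[j]]$amplitude <-
        m$components[[j]]$amplitude * scl[j]
    y2 <- synthesize(m2, ax)$real
    parts <- vapply(1:3, function(j) {
      mj <- spectrum_model(m$components[j])
      synthesize(mj, ax)$real
    }, numeric(ax$n_points))
    expect_equal(y1, rowSums(parts), tolerance = 1e-12)
    expect_equal(y2, drop(parts %*% scl), tolerance = 1e-12)
  }
})

test_that("equal and opposite components cancel exactly", {
  ax <- default_axis()
  m <- spectrum_model(list(
    lorentzian(0, 8, 1.5, label = "a", unit = "hz"),
    lorentzian(0, 8, -1.5, label = "b", unit = "hz")
  ))
  expect_equal(synthesize(m, ax)$real, numeric(2048))
})

test_that("well-separated singlets give two resolved maxima", {
  ax <- default_axis()
  s <- synthesize(two_singlet_model(40, fwhm = 8), ax)
  f <- axis_hz(ax)
  inner <- which(f > -60 & f < 60)
  y <- s$real[inner]
  peaks <- inner[which(diff(sign(diff(y))) == -2) + 1]
  expect_length(peaks, 2)
  expect_equal(sort(f[peaks]), c(-20, 20), tolerance = 1)
})

test_that("empty model warns and yields a zero spectrum", {
  ax <- spectral_axis(64, 100)
  m <- structure(list(components = list(), baseline_components = list(),
                      name = "empty"), class = "spectrum_model")
  expect_warning(s <- synthesize(m, ax), "empty model")
  expect_equal(s$real, numeric(64))
})

test_that("model line broadening adds widths exactly and conserves area", {
  ax <- dense_axis()
  m <- spectrum_model(lorentzian(0, 8, 2, label = "p", unit = "hz"))
  mb <- apply_line_broadening(m, 2)
  expect_equal(mb$components[[1]]$fwhm, 10)
  f <- axis_hz(ax)
  a0 <- mrscorr:::trapz(f, synthesize(m, ax)$real)
  a1 <- mrscorr:::trapz(f, synthesize(mb, ax)$real)
  expect_equal(a1 / a0, 1, tolerance = 5e-3)
  expect_error(apply_line_broadening(m, -1), "non-negative")
})

test_that("broadening by b1 then b2 equals broadening by b1+b2 (semigroup)", {
  m <- spectrum_model(list(lorentzian(-10, 8, 1, label = "a", unit = "hz"),
                           lorentzian(15, 5, 2, label = "b", unit = "hz")))
  one <- apply_line_broadening(m, 3)
  two <- apply_line_broadening(apply_line_broadening(m, 1), 2)
  expect_equal(two, one, tolerance = 1e-12)
  # and numerically on the sampled-spectrum convolution path
  ax <- dense_axis()
  s <- synthesize(m, ax)
  s_one <- apply_line_broadening(s, 3)
  s_two <- apply_line_broadening(apply_line_broadening(s, 1), 2)
  # discrete kernels only approximate the continuum convolution identity
  expect_equal(s_two$real, s_one$real, tolerance = 1e-2)
  expect_equal(apply_line_broadening(s, 0)$real, s$real)
})

test_that("sampled-spectrum broadening matches the exact model path", {
  ax <- dense_axis()
  m <- spectrum_model(lorentzian(0, 8, 1, label = "p", unit = "hz"))
  via_model <- synthesize(apply_line_broadening(m, 2), ax)$real
  via_fft <- apply_line_broadening(synthesize(m, ax), 2)$real
  expect_equal(via_fft, via_model, tolerance = 5e-3)
})

test_that("add_noise follows the SNR convention and records sigma", {
  ax <- default_axis()
  s <- synthesize(spectrum_model(lorentzian(0, 8, 1, label = "p",
                                            unit = "hz")), ax)
  expect_identical(add_noise(s, sigma = 0)$real, s$real)
  n1 <- add_noise(s, snr = 20, seed = 3)
  expect_equal(n1$noise_sigma, 0.05)  # peak height 1.0 / SNR 20
  expect_error(add_noise(s, sigma = 1, snr = 2), "exactly one")
  expect_error(add_noise(s, snr = -2), "positive")
  flat <- mrs_spectrum(ax, rep(-1, 2048))
  expect_error(add_noise(flat, snr = 20), "reference peak")
})

test_that("seeded noise is bit-reproducible, seeds independent", {
  ax <- spectral_axis(4096, 2000)
  s <- mrs_spectrum(ax, numeric(4096))
  a <- add_noise(s, sigma = 0.05, seed = 11)
  b <- add_noise(s, sigma = 0.05, seed = 11)
  c <- add_noise(s, sigma = 0.05, seed = 12)
  expect_identical(a$real, b$real)
  expect_false(identical(a$real, c$real))
  expect_lt(abs(cor(a$real, c$real)), 3 / sqrt(4096))
})

test_that("empirical noise SD matches the requested sigma", {
  ax <- spectral_axis(1e6, 1000)
  s <- mrs_spectrum(ax, numeric(1e6))
  n <- add_noise(s, sigma = 0.05, seed = 5)
  expect_equal(sd(n$real), 0.05, tolerance = 5e-3)  # within 0.5%
})

test_that("add_noise with a seed leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(add_noise(mrs_spectrum(spectral_axis(64, 100), numeric(64)),
                      sigma = 1, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("basis matrix columns are peak-height normalized and labelled", {
  ax <- spectral_axis(2000, 2000)  # 1 Hz grid: centers +/-20 are on-grid
  m <- two_singlet_model(40)
  B <- basis_matrix(m, ax)
  expect_equal(unname(apply(B, 2, max)), c(1, 1), tolerance = 1e-12)
  expect_identical(colnames(B), c("peak1", "peak2"))
  Ba <- basis_matrix(m, ax, normalization = "area")
  f <- axis_hz(ax)
  expect_equal(unname(apply(Ba, 2, function(y) mrscorr:::trapz(f, y))),
               c(1, 1), tolerance = 1e-10)
})

test_that("duplicate component labels are rejected", {
  expect_error(spectrum_model(list(
    lorentzian(0, 8, label = "x", unit = "hz"),
    lorentzian(5, 8, label = "x", unit = "hz"))), "unique")
})
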