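test_that("linear fit recovers exact amplitudes from a noiseless spectrum", {
  ax <- default_axis()
  m <- two_singlet_model(8, amplitudes = c(1.3, 0.4))
  s <- synthesize(m, ax)
  fit <- fit_linear(s, basis_matrix(m, ax))
  expect_equal(unname(fit$amplitudes), c(1.3, 0.4), tolerance = 1e-10)
  expect_equal(fit$sigma_hat_sq, 0, tolerance = 1e-20)
})

test_that("linear fit matches an explicit normal-equations solve", {
  # independent oracle: dense solve of B'B conc = B'y on a tiny toy system
  set.seed(42)
  B <- matrix(rnorm(15), 5, 3)
  colnames(B) <- c("a", "b", "c")
  y <- rnorm(5)
  oracle <- solve(t(B) %*% B) %*% (t(B) %*% y)
  ax <- spectral_axis(5, 5)
  fit <- fit_linear(mrs_spectrum(ax, y), B)
  expect_equal(unname(fit$amplitudes), unname(drop(oracle)), tolerance = 1e-10)
  oracle_cov <- fit$sigma_hat_sq * solve(t(B) %*% B)
  expect_equal(unname(fit$covariance), unname(oracle_cov), tolerance = 1e-10)
})

test_that("duplicated basis column raises a singular-design error naming it", {
  ax <- default_axis()
  m <- spectrum_model(list(lorentzian(0, 8, label = "glu", unit = "hz"),
                           lorentzian(0, 8, label = "gln", unit = "hz")))
  s <- synthesize(m, ax)
  expect_error(fit_linear(s, basis_matrix(m, ax)), "glu.*gln|singular")
})

test_that("linear-mode residual is orthogonal to the design columns", {
  ax <- default_axis()
  m <- two_singlet_model(8)
  s <- add_noise(synthesize(m, ax), sigma = 0.05, seed = 2)
  B <- basis_matrix(m, ax)
  fit <- fit_linear(s, B)
  expect_equal(drop(crossprod(unclass(B), fit$residual)), c(peak1 = 0, peak2 = 0),
               tolerance = 1e-8)
})

test_that("linear covariance equals the analytic formula (algebraic identity)", {
  ax <- default_axis()
  m <- two_singlet_model(8)
  s <- add_noise(synthesize(m, ax), sigma = 0.05, seed = 7)
  B <- basis_matrix(m, ax)
  fit <- fit_linear(s, B)
  ana <- analytic_covariance(B, fit$sigma_hat_sq)
  expect_equal(unname(amplitude_covariance(fit)), unname(ana$covariance),
               tolerance = 1e-12)
})

test_that("noiseless truth-initialized nonlinear fit is a fixed point", {
  ax <- default_axis()
  m <- two_singlet_model(8, amplitudes = c(1, 0.7))
  s <- synthesize(m, ax)
  for (mode in c("amp_freq", "amp_freq_width", "amp_freq_width_phase")) {
    fit <- fit_nonlinear(s, m, fit_spec(mode))
    expect_true(fit$converged)
    expect_equal(unname(fit$amplitudes), c(1, 0.7), tolerance = 1e-6)
    expect_equal(unname(fit$centers), c(-4, 4), tolerance = 1e-6)
    expect_equal(unname(fit$fwhms), c(8, 8), tolerance = 1e-5)
  }
})

test_that("nonlinear amplitude estimates are unbiased under noise", {
  ax <- spectral_axis(512, 500)
  m <- spectrum_model(lorentzian(0, 8, 1, label = "p", unit = "hz"))
  s <- synthesize(m, ax)
  n_rep <- 300
  est <- vapply(seq_len(n_rep), function(i) {
    noisy <- add_noise(s, sigma = 0.05, seed = 1000 + i)
    fit_nonlinear(noisy, m, fit_spec("amp_freq_width"))$amplitudes[[1]]
  }, numeric(1))
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 1), 3 * se)
})

test_that("frequency bounds prevent label switching at 4 Hz separation", {
  ax <- default_axis()
  m <- two_singlet_model(4)
  # adversarial: initial centers nudged towards each other's peak
  init <- spectrum_model(list(
    lorentzian(-0.5, 8, 1, label = "peak1", unit = "hz"),
    lorentzian(0.5, 8, 1, label = "peak2", unit = "hz")))
  s <- add_noise(synthesize(m, ax), sigma = 0.05, seed = 9)
  fit <- fit_nonlinear(s, init, fit_spec("amp_freq", frequency_bound_hz = 0.5))
  expect_lte(fit$centers[["peak1"]], 0)
  expect_gte(fit$centers[["peak2"]], 0)
  expect_lt(fit$centers[["peak1"]], fit$centers[["peak2"]])
})

test_that("heavy penalty drives the baseline to zero for a flat truth", {
  ax <- spectral_axis(1024, 1000)
  m <- two_singlet_model(20)
  s <- add_noise(synthesize(m, ax), sigma = 0.02, seed = 4)
  no_bl <- fit_nonlinear(s, m, fit_spec("amp_freq", window_hz = c(-200, 200)))
  with_bl <- fit_with_baseline(s, m, fit_spec("amp_freq",
    baseline = baseline_spec(25, 1e8), window_hz = c(-200, 200)))
  expect_lt(max(abs(with_bl$baseline_curve)), 0.01)
  expect_equal(unname(with_bl$amplitudes), unname(no_bl$amplitudes),
               tolerance = 0.02)
})

test_that("an additive constant offset is absorbed by an unpenalized baseline", {
  ax <- spectral_axis(1024, 1000)
  m <- two_singlet_model(20)
  s0 <- synthesize(m, ax)
  s_off <- mrs_spectrum(ax, s0$real + 0.3)
  spec <- fit_spec("amplitudes_only", baseline = baseline_spec(100, 0),
                   window_hz = c(-200, 200))
  fit0 <- fit_nonlinear(s0, m, spec)
  fit1 <- fit_nonlinear(s_off, m, spec)
  expect_equal(unname(fit1$amplitudes), unname(fit0$amplitudes),
               tolerance = 1e-4)
  expect_equal(mean(fit1$baseline_curve) - mean(fit0$baseline_curve), 0.3,
               tolerance = 1e-3)
})

test_that("negative penalty weight is rejected", {
  expect_error(baseline_spec(20, -1), "non-negative")
  expect_error(baseline_spec(0, 1), "positive")
})

test_that("RSS is non-decreasing as the fit window grows", {
  ax <- spectral_axis(2048, 2000)
  m <- two_singlet_model(8)
  s <- add_noise(synthesize(m, ax), sigma = 0.05, seed = 21)
  rss <- vapply(c(50, 100, 200, 400, 800), function(half) {
    fit <- fit_nonlinear(s, m, fit_spec("amp_freq", window_hz = c(-half, half)))
    sum(fit$residual^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= 0))
})

test_that("rougher baselines never decrease amplitude variance", {
  ax <- spectral_axis(1024, 1000)
  m <- two_singlet_model(18, fwhm = 8)
  s <- add_noise(synthesize(m, ax), sigma = 0.05, seed = 31)
  sds <- vapply(c(80, 40, 20), function(spacing) {
    fit <- fit_with_baseline(s, m, fit_spec("amplitudes_only",
      baseline = baseline_spec(spacing, 0), window_hz = c(-200, 200)))
    amplitude_sds(fit)[[1]]
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("noise sigma estimation works in a signal-free window", {
  ax <- spectral_axis(2048, 2000)
  m <- spectrum_model(lorentzian(-400, 8, 1, label = "p", unit = "hz"))
  pure <- add_noise(mrs_spectrum(ax, numeric(2048)), sigma = 0.05, seed = 6)
  est <- estimate_noise_sigma(pure, c(200, 500))  # 512-ish points
  expect_equal(est, 0.05, tolerance = 0.1 * 0.05 / 0.05)  # within 10%
  expect_lt(abs(est / 0.05 - 1), 0.10)

  clean <- synthesize(m, ax)
  expect_lt(estimate_noise_sigma(clean, c(300, 600), model = m), 1e-4)
  expect_error(estimate_noise_sigma(clean, c(-420, -380), model = m),
               "overlaps model component")
  expect_error(estimate_noise_sigma(clean, c(0, 5)), "at least 32")
})
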