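#' Construct a sampled spectrum
#'
#' @param axis A `spectral_axis`.
#' @param real Real (absorption) channel intensities, length `axis$n_points`.
#' @param imag Optional imaginary channel of the same length.
#' @param noise_sigma Optional known/estimated noise standard deviation.
#' @return An object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(axis, real, imag = NULL, noise_sigma = NULL) {
  stopifnot(inherits(axis, "spectral_axis"))
  real <- as.numeric(real)
  if (length(real) != axis$n_points) {
    stop("`real` must have length axis$n_points", call. = FALSE)
  }
  if (!all(is.finite(real))) stop("`real` contains non-finite values", call. = FALSE)
  if (!is.null(imag)) {
    imag <- as.numeric(imag)
    if (length(imag) != axis$n_points || !all(is.finite(imag))) {
      stop("`imag` must be finite and of length axis$n_points", call. = FALSE)
    }
  }
  structure(list(axis = axis, real = real, imag = imag,
                 noise_sigma = noise_sigma),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points over %.6g Hz%s%s\n",
              x$axis$n_points, x$axis$spectral_width,
              if (is.null(x$imag)) ", real only" else ", complex",
              if (is.null(x$noise_sigma)) "" else
                sprintf(", noise sigma %.4g", x$noise_sigma)))
  invisible(x)
}

#' Synthesize a noiseless spectrum from a model
#'
#' The real channel is the sum of amplitude-scaled component profiles
#' (metabolite and baseline components alike); synthesis is exactly linear in
#' the amplitudes.
#'
#' @param model A `spectrum_model`.
#' @param axis A `spectral_axis`.
#' @return An `mrs_spectrum` (noiseless; `noise_sigma = 0`).
#' @export
synthesize <- function(model, axis) {
  stopifnot(inherits(model, "spectrum_model"), inherits(axis, "spectral_axis"))
  comps <- c(model$components, model$baseline_components)
  y <- numeric(axis$n_points)
  if (length(comps) == 0L) {
    warning("empty model: returning zero spectrum", call. = FALSE)
  }
  for (cp in comps) {
    y <- y + cp$amplitude *
      lorentzian_profile(axis, component_center_hz(cp, axis), cp$fwhm, cp$phase)
  }
  mrs_spectrum(axis, y, noise_sigma = 0)
}

#' Apply Lorentzian line broadening
#'
#' Broadening by `b` Hz convolves every line with a unit-area Lorentzian of
#' width `b`. For Lorentzian components the widths add exactly:
#' `fwhm -> fwhm + b`, and peak heights are rescaled by `fwhm / (fwhm + b)`
#' so that each component's integrated area is conserved. Applied to a
#' `spectrum_model` this is exact; applied to a sampled `mrs_spectrum` it is
#' carried out by FFT-based circular convolution with a unit-sum discrete
#' Lorentzian kernel (accurate when signals are well inside the axis).
#'
#' @param x A `spectrum_model` or `mrs_spectrum`.
#' @param broadening_hz Additional Lorentzian width, Hz (>= 0).
#' @return Object of the same class as `x`.
#' @export
apply_line_broadening <- function(x, broadening_hz) {
  if (!is.numeric(broadening_hz) || length(broadening_hz) != 1L ||
      broadening_hz < 0) {
    stop("`broadening_hz` must be a single non-negative number", call. = FALSE)
  }
  UseMethod("apply_line_broadening")
}

#' @export
apply_line_broadening.spectrum_model <- function(x, broadening_hz) {
  widen <- function(cp) {
    new_fwhm <- cp$fwhm + broadening_hz
    cp$amplitude <- cp$amplitude * cp$fwhm / new_fwhm
    cp$fwhm <- new_fwhm
    cp
  }
  x$components <- lapply(x$components, widen)
  x$baseline_components <- lapply(x$baseline_components, widen)
  x
}

#' @export
apply_line_broadening.mrs_spectrum <- function(x, broadening_hz) {
  if (broadening_hz == 0) return(x)
  n <- x$axis$n_points
  df <- x$axis$spectral_width / n
  # unit-sum Lorentzian kernel centered at index 1 (circularly)
  k <- seq_len(n) - 1L
  k <- ifelse(k > n / 2, k - n, k) * df
  kern <- 1 / (1 + (2 * k / broadening_hz)^2)
  kern <- kern / sum(kern)
  conv <- function(y) Re(stats::fft(stats::fft(y) * stats::fft(kern),
                                    inverse = TRUE)) / n
  x$real <- conv(x$real)
  if (!is.null(x$imag)) x$imag <- conv(x$imag)
  x
}

#' Add white Gaussian noise to a spectrum
#'
#' I.i.d. zero-mean Gaussian noise is added to the real (and, if present,
#' imaginary) channel. The noise level may be given directly as `sigma` or
#' through a signal-to-noise ratio: `sigma = reference_height / snr`, where
#' the reference height is the peak height of a designated reference line
#' (the SNR convention used throughout the package).
#'
#' @param spectrum An `mrs_spectrum`.
#' @param sigma Noise standard deviation (>= 0). Exactly one of `sigma`, `snr`
#'   must be given.
#' @param snr Signal-to-noise ratio (> 0).
#' @param reference_height Reference peak height for the SNR convention;
#'   defaults to `max(spectrum$real)`. Must be positive when `snr` is used.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return The noisy `mrs_spectrum`, with `noise_sigma` recorded.
#' @export
add_noise <- function(spectrum, sigma = NULL, snr = NULL,
                      reference_height = NULL, seed = NULL) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  if (is.null(sigma) == is.null(snr)) {
    stop("give exactly one of `sigma` or `snr`", call. = FALSE)
  }
  if (!is.null(snr)) {
    if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
    if (is.null(reference_height)) reference_height <- max(spectrum$real)
    if (!is.finite(reference_height) || reference_height <= 0) {
      stop("no resolvable positive reference peak for the SNR convention",
           call. = FALSE)
    }
    sigma <- reference_height / snr
  }
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (sigma == 0) {
    spectrum$noise_sigma <- 0
    return(spectrum)
  }
  draw <- function() {
    spectrum$real <<- spectrum$real + stats::rnorm(length(spectrum$real), 0, sigma)
    if (!is.null(spectrum$imag)) {
      spectrum$imag <<- spectrum$imag + stats::rnorm(length(spectrum$imag), 0, sigma)
    }
  }
  local_seed(seed, draw())
  spectrum$noise_sigma <- sigma
  spectrum
}

# evaluate `code` under `set.seed(seed)` while preserving the caller's RNG
# state; with seed NULL the global stream is consumed as usual
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Plot a spectrum
#'
#' Simple absorption-mode display with the conventional reversed ppm axis.
#'
#' @param x An `mrs_spectrum`.
#' @param ppm Plot against ppm (default) or Hz offset.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mrs_spectrum <- function(x, ppm = TRUE, ...) {
  if (ppm) {
    f <- axis_ppm(x$axis)
    graphics::plot(f, x$real, type = "l", xlim = rev(range(f)),
                   xlab = "chemical shift (ppm)", ylab = "intensity", ...)
  } else {
    graphics::plot(axis_hz(x$axis), x$real, type = "l",
                   xlab = "frequency offset (Hz)", ylab = "intensity", ...)
  }
  invisible(x)
}
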