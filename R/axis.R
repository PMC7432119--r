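#' Construct a uniform spectral frequency axis
#'
#' Defines the frequency grid on which spectra are sampled. Internally all
#' arithmetic is in Hz, as offsets from the carrier (center) frequency; ppm
#' values are derived through the transmitter frequency. Following NMR
#' convention, chemical shift in ppm increases towards lower field
#' (right-to-left on a plotted spectrum); the stored Hz grid is ascending.
#'
#' @param n_points Number of sampled points (>= 2).
#' @param spectral_width Total width of the axis in Hz.
#' @param center_frequency Chemical shift of the carrier, in ppm.
#' @param transmitter_frequency Transmitter (Larmor) frequency in MHz, so that
#'   1 ppm corresponds to `transmitter_frequency` Hz.
#' @return An object of class `spectral_axis` with fields `n_points`,
#'   `spectral_width`, `center_frequency`, `transmitter_frequency`.
#' @examples
#' ax <- spectral_axis(2048, 2000, 4.7, 297.2)
#' diff(axis_hz(ax))[1]   # grid spacing: 2000/2048 Hz
#' @export
spectral_axis <- function(n_points, spectral_width, center_frequency = 0,
                          transmitter_frequency = 127.7) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2 ||
      n_points != round(n_points)) {
    stop("`n_points` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(spectral_width) || spectral_width <= 0) {
    stop("`spectral_width` must be a positive number of Hz", call. = FALSE)
  }
  if (!is.numeric(transmitter_frequency) || transmitter_frequency <= 0) {
    stop("`transmitter_frequency` must be positive (MHz)", call. = FALSE)
  }
  structure(
    list(
      n_points = as.integer(n_points),
      spectral_width = as.numeric(spectral_width),
      center_frequency = as.numeric(center_frequency),
      transmitter_frequency = as.numeric(transmitter_frequency)
    ),
    class = "spectral_axis"
  )
}

#' Frequency grid of an axis in Hz (offsets from the carrier)
#'
#' The grid is uniform with spacing `spectral_width / n_points`, centered on
#' zero offset: points run from `-spectral_width/2` upwards.
#'
#' @param axis A `spectral_axis`.
#' @return Numeric vector of length `axis$n_points`, strictly increasing.
#' @export
axis_hz <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  df <- axis$spectral_width / axis$n_points
  (seq_len(axis$n_points) - 1L - axis$n_points / 2) * df
}

#' Frequency grid of an axis in ppm
#' @param axis A `spectral_axis`.
#' @return Numeric vector of chemical shifts in ppm (ascending; plot reversed
#'   for the conventional ppm display).
#' @export
axis_ppm <- function(axis) {
  hz_to_ppm(axis_hz(axis), axis)
}

#' Convert between ppm and Hz offset on an axis
#'
#' `ppm_to_hz()` maps a chemical shift to its Hz offset from the carrier:
#' `hz = (ppm - center_frequency) * transmitter_frequency`. `hz_to_ppm()` is
#' the exact inverse.
#'
#' @param ppm,hz Numeric vectors.
#' @param axis A `spectral_axis` supplying carrier and transmitter frequency.
#' @return Numeric vector.
#' @export
ppm_to_hz <- function(ppm, axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  (ppm - axis$center_frequency) * axis$transmitter_frequency
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  hz / axis$transmitter_frequency + axis$center_frequency
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf(
    "<spectral_axis> %d points, %.6g Hz width (%.6g Hz spacing), carrier %.4g ppm at %.6g MHz\n",
    x$n_points, x$spectral_width, x$spectral_width / x$n_points,
    x$center_frequency, x$transmitter_frequency
  ))
  invisible(x)
}
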