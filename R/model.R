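#' Declare a Lorentzian spectral component
#'
#' A single absorption-mode Lorentzian line. `amplitude` is the peak height
#' at the line center (for zero phase); the half-height linewidth `fwhm` is
#' in Hz. The center may be declared in ppm or Hz offset; conversion happens
#' when the component is sampled on an axis.
#'
#' @param center Line center, in the unit given by `unit`.
#' @param fwhm Full width at half maximum, Hz (> 0).
#' @param amplitude Peak height at center (finite; default 1).
#' @param phase Zero-order phase in degrees (default 0 = pure absorption).
#' @param label Component label (unique within a model).
#' @param unit `"ppm"` or `"hz"`.
#' @return An object of class `lorentzian`.
#' @export
lorentzian <- function(center, fwhm, amplitude = 1, phase = 0,
                       label = NULL, unit = c("ppm", "hz")) {
  unit <- match.arg(unit)
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0) {
    stop("`fwhm` must be a single positive number of Hz", call. = FALSE)
  }
  if (!is.numeric(amplitude) || !is.finite(amplitude)) {
    stop("`amplitude` must be finite", call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), fwhm = as.numeric(fwhm),
         amplitude = as.numeric(amplitude), phase = as.numeric(phase),
         label = label, unit = unit),
    class = "lorentzian"
  )
}

component_center_hz <- function(comp, axis) {
  if (comp$unit == "hz") comp$center else ppm_to_hz(comp$center, axis)
}

#' Declare a spectrum model
#'
#' A declarative description of a spectrum: a list of narrow (metabolite)
#' Lorentzian components plus optional broad baseline components standing in
#' for macromolecule/lipid/residual-water signals. Baseline components are
#' flagged distinctly: they contribute to synthesis but are by default not
#' part of the fitted basis, which is how a macromolecular background that
#' the fit must soak up with a smooth baseline is emulated.
#'
#' @param components List of [lorentzian()] components (metabolite lines).
#' @param baseline_components Optional list of broad [lorentzian()] components.
#' @param name Model name.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(components, baseline_components = list(),
                           name = "model") {
  if (inherits(components, "lorentzian")) components <- list(components)
  if (inherits(baseline_components, "lorentzian")) {
    baseline_components <- list(baseline_components)
  }
  stopifnot(all(vapply(components, inherits, TRUE, "lorentzian")),
            all(vapply(baseline_components, inherits, TRUE, "lorentzian")))
  all_comps <- c(components, baseline_components)
  labels <- vapply(seq_along(all_comps), function(i) {
    if (is.null(all_comps[[i]]$label)) paste0("c", i) else all_comps[[i]]$label
  }, character(1))
  if (anyDuplicated(labels)) {
    stop("component labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(components)) components[[i]]$label <- labels[i]
  for (i in seq_along(baseline_components)) {
    baseline_components[[i]]$label <- labels[length(components) + i]
  }
  structure(
    list(components = components, baseline_components = baseline_components,
         name = name),
    class = "spectrum_model"
  )
}

model_labels <- function(model, which = c("metabolite", "baseline", "all")) {
  which <- match.arg(which)
  comps <- switch(which,
    metabolite = model$components,
    baseline = model$baseline_components,
    all = c(model$components, model$baseline_components))
  vapply(comps, `[[`, character(1), "label")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> '%s': %d component(s), %d baseline component(s)\n",
              x$name, length(x$components), length(x$baseline_components)))
  for (cp in c(x$components, x$baseline_components)) {
    cat(sprintf("  %-12s center %8.4g %s  fwhm %6.3g Hz  amp %8.4g  phase %g deg\n",
                cp$label, cp$center, cp$unit, cp$fwhm, cp$amplitude, cp$phase))
  }
  invisible(x)
}

#' Sample a unit-amplitude Lorentzian profile on an axis
#'
#' Absorption-mode Lorentzian, peak-height normalized: for zero phase the
#' profile is `1 / (1 + u^2)` with `u = 2 (f - center) / fwhm`, so it equals
#' 1 at the center and 0.5 at `center +/- fwhm/2`. A nonzero phase mixes in
#' the dispersion-mode partner `u / (1 + u^2)`:
#' `cos(phase) * absorption + sin(phase) * dispersion`.
#'
#' @param axis A `spectral_axis`.
#' @param center Line center, Hz offset from the carrier.
#' @param fwhm Half-height linewidth, Hz.
#' @param phase Zero-order phase, degrees.
#' @return Numeric vector of length `axis$n_points`. If the center lies
#'   outside the axis range a warning is raised and the (truncated) tail of
#'   the profile is returned.
#' @export
lorentzian_profile <- function(axis, center, fwhm, phase = 0) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  f <- axis_hz(axis)
  if (center < f[1] || center > f[length(f)]) {
    warning(sprintf("component center %.4g Hz lies outside the axis [%.4g, %.4g] Hz; profile truncated",
                    center, f[1], f[length(f)]), call. = FALSE)
  }
  u <- 2 * (f - center) / fwhm
  phi <- phase * pi / 180
  denom <- 1 + u^2
  cos(phi) / denom + sin(phi) * u / denom
}

# analytic partials of amplitude * profile w.r.t. (amplitude, center, fwhm,
# phase); used by the nonlinear fitter and the Fisher information matrix
lorentzian_partials <- function(f, amplitude, center, fwhm, phase = 0) {
  u <- 2 * (f - center) / fwhm
  phi <- phase * pi / 180
  d <- 1 + u^2
  absr <- 1 / d
  disp <- u / d
  shape <- cos(phi) * absr + sin(phi) * disp
  # d shape / d u
  dshape_du <- cos(phi) * (-2 * u / d^2) + sin(phi) * ((1 - u^2) / d^2)
  du_dc <- -2 / fwhm
  du_dw <- -u / fwhm
  list(
    value = amplitude * shape,
    amplitude = shape,
    center = amplitude * dshape_du * du_dc,
    fwhm = amplitude * dshape_du * du_dw,
    phase = amplitude * (pi / 180) * (-sin(phi) * absr + cos(phi) * disp)
  )
}

#' Build the basis matrix of a model on an axis
#'
#' One column per component: its unit-amplitude (peak-height normalized)
#' sampled profile. This is the design matrix of linear-combination spectral
#' fitting, where the fitted spectrum is `basis %*% amplitudes`.
#'
#' @param model A `spectrum_model` (or list of `lorentzian`s).
#' @param axis A `spectral_axis`.
#' @param include_baseline Include the broad baseline components as columns?
#'   Default `FALSE`: the fitted basis normally carries metabolite lines only.
#' @param normalization `"height"` (default; each column peaks at 1) or
#'   `"area"` (columns scaled to unit trapezoidal area).
#' @return An object of class `basis_matrix`: a numeric matrix with one column
#'   per component, `labels` attribute, and the axis attached.
#' @export
basis_matrix <- function(model, axis, include_baseline = FALSE,
                         normalization = c("height", "area")) {
  normalization <- match.arg(normalization)
  if (!inherits(model, "spectrum_model")) model <- spectrum_model(model)
  comps <- model$components
  if (include_baseline) comps <- c(comps, model$baseline_components)
  if (length(comps) == 0L) stop("model has no components", call. = FALSE)
  cols <- lapply(comps, function(cp) {
    lorentzian_profile(axis, component_center_hz(cp, axis), cp$fwhm, cp$phase)
  })
  B <- do.call(cbind, cols)
  labels <- vapply(comps, `[[`, character(1), "label")
  colnames(B) <- labels
  if (normalization == "area") {
    f <- axis_hz(axis)
    areas <- apply(B, 2, function(y) trapz(f, y))
    B <- sweep(B, 2, areas, "/")
  }
  structure(B, class = c("basis_matrix", class(B)), axis = axis,
            labels = labels, normalization = normalization)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
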