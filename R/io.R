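#' Read / write a spectrum as plain CSV
#'
#' The on-disk format is a UTF-8 CSV with header `frequency_hz,real` or
#' `frequency_hz,real,imag`, one row per point, frequencies ascending on a
#' uniform grid. Values are written at full double precision, so a
#' write–read round trip is lossless. On read, the grid is validated to be
#' uniform; a non-uniform grid is an error reporting the largest deviation.
#' The grid is recentered to the package's symmetric axis convention; any
#' constant offset is folded into the axis carrier frequency.
#'
#' @param path File path.
#' @param transmitter_frequency Transmitter frequency in MHz used to attach a
#'   ppm scale to the read spectrum.
#' @param center_frequency Carrier chemical shift, ppm, assigned to the zero
#'   of the file's frequency column.
#' @return `read_spectrum_csv()` returns an `mrs_spectrum`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, transmitter_frequency = 127.7,
                              center_frequency = 0) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!(identical(header, c("frequency_hz", "real")) ||
        identical(header, c("frequency_hz", "real", "imag")))) {
    stop("bad header: expected 'frequency_hz,real[,imag]', got '",
         lines[1], "'", call. = FALSE)
  }
  ncol_exp <- length(header)
  fields <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ncol_exp)) {
    bad <- which(nf != ncol_exp)[1]
    stop(sprintf("row %d has %d column(s), expected %d", bad + 1L,
                 nf[bad], ncol_exp), call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncol_exp, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in spectrum CSV", call. = FALSE)
  freq <- m[, 1]
  n <- length(freq)
  if (n < 2) stop("spectrum needs at least 2 points", call. = FALSE)
  df <- (freq[n] - freq[1]) / (n - 1)
  dev <- abs(diff(freq) - df)
  if (df <= 0 || max(dev) > 1e-6 * abs(df)) {
    stop(sprintf("non-uniform frequency grid: max spacing deviation %.3g Hz",
                 max(dev)), call. = FALSE)
  }
  sw <- df * n
  # fold any constant grid offset into the carrier frequency
  shift <- freq[1] + sw / 2 - df * 0   # expected first point is -sw/2
  axis <- spectral_axis(n, sw, center_frequency + shift / transmitter_frequency,
                        transmitter_frequency)
  mrs_spectrum(axis, m[, 2], if (ncol_exp == 3L) m[, 3])
}

#' @param spectrum An `mrs_spectrum`.
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  f <- axis_hz(spectrum$axis)
  cols <- list(frequency_hz = f, real = spectrum$real)
  if (!is.null(spectrum$imag)) cols$imag <- spectrum$imag
  header <- paste(names(cols), collapse = ",")
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = ","))
  atomic_write(path, function(tmp) {
    writeLines(c(header, body), tmp, useBytes = TRUE)
  })
  invisible(path)
}

# write-temp-then-rename so that readers never observe a partial file
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key '%s' in %s (allowed: %s)", extra[1], where,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

component_from_list <- function(cp, where) {
  check_keys(cp, c("label", "center_ppm", "center_hz", "fwhm_hz", "amplitude",
                   "phase_deg"), where)
  has_ppm <- !is.null(cp$center_ppm); has_hz <- !is.null(cp$center_hz)
  if (has_ppm == has_hz) {
    stop("each component needs exactly one of center_ppm / center_hz (",
         where, ")", call. = FALSE)
  }
  if (is.null(cp$fwhm_hz)) stop("component missing fwhm_hz (", where, ")",
                                call. = FALSE)
  lorentzian(center = if (has_ppm) cp$center_ppm else cp$center_hz,
             fwhm = cp$fwhm_hz,
             amplitude = if (is.null(cp$amplitude)) 1 else cp$amplitude,
             phase = if (is.null(cp$phase_deg)) 0 else cp$phase_deg,
             label = cp$label,
             unit = if (has_ppm) "ppm" else "hz")
}

#' Read / write a spectrum model as JSON
#'
#' Document layout:
#' `{"name": ..., "components": [{"label", "center_ppm"|"center_hz",
#' "fwhm_hz", "amplitude", "phase_deg"}], "baseline_components": [...]}`.
#' Unknown keys are rejected with the offending key named.
#'
#' @param path File path.
#' @return `read_spectrum_model()` returns a `spectrum_model`.
#' @export
read_spectrum_model <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  model_from_list(doc, path)
}

model_from_list <- function(doc, where = "model") {
  check_keys(doc, c("name", "components", "baseline_components"), where)
  if (is.null(doc$components) || length(doc$components) == 0L) {
    stop("model has no components (", where, ")", call. = FALSE)
  }
  comps <- lapply(seq_along(doc$components), function(i) {
    component_from_list(doc$components[[i]],
                        sprintf("%s$components[[%d]]", where, i))
  })
  bl <- lapply(seq_along(doc$baseline_components), function(i) {
    component_from_list(doc$baseline_components[[i]],
                        sprintf("%s$baseline_components[[%d]]", where, i))
  })
  spectrum_model(comps, bl,
                 name = if (is.null(doc$name)) "model" else doc$name)
}

model_to_list <- function(model) {
  comp_list <- function(cp) {
    out <- list(label = cp$label, fwhm_hz = cp$fwhm, amplitude = cp$amplitude,
                phase_deg = cp$phase)
    if (cp$unit == "ppm") out$center_ppm <- cp$center else out$center_hz <- cp$center
    out
  }
  list(name = model$name,
       components = lapply(model$components, comp_list),
       baseline_components = lapply(model$baseline_components, comp_list))
}

#' @param model A `spectrum_model`.
#' @rdname read_spectrum_model
#' @export
write_spectrum_model <- function(model, path) {
  stopifnot(inherits(model, "spectrum_model"))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(model_to_list(model), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  invisible(path)
}

#' Serialize a fit result to JSON (and its baseline curve to CSV)
#'
#' Writes labels, estimates, amplitude standard deviations, the full free
#' parameter covariance in row-major order, and convergence metadata. When a
#' baseline was fitted its sampled curve is written as CSV next to the JSON.
#'
#' @param fit A `fit_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  sds <- amplitude_sds(fit)
  out <- list(
    mode = fit$mode,
    labels = fit$labels,
    amplitudes = unname(fit$amplitudes),
    centers_hz = unname(fit$centers),
    fwhms_hz = unname(fit$fwhms),
    phases_deg = unname(fit$phases),
    amplitude_sd = if (is.null(sds)) NULL else unname(sds),
    sigma_hat_sq = fit$sigma_hat_sq,
    covariance = list(parameters = rownames(fit$covariance),
                      row_major = as.vector(t(fit$covariance))),
    converged = fit$converged,
    n_iterations = fit$niter,
    effective_df = fit$edf
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(path)
}

#' Serialize a covariance report
#'
#' JSON with covariance and correlation (row-major); the correlation matrix
#' additionally as a labelled CSV when `csv_path` is given.
#'
#' @param report A `covariance_report`.
#' @param path Output JSON path.
#' @param csv_path Optional CSV path for the correlation matrix.
#' @return `path`, invisibly.
#' @export
write_covariance_report <- function(report, path, csv_path = NULL) {
  stopifnot(inherits(report, "covariance_report"))
  out <- list(labels = report$labels, sigma_sq = report$sigma_sq,
              covariance_row_major = as.vector(t(report$covariance)),
              correlation_row_major = as.vector(t(report$correlation)),
              crlb = unname(report$crlb))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  if (!is.null(csv_path)) {
    df <- as.data.frame(report$correlation)
    df <- cbind(label = report$labels, df)
    atomic_write(csv_path, function(tmp) {
      utils::write.csv(df, tmp, row.names = FALSE)
    })
  }
  invisible(path)
}

write_table_csv <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(format(df, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     tmp, row.names = FALSE, quote = FALSE)
  })
  invisible(path)
}
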