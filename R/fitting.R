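#' Fitting specification
#'
#' Declares which parameters of each Lorentzian line are free, the parameter
#' bounds that preserve peak identity, an optional penalized-spline baseline,
#' and the fit window.
#'
#' Modes:
#' * `"amplitudes_only"` — linear fit of amplitudes against the fixed-shape
#'   basis (the classic linear-combination model `spec = basis %*% conc`);
#' * `"amp_freq"` — amplitude and center frequency free per peak;
#' * `"amp_freq_width"` — amplitude, center and linewidth free;
#' * `"amp_freq_width_phase"` — additionally a per-peak zero-order phase.
#'
#' Frequency bounds prevent label switching between overlapped peaks: each
#' fitted center is confined to a window around its initial value. The
#' default bound is the smaller of half the linewidth and half the smallest
#' initial separation between peaks.
#'
#' @param mode Fit mode; see Details.
#' @param frequency_bound_hz Half-width of the per-peak center window, Hz
#'   (`NULL` = automatic default above).
#' @param width_bound_factor Length-2 multiplicative bounds on each linewidth
#'   relative to its initial value.
#' @param phase_bound_deg Symmetric bound on per-peak phase, degrees.
#' @param baseline Optional [baseline_spec()].
#' @param window_hz Optional length-2 fit window in Hz offsets (`NULL` = full
#'   axis).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(mode = c("amplitudes_only", "amp_freq", "amp_freq_width",
                              "amp_freq_width_phase"),
                     frequency_bound_hz = NULL,
                     width_bound_factor = c(0.25, 4),
                     phase_bound_deg = 90,
                     baseline = NULL,
                     window_hz = NULL) {
  mode <- match.arg(mode)
  if (!is.null(baseline) && !inherits(baseline, "baseline_spec")) {
    stop("`baseline` must be a baseline_spec()", call. = FALSE)
  }
  if (!is.null(window_hz) &&
      (length(window_hz) != 2L || diff(window_hz) <= 0)) {
    stop("`window_hz` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  stopifnot(length(width_bound_factor) == 2L,
            width_bound_factor[1] > 0,
            width_bound_factor[2] > width_bound_factor[1])
  structure(list(mode = mode, frequency_bound_hz = frequency_bound_hz,
                 width_bound_factor = width_bound_factor,
                 phase_bound_deg = phase_bound_deg,
                 baseline = baseline, window_hz = window_hz),
            class = "fit_spec")
}

#' Penalized-spline baseline specification
#'
#' A B-spline baseline on an equidistant knot grid with a second-difference
#' roughness penalty on the coefficients. Small `knot_spacing` and small
#' `penalty_weight` give a loose (wiggly) baseline; a large penalty forces it
#' towards a straight line.
#'
#' @param knot_spacing Knot spacing in Hz (> 0).
#' @param penalty_weight Non-negative roughness penalty weight.
#' @param spline_order B-spline order (4 = cubic, the default).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(knot_spacing, penalty_weight = 0, spline_order = 4) {
  if (!is.numeric(knot_spacing) || knot_spacing <= 0) {
    stop("`knot_spacing` must be positive (Hz)", call. = FALSE)
  }
  if (!is.numeric(penalty_weight) || penalty_weight < 0) {
    stop("`penalty_weight` must be non-negative", call. = FALSE)
  }
  structure(list(knot_spacing = knot_spacing, penalty_weight = penalty_weight,
                 spline_order = as.integer(spline_order)),
            class = "baseline_spec")
}

window_mask <- function(axis, window_hz) {
  f <- axis_hz(axis)
  if (is.null(window_hz)) rep(TRUE, length(f))
  else f >= window_hz[1] & f <= window_hz[2]
}

baseline_design <- function(bl, f_window) {
  lo <- min(f_window); hi <- max(f_window)
  n_inner <- floor((hi - lo) / bl$knot_spacing) + 1L
  if (n_inner < 4L) {
    stop("baseline knots must span the fit window: need >= 4 knots, got ",
         n_inner, call. = FALSE)
  }
  ord <- bl$spline_order
  # extend ord-1 knots past each end so the basis keeps partition of unity
  # (and every edge column at least one full knot interval) on the window
  n_int <- ceiling((hi - lo) / bl$knot_spacing)
  kn <- lo + bl$knot_spacing * seq(-(ord - 1), n_int + ord - 1)
  S <- splines::splineDesign(kn, f_window, ord = ord, outer.ok = TRUE)
  D <- diff(diag(ncol(S)), differences = 2)
  list(S = S, D = D, knots = kn)
}

new_fit_result <- function(labels, amplitudes, centers, fwhms, phases,
                           sigma_hat_sq, covariance, converged, fitted,
                           residual, window, mode, baseline_curve = NULL,
                           baseline_coefs = NULL, edf = NA_real_,
                           niter = NA_integer_, message = NULL) {
  structure(list(labels = labels,
                 amplitudes = stats::setNames(amplitudes, labels),
                 centers = stats::setNames(centers, labels),
                 fwhms = stats::setNames(fwhms, labels),
                 phases = stats::setNames(phases, labels),
                 sigma_hat_sq = sigma_hat_sq, covariance = covariance,
                 converged = converged, fitted = fitted, residual = residual,
                 window = window, mode = mode,
                 baseline_curve = baseline_curve,
                 baseline_coefs = baseline_coefs, edf = edf, niter = niter,
                 message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mode '%s'%s, sigma_hat^2 = %.4g, %s\n",
              x$mode,
              if (is.null(x$baseline_curve)) "" else " + spline baseline",
              x$sigma_hat_sq,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(amplitude = x$amplitudes, center_hz = x$centers,
                    fwhm_hz = x$fwhms, phase_deg = x$phases)
  sds <- amplitude_sds(x)
  if (!is.null(sds)) tab$amp_sd <- sds
  print(tab, digits = 5)
  invisible(x)
}

amplitude_sds <- function(fit) {
  nm <- paste0("amp.", fit$labels)
  if (is.null(fit$covariance) || !all(nm %in% rownames(fit$covariance))) {
    return(NULL)
  }
  sqrt(diag(fit$covariance)[nm])
}

#' Extract the amplitude covariance block of a fit
#'
#' @param fit A `fit_result`.
#' @return Covariance matrix over component amplitudes, labelled.
#' @export
amplitude_covariance <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  nm <- paste0("amp.", fit$labels)
  V <- fit$covariance[nm, nm, drop = FALSE]
  dimnames(V) <- list(fit$labels, fit$labels)
  V
}

#' Linear (amplitudes-only) least-squares fit against a basis
#'
#' Solves `spec = basis %*% conc` in the least-squares sense over the fit
#' window. The noise variance is estimated from the residual as
#' `RSS / (n - p)` and the amplitude covariance is
#' `sigma_hat_sq * solve(crossprod(basis))` — the standard linear-model
#' covariance through the Gram matrix of the basis columns.
#'
#' @param spectrum An `mrs_spectrum`.
#' @param basis A `basis_matrix` on the same axis (or a plain numeric matrix
#'   with one column per component).
#' @param window_hz Optional fit window `c(lo, hi)` in Hz offsets.
#' @return A `fit_result` with linear-mode amplitudes; centers/linewidths are
#'   carried over from the basis when available.
#' @export
fit_linear <- function(spectrum, basis, window_hz = NULL) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  B <- unclass(basis)
  labels <- colnames(B)
  if (is.null(labels)) labels <- paste0("c", seq_len(ncol(B)))
  w <- window_mask(spectrum$axis, window_hz)
  Bw <- B[w, , drop = FALSE]
  y <- spectrum$real[w]
  qrB <- qr(Bw)
  p <- ncol(Bw)
  if (qrB$rank < p) {
    stop(singular_design_message(Bw, labels), call. = FALSE)
  }
  amps <- qr.coef(qrB, y)
  fitted <- drop(Bw %*% amps)
  res <- y - fitted
  n <- length(y)
  sigma2 <- sum(res^2) / (n - p)
  G <- crossprod(Bw)
  V <- sigma2 * chol2inv(chol(G))
  dimnames(V) <- list(paste0("amp.", labels), paste0("amp.", labels))
  new_fit_result(labels, amps, rep(NA_real_, p), rep(NA_real_, p),
                 rep(0, p), sigma2, V, TRUE, fitted, res, w,
                 "amplitudes_only", edf = p)
}

singular_design_message <- function(B, labels) {
  cc <- suppressWarnings(stats::cor(B))
  diag(cc) <- 0
  cc[!is.finite(cc)] <- 1  # constant/zero columns are perfectly collinear
  idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
  sprintf("singular design: basis columns are collinear (worst pair '%s' and '%s', |cor| = %.6g)",
          labels[idx[1]], labels[idx[2]], max(abs(cc)))
}

# pack the free parameters of `model` under `spec` into a vector with bounds
pack_parameters <- function(model, axis, spec) {
  comps <- model$components
  k <- length(comps)
  centers <- vapply(comps, component_center_hz, numeric(1), axis = axis)
  fwhms <- vapply(comps, `[[`, numeric(1), "fwhm")
  amps <- vapply(comps, `[[`, numeric(1), "amplitude")
  phases <- vapply(comps, `[[`, numeric(1), "phase")
  labels <- model_labels(model)

  fb <- spec$frequency_bound_hz
  if (is.null(fb)) {
    sep <- if (k > 1) min(diff(sort(centers))) else Inf
    fb <- pmin(fwhms / 2, sep / 2)
  } else {
    fb <- rep_len(fb, k)
  }

  free_freq <- spec$mode %in% c("amp_freq", "amp_freq_width", "amp_freq_width_phase")
  free_width <- spec$mode %in% c("amp_freq_width", "amp_freq_width_phase")
  free_phase <- spec$mode == "amp_freq_width_phase"

  par <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  names_ <- character(0)
  add <- function(value, lo, hi, nm) {
    par <<- c(par, value); lower <<- c(lower, lo); upper <<- c(upper, hi)
    names_ <<- c(names_, nm)
  }
  for (j in seq_len(k)) {
    add(amps[j], -Inf, Inf, paste0("amp.", labels[j]))
    if (free_freq) {
      add(centers[j], centers[j] - fb[j], centers[j] + fb[j],
          paste0("freq.", labels[j]))
    }
    if (free_width) {
      add(fwhms[j], fwhms[j] * spec$width_bound_factor[1],
          fwhms[j] * spec$width_bound_factor[2], paste0("width.", labels[j]))
    }
    if (free_phase) {
      add(phases[j], phases[j] - spec$phase_bound_deg,
          phases[j] + spec$phase_bound_deg, paste0("phase.", labels[j]))
    }
  }
  list(par = stats::setNames(par, names_), lower = lower, upper = upper,
       labels = labels, k = k,
       init = list(amps = amps, centers = centers, fwhms = fwhms,
                   phases = phases),
       free = list(freq = free_freq, width = free_width, phase = free_phase))
}

unpack_parameters <- function(par, pk) {
  k <- pk$k
  amps <- pk$init$amps; centers <- pk$init$centers
  fwhms <- pk$init$fwhms; phases <- pk$init$phases
  i <- 1L
  for (j in seq_len(k)) {
    amps[j] <- par[i]; i <- i + 1L
    if (pk$free$freq) { centers[j] <- par[i]; i <- i + 1L }
    if (pk$free$width) { fwhms[j] <- par[i]; i <- i + 1L }
    if (pk$free$phase) { phases[j] <- par[i]; i <- i + 1L }
  }
  list(amps = amps, centers = centers, fwhms = fwhms, phases = phases)
}

# model value and Jacobian (columns in packed order) on frequency grid fw
peak_model_eval <- function(par, pk, fw, jacobian = FALSE) {
  u <- unpack_parameters(par, pk)
  y <- numeric(length(fw))
  J <- if (jacobian) matrix(0, length(fw), length(par)) else NULL
  i <- 1L
  for (j in seq_len(pk$k)) {
    pr <- lorentzian_partials(fw, u$amps[j], u$centers[j], u$fwhms[j],
                              u$phases[j])
    y <- y + pr$value
    if (jacobian) {
      J[, i] <- pr$amplitude
      ii <- i + 1L
      if (pk$free$freq) { J[, ii] <- pr$center; ii <- ii + 1L }
      if (pk$free$width) { J[, ii] <- pr$fwhm; ii <- ii + 1L }
      if (pk$free$phase) { J[, ii] <- pr$phase; ii <- ii + 1L }
    }
    i <- i + 1L + pk$free$freq + pk$free$width + pk$free$phase
  }
  list(y = y, J = J, u = u)
}

#' Nonlinear bounded least-squares fit of Lorentzian components
#'
#' Fits the metabolite components of `model` to the real channel of
#' `spectrum` by Levenberg–Marquardt least squares with box bounds
#' ([minpack.lm::nls.lm]), with the free parameters chosen by the
#' [fit_spec()] mode. The fit is truth-initialized from `model`; per-peak
#' frequency bounds keep each estimate attached to its own line so that
#' labels cannot switch between overlapped peaks. With
#' `mode = "amplitudes_only"` and no baseline the problem is linear and is
#' solved exactly via [fit_linear()].
#'
#' When `spec$baseline` is set, B-spline baseline coefficients are estimated
#' jointly, with the second-difference roughness penalty appended to the
#' residual (penalized least squares). The parameter covariance is then the
#' ridge-type sandwich `sigma^2 A^-1 (X'X) A^-1` with
#' `A = X'X + lambda * P`, which reduces to `sigma^2 (X'X)^-1` for zero
#' penalty; `sigma^2` uses the effective residual degrees of freedom
#' `n - tr(A^-1 X'X)`.
#'
#' @param spectrum An `mrs_spectrum`.
#' @param model A `spectrum_model` supplying starting values (its baseline
#'   components are *not* part of the fitted model).
#' @param spec A [fit_spec()].
#' @return A `fit_result`. Non-convergence is flagged (`converged = FALSE`),
#'   not raised.
#' @export
fit_nonlinear <- function(spectrum, model, spec = fit_spec()) {
  stopifnot(inherits(spectrum, "mrs_spectrum"),
            inherits(model, "spectrum_model"),
            inherits(spec, "fit_spec"))
  if (spec$mode == "amplitudes_only" && is.null(spec$baseline)) {
    B <- basis_matrix(model, spectrum$axis)
    fit <- fit_linear(spectrum, B, spec$window_hz)
    centers <- vapply(model$components, component_center_hz, numeric(1),
                      axis = spectrum$axis)
    fit$centers[] <- centers
    fit$fwhms[] <- vapply(model$components, `[[`, numeric(1), "fwhm")
    return(fit)
  }

  w <- window_mask(spectrum$axis, spec$window_hz)
  fw <- axis_hz(spectrum$axis)[w]
  y <- spectrum$real[w]
  pk <- pack_parameters(model, spectrum$axis, spec)

  bl <- spec$baseline
  n_bl <- 0L
  S <- NULL; D <- NULL; lam <- 0
  if (!is.null(bl)) {
    bd <- baseline_design(bl, fw)
    S <- bd$S; D <- bd$D; lam <- bl$penalty_weight
    n_bl <- ncol(S)
  }
  n_par <- length(pk$par) + n_bl
  n_pen <- if (!is.null(bl) && lam > 0) nrow(D) else 0L
  sqlam <- sqrt(lam)

  fn <- function(p) {
    pe <- peak_model_eval(p[seq_along(pk$par)], pk, fw)
    r <- y - pe$y
    if (n_bl > 0L) {
      cb <- p[-seq_along(pk$par)]
      r <- r - drop(S %*% cb)
      if (n_pen > 0L) r <- c(r, sqlam * drop(D %*% cb))
    }
    r
  }
  jac <- function(p) {
    pe <- peak_model_eval(p[seq_along(pk$par)], pk, fw, jacobian = TRUE)
    J <- -pe$J
    if (n_bl > 0L) {
      J <- cbind(J, -S)
      if (n_pen > 0L) {
        Jp <- cbind(matrix(0, n_pen, length(pk$par)), sqlam * D)
        J <- rbind(J, Jp)
      }
    }
    J
  }
  p0 <- c(pk$par, rep(0, n_bl))
  lower <- c(pk$lower, rep(-Inf, n_bl))
  upper <- c(pk$upper, rep(Inf, n_bl))

  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                    ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = fn, jac = jac, control = ctl)
  converged <- fit$info %in% 1:4  # 1-3: ftol/ptol; 4: gradient criterion
  p_hat <- fit$par
  pe <- peak_model_eval(p_hat[seq_along(pk$par)], pk, fw, jacobian = TRUE)
  X <- pe$J
  bl_curve <- NULL; bl_coefs <- NULL
  fitted <- pe$y
  if (n_bl > 0L) {
    bl_coefs <- p_hat[-seq_along(pk$par)]
    bl_curve <- drop(S %*% bl_coefs)
    fitted <- fitted + bl_curve
    X <- cbind(X, S)
  }
  res <- y - fitted
  n <- length(y)
  XtX <- crossprod(X)
  A <- XtX
  if (n_bl > 0L && lam > 0) {
    P <- matrix(0, n_par, n_par)
    idx <- seq_len(n_bl) + length(pk$par)
    P[idx, idx] <- crossprod(D)
    A <- A + lam * P
  }
  sc <- sqrt(diag(A))
  sc[sc == 0] <- 1
  Ainv <- tryCatch(t(solve(A / (sc %o% sc)) / sc) / sc,
                   error = function(e) NULL)
  if (is.null(Ainv)) {
    edf <- n_par
    sigma2 <- sum(res^2) / max(n - n_par, 1)
    V <- matrix(NA_real_, n_par, n_par)
  } else {
    H <- Ainv %*% XtX
    edf <- sum(diag(H))
    sigma2 <- sum(res^2) / max(n - edf, 1)
    V <- sigma2 * (H %*% Ainv)
    V <- (V + t(V)) / 2
  }
  par_names <- c(names(pk$par), if (n_bl > 0L) paste0("bl.", seq_len(n_bl)))
  dimnames(V) <- list(par_names, par_names)

  new_fit_result(pk$labels, pe$u$amps, pe$u$centers, pe$u$fwhms, pe$u$phases,
                 sigma2, V, converged, fitted, res, w, spec$mode,
                 baseline_curve = bl_curve, baseline_coefs = bl_coefs,
                 edf = edf, niter = fit$niter, message = fit$message)
}

#' Joint peak + penalized-spline-baseline fit
#'
#' Convenience wrapper around [fit_nonlinear()] that requires a baseline to
#' be part of the fitting specification.
#'
#' @inheritParams fit_nonlinear
#' @return A `fit_result` including `baseline_curve`.
#' @export
fit_with_baseline <- function(spectrum, model, spec) {
  if (is.null(spec$baseline)) {
    stop("`spec$baseline` must be a baseline_spec(); use fit_nonlinear() for baseline-free fits",
         call. = FALSE)
  }
  fit_nonlinear(spectrum, model, spec)
}

#' Estimate the noise standard deviation from a signal-free window
#'
#' Returns the standard deviation of the real channel inside the window,
#' after an optional linear detrend. When a model is supplied, the window is
#' checked to be signal-free: no component center may lie within five
#' linewidths of the window.
#'
#' @param spectrum An `mrs_spectrum`.
#' @param window_hz Length-2 Hz window, containing at least 32 points.
#' @param model Optional `spectrum_model` used to verify the window is
#'   signal-free.
#' @param detrend Remove a linear trend first? Default `TRUE`.
#' @return Estimated noise SD (scalar).
#' @export
estimate_noise_sigma <- function(spectrum, window_hz, model = NULL,
                                 detrend = TRUE) {
  stopifnot(inherits(spectrum, "mrs_spectrum"), length(window_hz) == 2L)
  w <- window_mask(spectrum$axis, window_hz)
  if (sum(w) < 32L) {
    stop("noise window must contain at least 32 points (has ", sum(w), ")",
         call. = FALSE)
  }
  if (!is.null(model)) {
    comps <- c(model$components, model$baseline_components)
    bad <- vapply(comps, function(cp) {
      ctr <- component_center_hz(cp, spectrum$axis)
      ctr >= window_hz[1] - 5 * cp$fwhm && ctr <= window_hz[2] + 5 * cp$fwhm
    }, logical(1))
    if (any(bad)) {
      stop("noise window overlaps model component(s): ",
           paste(vapply(comps[bad], `[[`, character(1), "label"),
                 collapse = ", "), call. = FALSE)
    }
  }
  y <- spectrum$real[w]
  if (detrend) {
    x <- axis_hz(spectrum$axis)[w]
    y <- stats::lm.fit(cbind(1, x), y)$residuals
  }
  stats::sd(y)
}
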