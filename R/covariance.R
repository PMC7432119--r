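#' Analytic covariance of linear amplitude estimates
#'
#' For the linear-combination model `spec = basis %*% conc + noise` with
#' white noise of variance `sigma_sq`, the least-squares amplitude estimates
#' have covariance
#' \deqn{COV(conc) = \sigma^2 (B^\dagger B)^{-1}}
#' the inverse (Hermitian) Gram matrix of the basis columns scaled by the
#' noise variance. Overlapping columns make the Gram matrix non-diagonal and
#' hence induce purely statistical correlations among the estimates. The
#' correlation matrix uses the standard normalization
#' `rho_ij = COV_ij / sqrt(COV_ii COV_jj)` and is well defined even for
#' `sigma_sq = 0` (it is computed from the unscaled inverse Gram matrix).
#'
#' @param basis A `basis_matrix` or numeric (possibly complex) matrix, one
#'   column per component.
#' @param sigma_sq Noise variance (>= 0).
#' @return An object of class `covariance_report`: `covariance`,
#'   `correlation`, `crlb` (per-amplitude SD), `labels`, `sigma_sq`.
#' @export
analytic_covariance <- function(basis, sigma_sq) {
  if (!is.numeric(sigma_sq) || length(sigma_sq) != 1L || sigma_sq < 0) {
    stop("`sigma_sq` must be a single non-negative number", call. = FALSE)
  }
  B <- unclass(basis)
  labels <- colnames(B)
  if (is.null(labels)) labels <- paste0("c", seq_len(ncol(B)))
  G <- if (is.complex(B)) Re(Conj(t(B)) %*% B) else crossprod(B)
  kap <- kappa(G, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    stop(sprintf("%s; Gram matrix condition number %.3g exceeds 1e10",
                 singular_design_message(Re(B), labels), kap), call. = FALSE)
  }
  Ginv <- chol2inv(chol(G))
  V <- sigma_sq * Ginv
  R <- stats::cov2cor(Ginv)   # scale-free: identical for any sigma_sq > 0
  dimnames(V) <- dimnames(R) <- list(labels, labels)
  covariance_report(V, R, labels, sigma_sq)
}

covariance_report <- function(covariance, correlation, labels, sigma_sq) {
  structure(list(covariance = covariance, correlation = correlation,
                 crlb = stats::setNames(sqrt(pmax(diag(covariance), 0)), labels),
                 labels = labels, sigma_sq = sigma_sq),
            class = "covariance_report")
}

#' @export
print.covariance_report <- function(x, ...) {
  cat(sprintf("<covariance_report> %d parameter(s), sigma^2 = %.4g\n",
              length(x$labels), x$sigma_sq))
  cat("correlation:\n")
  print(round(x$correlation, 4))
  cat("CRLB (SD):\n")
  print(signif(x$crlb, 5))
  invisible(x)
}

#' Closed-form amplitude correlation of two overlapping Lorentzian singlets
#'
#' Continuum limit of the amplitudes-only estimate correlation for two
#' equal-width absorption Lorentzians separated by `delta` Hz:
#' \deqn{\rho(\Delta) = -\frac{fwhm^2}{\Delta^2 + fwhm^2}}
#' It equals -1 at zero separation (identical columns) and tends to 0 as the
#' separation grows (orthogonal columns). The magnitude decreases
#' monotonically with separation — the analytic statement that statistical
#' correlation grows with spectral overlap.
#'
#' @param fwhm Common half-height linewidth, Hz (> 0).
#' @param delta Center separation, Hz (>= 0). Vectorized.
#' @return Correlation value(s) in `[-1, 0]`.
#' @export
closed_form_pair_correlation <- function(fwhm, delta) {
  if (any(fwhm <= 0)) stop("`fwhm` must be positive", call. = FALSE)
  if (any(delta < 0)) stop("`delta` must be non-negative", call. = FALSE)
  -fwhm^2 / (delta^2 + fwhm^2)
}

#' Fisher-information covariance for a nonlinear fit parameterization
#'
#' Evaluates the Gaussian Fisher information of the model under the free
#' parameters of `spec` (and, when a baseline is part of the specification,
#' the spline baseline columns) at the model's true parameter values, and
#' returns `sigma_sq` times its inverse — the Cramér–Rao covariance of the
#' parameterization. With `mode = "amplitudes_only"` and no baseline this is
#' identical to [analytic_covariance()].
#'
#' @param model A `spectrum_model` (truth; baseline components are not part
#'   of the parameterization).
#' @param axis A `spectral_axis`.
#' @param sigma_sq Noise variance (>= 0).
#' @param spec A [fit_spec()].
#' @return A `covariance_report` over all free parameters, with the
#'   amplitude sub-block attached as `amplitude_covariance` /
#'   `amplitude_correlation`.
#' @export
fisher_covariance <- function(model, axis, sigma_sq, spec = fit_spec()) {
  stopifnot(inherits(model, "spectrum_model"), inherits(axis, "spectral_axis"))
  w <- window_mask(axis, spec$window_hz)
  fw <- axis_hz(axis)[w]
  pk <- pack_parameters(model, axis, spec)
  J <- peak_model_eval(pk$par, pk, fw, jacobian = TRUE)$J
  par_names <- names(pk$par)
  if (!is.null(spec$baseline)) {
    bd <- baseline_design(spec$baseline, fw)
    J <- cbind(J, bd$S)
    par_names <- c(par_names, paste0("bl.", seq_len(ncol(bd$S))))
  }
  Iinfo <- crossprod(J)
  # equilibrate before inversion: mixed parameter scales (amplitudes vs Hz)
  # make the raw information matrix artificially ill-conditioned
  sc <- sqrt(diag(Iinfo))
  sc[sc == 0] <- 1
  Iinv <- tryCatch(
    t(chol2inv(chol(Iinfo / (sc %o% sc))) / sc) / sc,
    error = function(e) NULL)
  if (is.null(Iinv)) {
    cc <- suppressWarnings(stats::cor(J)); diag(cc) <- 0
    cc[!is.finite(cc)] <- 1
    idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop(sprintf("singular information matrix: parameters '%s' and '%s' are not jointly identifiable",
                 par_names[idx[1]], par_names[idx[2]]), call. = FALSE)
  }
  V <- sigma_sq * Iinv
  R <- stats::cov2cor(Iinv)
  dimnames(V) <- dimnames(R) <- list(par_names, par_names)
  rep_ <- covariance_report(V, R, par_names, sigma_sq)
  amp_idx <- paste0("amp.", pk$labels)
  rep_$amplitude_covariance <- V[amp_idx, amp_idx, drop = FALSE]
  rep_$amplitude_correlation <- R[amp_idx, amp_idx, drop = FALSE]
  dimnames(rep_$amplitude_covariance) <- dimnames(rep_$amplitude_correlation) <-
    list(pk$labels, pk$labels)
  rep_
}
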