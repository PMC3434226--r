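## Baseline subtraction and cell masking.
##
## The baseline model is iterative modified-polynomial fitting ("modpoly"):
## fit a polynomial, clip the working spectrum to min(spectrum, fit),
## refit, until the fitted baseline stops changing. This is the standard
## transparent choice for broad fluorescence backgrounds under sharp Raman
## lines: peaks are progressively excluded from the fit because clipping
## removes everything above the current polynomial.

#' Baseline-correction configuration
#'
#' @param order Polynomial order (default 5).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   fitted baseline between iterations, as a fraction of the spectrum
#'   maximum (default 1e-6).
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(order = 5, max_iter = 100, tol = 1e-6) {
  if (order < 1 || max_iter < 1 || tol <= 0)
    rr_error("need order >= 1, max_iter >= 1, tol > 0", "rr_config_error")
  structure(list(order = order, max_iter = max_iter, tol = tol),
            class = "baseline_config")
}

## Orthogonal polynomial design for a given axis; shared across all pixels
## of a map. Returns the n x (order+1) basis and its pseudo-inverse.
poly_basis <- function(axis, order) {
  x <- as.numeric(axis)
  x <- (x - mean(x)) / (diff(range(x)) / 2)  # scale to [-1, 1] for conditioning
  X <- cbind(1, stats::poly(x, degree = order, raw = FALSE))
  qr_ <- qr(X)
  list(X = X, P = qr.coef(qr_, diag(nrow(X))))  # P: coef = P %*% y
}

## Vectorised noise-aware modified-polynomial fit over the columns of Y
## (n_wavenumber x n_spectra). Clipping happens at fit + residual SD, not
## at the fit itself, so on noisy spectra the baseline settles at the
## centre of the noise band instead of sinking to its lower envelope
## (which would bias every band intensity upward). On noiseless input the
## residual SD shrinks toward zero and the scheme reduces to plain
## min-clipping. Returns list(baseline, iterations, converged).
modpoly_fit <- function(Y, basis, max_iter, tol) {
  W <- Y
  fit_final <- matrix(0, nrow(Y), ncol(Y))
  scale_ <- pmax(apply(abs(Y), 2, max), .Machine$double.eps)
  converged <- rep(FALSE, ncol(Y))
  ## converged columns are frozen so a spectrum gets the same baseline
  ## whether it is fitted alone or as part of a map
  active <- seq_len(ncol(Y))
  fit_old <- matrix(0, nrow(Y), length(active))
  it <- 0L
  for (it in seq_len(max_iter)) {
    coef_ <- basis$P %*% W[, active, drop = FALSE]
    fit <- basis$X %*% coef_
    dmax <- apply(abs(fit - fit_old), 2, max) / scale_[active]
    done <- dmax < tol
    fit_final[, active] <- fit
    converged[active[done]] <- TRUE
    if (all(done)) break
    keep <- which(!done)
    dev <- sqrt(colMeans((W[, active[keep], drop = FALSE] -
                            fit[, keep, drop = FALSE])^2))
    W[, active[keep]] <- pmin(W[, active[keep], drop = FALSE],
                              sweep(fit[, keep, drop = FALSE], 2, dev, "+"))
    active <- active[keep]
    fit_old <- fit[, keep, drop = FALSE]
  }
  list(baseline = fit_final, iterations = it, converged = converged)
}

#' Subtract a fluorescence-like baseline from a spectrum
#'
#' Iterative modified-polynomial fitting. The returned decomposition is
#' exact: `corrected + baseline` reconstructs the input bit-for-bit.
#' Corrected intensities may be negative (they are not clipped, so band
#' means stay unbiased).
#'
#' @param spec A [spectrum()].
#' @param config A [baseline_config()].
#' @return List with `corrected` and `baseline` (both [spectrum()]s),
#'   `iterations`, and `converged` (FALSE means the iteration cap was hit
#'   and the best iterate is returned, with a warning).
#' @export
subtract_baseline <- function(spec, config = baseline_config()) {
  n <- length(spec$axis)
  if (n <= config$order + 1)
    rr_error("spectrum shorter than polynomial order + 2", "rr_config_error")
  basis <- poly_basis(spec$axis, config$order)
  res <- modpoly_fit(matrix(spec$intensities, ncol = 1), basis,
                     config$max_iter, config$tol)
  if (!all(res$converged))
    warning("baseline iteration cap reached; returning best iterate")
  bl <- as.vector(res$baseline)
  list(corrected = spectrum(spec$axis, spec$intensities - bl),
       baseline = spectrum(spec$axis, bl),
       iterations = res$iterations,
       converged = all(res$converged))
}

#' Subtract baselines at every pixel of a map
#'
#' Same procedure as [subtract_baseline()], run jointly over all pixels
#' (one shared polynomial basis; per-pixel convergence).
#'
#' @param map A [hyperspec_map()].
#' @param config A [baseline_config()].
#' @return List with `corrected` and `baseline` maps plus `iterations` and
#'   the fraction of pixels converged (`converged_frac`).
#' @export
subtract_baseline_map <- function(map, config = baseline_config()) {
  d <- dim(map$cube)
  Y <- t(map_matrix(map))  # wavenumber x pixel
  basis <- poly_basis(map$axis, config$order)
  res <- modpoly_fit(Y, basis, config$max_iter, config$tol)
  if (!all(res$converged))
    warning(sprintf("baseline iteration cap reached for %d pixel(s)",
                    sum(!res$converged)))
  bl_cube <- matrix_to_cube(t(res$baseline), d[1], d[2])
  list(corrected = hyperspec_map(map$axis, map$cube - bl_cube, map$pixel_size),
       baseline = hyperspec_map(map$axis, bl_cube, map$pixel_size),
       iterations = res$iterations,
       converged_frac = mean(res$converged))
}

#' Mask pixels belonging to cells
#'
#' A pixel is inside the mask when its summed baseline-corrected intensity
#' over a summary window exceeds a quantile-derived threshold
#' (`frac` x the `quantile` quantile of the per-pixel sums). The rule is
#' scale-free: multiplying the whole cube by a positive constant leaves the
#' mask unchanged.
#'
#' @param map Baseline-corrected [hyperspec_map()].
#' @param window Numeric length-2, summary window in cm^-1
#'   (default `c(1400, 1700)`, covering the strong heme bands).
#' @param frac Threshold as a fraction of the reference quantile
#'   (default 0.25).
#' @param quantile Reference quantile of per-pixel sums (default 0.99).
#' @return List of class `pixel_mask`: `mask` (logical height x width),
#'   `threshold`, `window`. An empty mask triggers a warning, not an error.
#' @export
mask_cells <- function(map, window = c(1400, 1700), frac = 0.25,
                       quantile = 0.99) {
  sel <- map$axis >= window[1] & map$axis <= window[2]
  if (!any(sel))
    rr_error("mask summary window outside the wavenumber axis", "rr_band_error")
  sums <- apply(map$cube[, , sel, drop = FALSE], c(1, 2), sum)
  thr <- frac * stats::quantile(sums, quantile, names = FALSE)
  mask <- sums > thr
  if (!any(mask)) warning("cell mask is empty: no pixel exceeds the threshold")
  structure(list(mask = mask, threshold = thr, window = window),
            class = "pixel_mask")
}

#' Resample a spectrum or map onto a new wavenumber axis
#'
#' Linear interpolation; the target axis must lie inside the source range
#' (no extrapolation). Band quantifiers assume locatable window edges, so
#' non-uniform axes can be regularised with this before analysis.
#'
#' @param x A [spectrum()] or [hyperspec_map()].
#' @param target A [wn_axis()] (or numeric vector).
#' @return Object of the same kind as `x` on the target axis.
#' @export
resample_axis <- function(x, target) {
  if (!inherits(target, "wn_axis")) target <- wn_axis(target)
  UseMethod("resample_axis")
}

#' @export
resample_axis.spectrum <- function(x, target) {
  if (!inherits(target, "wn_axis")) target <- wn_axis(target)
  if (min(target) < min(x$axis) || max(target) > max(x$axis))
    rr_error("target axis extends beyond the source range (extrapolation)",
             "rr_axis_error")
  yi <- stats::approx(as.numeric(x$axis), x$intensities,
                      xout = as.numeric(target))$y
  spectrum(target, yi)
}

#' @export
resample_axis.hyperspec_map <- function(x, target) {
  if (!inherits(target, "wn_axis")) target <- wn_axis(target)
  if (min(target) < min(x$axis) || max(target) > max(x$axis))
    rr_error("target axis extends beyond the source range (extrapolation)",
             "rr_axis_error")
  m <- map_matrix(x)
  out <- t(apply(m, 1, function(y)
    stats::approx(as.numeric(x$axis), y, xout = as.numeric(target))$y))
  d <- dim(x$cube)
  hyperspec_map(target, matrix_to_cube(out, d[1], d[2]), x$pixel_size)
}
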