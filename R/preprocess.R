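#' Calibrate the wavenumber axis against a reference standard
#'
#' Fits a least-squares polynomial mapping detector channel index to
#' wavenumber from the detected channel positions of known reference peaks
#' (acetaminophen is the usual standard for biomedical Raman systems).
#'
#' @param peak_channels Detected channel indices of the reference peaks.
#' @param reference_positions Known peak positions in cm^-1, sorted
#'   ascending, same length as `peak_channels`.
#' @param degree Polynomial degree of the channel-to-wavenumber map.
#' @return Object of class `calibration_model` with `coefficients`
#'   (intercept first), `degree`, `residuals` (cm^-1, at the reference
#'   peaks) and a `predict` method mapping channel indices to wavenumbers.
#' @export
calibrate_wavenumber <- function(peak_channels, reference_positions,
                                 degree = 1L) {
  if (length(peak_channels) != length(reference_positions)) {
    stop("peak_channels and reference_positions must have equal length")
  }
  if (is.unsorted(reference_positions, strictly = TRUE)) {
    stop("reference_positions must be sorted ascending")
  }
  if (length(peak_channels) < degree + 1) {
    stop(sprintf("need at least %d peaks for a degree-%d fit, got %d",
                 degree + 1, degree, length(peak_channels)))
  }
  X <- outer(as.numeric(peak_channels), 0:degree, `^`)
  fit <- stats::lm.fit(X, as.numeric(reference_positions))
  coefs <- fit$coefficients
  # the fitted axis must be monotone over the covered channel range
  probe <- seq(min(peak_channels), max(peak_channels), length.out = 201)
  axis <- drop(outer(probe, 0:degree, `^`) %*% coefs)
  if (any(diff(axis) <= 0)) {
    stop("calibration polynomial is not monotone over the channel range")
  }
  structure(
    list(coefficients = unname(coefs), degree = degree,
         residuals = unname(fit$residuals)),
    class = "calibration_model"
  )
}

#' @export
predict.calibration_model <- function(object, channels, ...) {
  drop(outer(as.numeric(channels), 0:object$degree, `^`) %*%
         object$coefficients)
}

#' Crop a spectrum or dataset to a wavenumber window
#'
#' Retains channels with `lo <= w <= hi` (closed on both ends); the default
#' window is the 600-1800 cm^-1 fingerprint region.
#'
#' @param d A [spectra_dataset()].
#' @param lo,hi Window limits in cm^-1.
#' @return The cropped dataset.
#' @export
crop_fingerprint <- function(d, lo = 600, hi = 1800) {
  stopifnot(inherits(d, "spectra_dataset"))
  if (lo >= hi) stop("need lo < hi")
  keep <- d$wavenumbers >= lo & d$wavenumbers <= hi
  if (!any(keep)) {
    stop(sprintf("crop window [%g, %g] does not overlap the axis [%g, %g]",
                 lo, hi, min(d$wavenumbers), max(d$wavenumbers)))
  }
  d$intensities <- d$intensities[, keep, drop = FALSE]
  d$wavenumbers <- d$wavenumbers[keep]
  add_provenance(d, sprintf("crop(%g,%g)", lo, hi))
}

# Iterative modified polynomial fit (Lieber-style) for one or many spectra.
# Y: channels x spectra matrix. Returns the fitted baseline matrix.
# Convergence is judged per spectrum, so results do not depend on which
# other spectra happen to share the batch.
modpoly_baseline <- function(x, Y, order, max_iter, tol) {
  # orthonormal polynomial basis for numerical stability
  B <- cbind(1 / sqrt(length(x)), stats::poly(x, degree = order))
  work <- Y
  fit <- B %*% crossprod(B, work)
  active <- rep(TRUE, ncol(Y))
  for (i in seq_len(max_iter)) {
    a <- which(active)
    work[, a] <- pmin(work[, a, drop = FALSE], fit[, a, drop = FALSE])
    new_fit <- B %*% crossprod(B, work[, a, drop = FALSE])
    scale <- pmax(apply(abs(fit[, a, drop = FALSE]), 2, max),
                  .Machine$double.eps)
    delta <- apply(abs(new_fit - fit[, a, drop = FALSE]), 2, max) / scale
    fit[, a] <- new_fit
    active[a] <- delta >= tol
    if (!any(active)) break
  }
  fit
}

#' Remove the fluorescence background by iterative polynomial fitting
#'
#' Implements the modified-polyfit scheme: fit a polynomial of the given
#' order, clip every intensity above the fit down to the fit, refit, and
#' repeat until the fitted curve is stable; the final fit is subtracted.
#' Peaks are excluded progressively so the polynomial tracks the smooth
#' fluorescence background only. Output may contain small negative values;
#' they are retained so the subsequent normalization is unbiased.
#'
#' @param d A [spectra_dataset()].
#' @param order Polynomial order (the standard choice is 5).
#' @param max_iter Maximum clip-refit iterations.
#' @param tol Relative change in the fitted curve that stops iteration.
#' @return The background-subtracted dataset.
#' @export
subtract_background <- function(d, order = 5L, max_iter = 200L, tol = 1e-4) {
  stopifnot(inherits(d, "spectra_dataset"))
  if (!all(is.finite(d$intensities))) {
    stop("spectra contain non-finite intensities")
  }
  if (length(d$wavenumbers) <= order + 1) {
    stop("need more channels than polynomial coefficients")
  }
  if (nrow(d$intensities) > 0) {
    Y <- t(d$intensities)
    base <- modpoly_baseline(d$wavenumbers, Y, order, max_iter, tol)
    d$intensities <- t(Y - base)
  }
  add_provenance(d, sprintf("background(order=%d)", order))
}

#' Median filter along the wavenumber axis
#'
#' Running median with the stated odd window, edges handled by replicating
#' the first/last channel.
#'
#' @param d A [spectra_dataset()].
#' @param window Odd window width in channels; 1 is the identity.
#' @return The filtered dataset.
#' @export
median_filter <- function(d, window = 5L) {
  stopifnot(inherits(d, "spectra_dataset"))
  window <- as.integer(window)
  if (window %% 2 == 0 || window < 1) stop("window must be odd and >= 1")
  nchan <- length(d$wavenumbers)
  if (window > nchan) stop("window exceeds the number of channels")
  if (window > 1 && nrow(d$intensities) > 0) {
    k <- (window - 1L) %/% 2L
    d$intensities <- t(apply(d$intensities, 1, function(y) {
      padded <- c(rep(y[1], k), y, rep(y[nchan], k))
      stats::runmed(padded, window)[(k + 1L):(k + nchan)]
    }))
  }
  add_provenance(d, sprintf("median(window=%d)", window))
}

#' Scale every spectrum to unit Euclidean norm
#'
#' Vector normalization: each spectrum is divided by its L2 norm so that
#' downstream score comparisons are independent of acquisition intensity.
#'
#' @param d A [spectra_dataset()].
#' @return The normalized dataset; every row has norm 1.
#' @export
vector_normalize <- function(d) {
  stopifnot(inherits(d, "spectra_dataset"))
  if (nrow(d$intensities) > 0) {
    norms <- sqrt(rowSums(d$intensities^2))
    zero <- which(norms == 0)
    if (length(zero) > 0) {
      stop("cannot normalize all-zero spectrum: ",
           paste(d$meta$spectrum_id[zero], collapse = ", "))
    }
    d$intensities <- d$intensities / norms
  }
  add_provenance(d, "normalize")
}

#' Run the full preprocessing chain on a dataset
#'
#' Applies, in order: fingerprint crop, iterative polynomial background
#' subtraction, median filtering, and vector normalization. The chain is
#' deterministic (no randomness) and is recorded in the dataset provenance.
#'
#' @param d A [spectra_dataset()].
#' @param crop_lo,crop_hi Fingerprint window in cm^-1.
#' @param poly_order Background polynomial order.
#' @param max_iter,tol Background iteration controls.
#' @param median_window Median filter width (odd).
#' @return The preprocessed dataset (unit-norm spectra).
#' @export
preprocess_dataset <- function(d, crop_lo = 600, crop_hi = 1800,
                               poly_order = 5L, max_iter = 200L, tol = 1e-4,
                               median_window = 5L) {
  d <- crop_fingerprint(d, crop_lo, crop_hi)
  d <- subtract_background(d, poly_order, max_iter, tol)
  d <- median_filter(d, median_window)
  vector_normalize(d)
}
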