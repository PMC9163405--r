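#' Polynomial detrending of network time courses
#'
#' Removes trends up to `max_order` (0 = mean, 1 = linear, 2 = quadratic,
#' 3 = cubic) from every network signal by joint least squares on an
#' orthogonal polynomial basis, so the result is independent of fitting
#' order and has zero projection on every removed polynomial.
#'
#' @param tc a [timecourse()].
#' @param max_order highest polynomial order to remove, 0..3 (default 3).
#' @return detrended [timecourse()].
#' @export
detrend_poly <- function(tc, max_order = 3) {
  stopifnot(max_order >= 0, max_order <= 3)
  T_ <- nrow(tc$data)
  if (T_ <= max_order + 1)
    stop_dynfc("detrend_poly: %d timepoints too few for order %d", T_,
               max_order)
  X <- cbind(1, if (max_order > 0) stats::poly(seq_len(T_), max_order))
  res <- stats::lm.fit(X, tc$data)$residuals
  tc_replace(tc, res)
}

#' Despike network time courses by running-median/MAD clipping
#'
#' A transparent surrogate for AFNI-style despiking: samples deviating from
#' a centered running median by more than `threshold_mad` local MADs are
#' clipped to the threshold boundary; all other samples pass unchanged.
#' The local MAD is floored at `eps` so constant stretches (MAD = 0) still
#' pull an isolated spike back to the running median.
#'
#' @param tc a [timecourse()].
#' @param threshold_mad clipping threshold in MAD units (default 4).
#' @param window odd running-window length (default 11).
#' @param eps MAD floor (default 1e-9).
#' @return despiked [timecourse()].
#' @export
despike <- function(tc, threshold_mad = 4, window = 11, eps = 1e-9) {
  stopifnot(threshold_mad > 0, window >= 3, window %% 2 == 1)
  T_ <- nrow(tc$data)
  if (window > T_) stop_dynfc("despike: window %d longer than series %d",
                              window, T_)
  half <- (window - 1L) / 2L
  out <- tc$data
  for (c in seq_len(ncol(out))) {
    x <- out[, c]
    med <- stats::runmed(x, window, endrule = "median")
    # centered running MAD with edge truncation
    madv <- vapply(seq_len(T_), function(t) {
      idx <- max(1L, t - half):min(T_, t + half)
      stats::median(abs(x[idx] - med[t]))
    }, 0)
    madv <- pmax(madv * 1.4826, eps)
    dev <- x - med
    bound <- threshold_mad * madv
    hit <- abs(dev) > bound
    x[hit] <- med[hit] + sign(dev[hit]) * bound[hit]
    out[, c] <- x
  }
  tc_replace(tc, out)
}

#' Regress nuisance confounds out of network time courses
#'
#' Returns the least-squares residuals of every network signal on an
#' intercept plus the confound columns (e.g. the six rigid-body motion
#' parameters). Residuals are orthogonal to every confound.
#'
#' @param tc a [timecourse()].
#' @param confounds timepoints x p numeric matrix of regressors.
#' @return residual [timecourse()].
#' @export
regress_nuisance <- function(tc, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(tc$data))
    stop_dynfc("regress_nuisance: %d confound rows vs %d timepoints",
               nrow(confounds), nrow(tc$data))
  if (!all(is.finite(confounds)))
    stop_dynfc("regress_nuisance: non-finite confounds")
  X <- cbind(intercept = 1, confounds)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop_dynfc("regress_nuisance: rank-deficient design (collinear: %s)",
               paste(bad, collapse = ", "))
  }
  tc_replace(tc, qr.resid(q, tc$data))
}

#' Zero-phase low-pass filtering of network time courses
#'
#' Order-5 Butterworth low-pass applied forward and backward (zero phase)
#' with odd reflection padding, as is standard for resting-state network
#' time courses. Pass-band sinusoids are preserved, stop-band components
#' attenuated, and the DC level is untouched.
#'
#' @param tc a [timecourse()].
#' @param cutoff_hz cutoff frequency in Hz (default 0.15); must be below
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @param order Butterworth order (default 5).
#' @return filtered [timecourse()].
#' @export
lowpass_filter <- function(tc, cutoff_hz = 0.15, order = 5) {
  nyq <- 1 / (2 * tc$tr)
  if (cutoff_hz >= nyq)
    stop_dynfc("lowpass_filter: cutoff %g Hz >= Nyquist %g Hz", cutoff_hz,
               nyq)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  T_ <- nrow(tc$data)
  pad <- min(T_ - 1L, 3L * (order + 1L) * 3L)
  out <- apply(tc$data, 2, function(x) {
    # odd reflection padding at both ends
    front <- 2 * x[1] - x[(pad + 1):2]
    back <- 2 * x[T_] - x[(T_ - 1):(T_ - pad)]
    xx <- c(front, x, back)
    y <- signal::filter(bf, xx)
    y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
    y[(pad + 1):(pad + T_)]
  })
  tc_replace(tc, out)
}

#' Post-ICA cleaning pipeline
#'
#' Applies, in order: polynomial detrending (linear, quadratic and cubic
#' trends), despiking, nuisance regression (when confounds are supplied)
#' and zero-phase low-pass filtering at 0.15 Hz.
#'
#' @param tc a [timecourse()].
#' @param confounds optional timepoints x p confound matrix.
#' @param max_order,threshold_mad,window,cutoff_hz stage parameters.
#' @return cleaned [timecourse()].
#' @export
preprocess_timecourse <- function(tc, confounds = NULL, max_order = 3,
                                  threshold_mad = 4, window = 11,
                                  cutoff_hz = 0.15) {
  tc <- detrend_poly(tc, max_order)
  tc <- despike(tc, threshold_mad, window)
  if (!is.null(confounds)) tc <- regress_nuisance(tc, confounds)
  lowpass_filter(tc, cutoff_hz)
}
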