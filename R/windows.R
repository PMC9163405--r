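#' Tapered sliding-window specification
#'
#' A rectangle of `window_length_tr` TRs convolved with a Gaussian kernel
#' (`taper_sigma_tr` TRs, truncated at +-4 sigma, 'same' convolution),
#' normalized to sum 1, slid by `step_tr` TRs. The main-analysis defaults
#' are a 22-TR window (44 s at TR = 2 s) with sigma = 3 TRs and step 1;
#' 20- and 30-TR windows are the conventional robustness settings.
#'
#' @param window_length_tr window length W in TRs (default 22).
#' @param taper_sigma_tr Gaussian taper sigma in TRs (default 3).
#' @param step_tr slide step in TRs (default 1).
#' @param count_convention `"n_minus_w"` (default; `n - W` windows for step
#'   1, the toolbox convention that yields 148 windows from 170 timepoints)
#'   or `"n_minus_w_plus_1"` (all placements).
#' @return object of class `tapered_window_spec`.
#' @export
tapered_window_spec <- function(window_length_tr = 22, taper_sigma_tr = 3,
                                step_tr = 1,
                                count_convention = c("n_minus_w",
                                                     "n_minus_w_plus_1")) {
  count_convention <- match.arg(count_convention)
  stopifnot(window_length_tr >= 3, taper_sigma_tr > 0, step_tr >= 1)
  structure(list(window_length_tr = as.integer(window_length_tr),
                 taper_sigma_tr = taper_sigma_tr,
                 step_tr = as.integer(step_tr),
                 count_convention = count_convention),
            class = "tapered_window_spec")
}

#' Build tapered window weights and placements
#'
#' @param n_timepoints number of timepoints in the scan.
#' @param wspec a [tapered_window_spec()].
#' @return list with `weights` (length-W taper, nonnegative, symmetric,
#'   sum 1), `starts` (first timepoint of each window), `centers`
#'   (window-center timepoints) and `n_windows`.
#' @export
make_tapered_windows <- function(n_timepoints, wspec = tapered_window_spec()) {
  W <- wspec$window_length_tr
  if (n_timepoints <= W)
    stop_dynfc("make_tapered_windows: n_timepoints (%d) must exceed W (%d)",
               n_timepoints, W)
  weights <- gaussian_tapered_rect(W, wspec$taper_sigma_tr)
  last <- if (wspec$count_convention == "n_minus_w")
    n_timepoints - W else n_timepoints - W + 1L
  starts <- seq.int(1L, last, by = wspec$step_tr)
  list(weights = weights, starts = starts,
       centers = starts + (W - 1) / 2,
       n_windows = length(starts))
}

# rectangle(W) convolved with a Gaussian kernel (sigma, truncated +-4
# sigma), 'same' mode, renormalized to sum 1
gaussian_tapered_rect <- function(W, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  # 'same'-mode convolution of the unit rectangle with the kernel:
  # w[i] = sum of kernel offsets m with 1 <= i - m <= W
  w <- vapply(seq_len(W), function(i) {
    m <- max(-half, i - W):min(half, i - 1L)
    sum(kern[m + half + 1L])
  }, 0)
  w / sum(w)
}
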