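#' Detector noise parameters
#'
#' The pixel-level noise model of a pixelated electron detector:
#' `gain` (G) converts incident electrons to detector counts, the cascade
#' factor `cascade` (gamma >= 1) inflates the variance above the pure
#' Poisson value, and the pixel factor `pixel_var` (psi) is the variance of
#' pixel values in a dark image, in counts squared.
#'
#' @param gain Detector gain G, counts per incident electron, `> 0`.
#' @param cascade Cascade factor gamma, `>= 1`.
#' @param pixel_var Dark-image pixel variance psi, counts^2, `>= 0`.
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(gain = 1, cascade = 1, pixel_var = 0) {
  if (!(gain > 0)) stop("gain must be positive")
  if (!(cascade >= 1)) stop("cascade factor must be >= 1")
  if (!(pixel_var >= 0)) stop("pixel variance must be non-negative")
  structure(list(gain = gain, cascade = cascade, pixel_var = pixel_var),
            class = "noise_params")
}

#' Variance of a single pixel count
#'
#' `var(c) = gamma * G * c + psi`: the Poisson term in detector counts,
#' scaled by the gain and inflated by the cascade factor, plus the
#' dark-image floor. Never falls below `psi`, nor below `G * c` for
#' `gamma >= 1`.
#'
#' @param counts Non-negative pixel count(s), in detector counts.
#' @param np A [noise_params()].
#' @return Variance(s) in counts^2, vectorized over `counts`.
#' @examples
#' pixel_variance(100, noise_params(1, 1, 0))  # pure Poisson: 100
#' @export
pixel_variance <- function(counts, np) {
  if (!inherits(np, "noise_params")) stop("'np' must be noise_params")
  if (any(counts < 0)) stop("negative pixel count")
  np$cascade * np$gain * counts + np$pixel_var
}

#' Integrate a peak with background subtraction and error propagation
#'
#' The integrated intensity is the sum of peak-region counts minus the
#' estimated background, `n_S` times the unweighted mean of the rim counts:
#' `I = sum(peak) - n_S * mean(rim)`. Propagating independent pixel
#' variances through this expression gives
#' `Var(I) = sum_S var(c_i) + (n_S/n_rim)^2 * sum_rim var(b_j)`.
#'
#' @param peak Numeric vector of pixel counts over the peak region S.
#' @param rim Numeric vector of pixel counts over the background rim.
#' @param np A [noise_params()].
#' @return A list with `intensity` and `sigma` (= sqrt of the propagated
#'   variance), both in detector counts.
#' @examples
#' integrate_peak(c(10, 10), c(5, 5, 5, 5), noise_params())
#' @export
integrate_peak <- function(peak, rim, np) {
  if (length(peak) < 1L) stop("empty peak region")
  if (length(rim) < 1L) stop("no background estimate: empty rim")
  if (any(peak < 0) || any(rim < 0)) stop("negative pixel count")
  n_s <- length(peak); n_rim <- length(rim)
  I <- sum(peak) - n_s * mean(rim)
  v <- sum(pixel_variance(peak, np)) + (n_s / n_rim)^2 * sum(pixel_variance(rim, np))
  list(intensity = I, sigma = sqrt(v))
}
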