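# Wavelet soft-threshold denoising.

#' Universal shrinkage threshold
#'
#' \eqn{T = \hat\sigma \sqrt{2 \ln n}} with the noise scale
#' \eqn{\hat\sigma = \mathrm{median}(|d|)/0.6745} estimated from the
#' finest-scale detail coefficients (the median absolute deviation of a
#' zero-mean Gaussian).
#'
#' @param detail_coeffs numeric vector of detail coefficients.
#' @param n signal length used in the \eqn{\sqrt{2 \ln n}} factor; must be >= 2.
#' @return a single non-negative threshold.
#' @export
universal_threshold <- function(detail_coeffs, n) {
  if (length(detail_coeffs) == 0L) stop("detail_coeffs must be non-empty", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  sigma <- stats::median(abs(detail_coeffs)) / 0.6745
  sigma * sqrt(2 * log(n))
}

#' Soft thresholding
#'
#' Shrinks coefficients toward zero: \eqn{sgn(W)(|W|-T)} for \eqn{|W| \ge T},
#' zero otherwise.
#'
#' @param w numeric vector of coefficients.
#' @param t non-negative threshold.
#' @return shrunk coefficients, same length as \code{w}.
#' @export
soft_threshold <- function(w, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  sign(w) * pmax(abs(w) - t, 0)
}

#' Wavelet denoising of a phonocardiogram
#'
#' Decomposes the signal (Daubechies 6, 5 levels, symmetric extension),
#' soft-thresholds all detail coefficients with one global universal threshold
#' estimated from the level-1 details, leaves the approximation band (which
#' carries the S1/S2 energy) untouched, and reconstructs by the inverse
#' transform.
#'
#' @param x a [pcg_signal()], typically peak-normalized.
#' @param levels decomposition depth (default 5).
#' @param wavelet wavelet basis (default \code{"db6"}).
#' @param threshold optional fixed threshold overriding the universal rule;
#'   \code{threshold = 0} disables shrinkage (useful to verify perfect
#'   reconstruction).
#' @return a denoised [pcg_signal()] of the same length and rate.
#' @export
denoise_pcg <- function(x, levels = 5L, wavelet = "db6", threshold = NULL) {
  stopifnot(inherits(x, "pcg_signal"))
  wd <- pcg_wavedec(x$samples, levels = levels, wavelet = wavelet)
  t_val <- if (is.null(threshold))
    universal_threshold(wd$d[[1L]], length(x$samples))
  else threshold
  wd$d <- lapply(wd$d, soft_threshold, t = t_val)
  pcg_signal(pcg_waverec(wd), x$rate, subject_id = x$subject_id, site = x$site)
}
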