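# Time-frequency features of the closed-valve intervals (CAV, CSV).

#' Names of the 10 murmur features, in canonical order
#' @export
pcg_feature_names <- c(
  "cav_max", "cav_min", "cav_meanabs",
  "csv_max", "csv_min", "csv_meanabs",
  "cav_psd_max", "cav_psd_mean", "csv_psd_max", "csv_psd_mean")

# Sample indices of a [t0, t1) interval.
.interval_idx <- function(t0, t1, rate, n) {
  i0 <- floor(t0 * rate) + 1L
  i1 <- min(floor(t1 * rate), n)
  if (i1 < i0) integer(0) else i0:i1
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann window and 50\% segment
#' overlap; one-sided density scaling (power per Hz). Segments shorter than
#' \code{nperseg} fall back to a single full-length Hann periodogram, which
#' keeps the estimator defined for the short diastolic intervals of
#' high-rate recordings.
#'
#' @param x numeric vector, at least 8 samples.
#' @param rate sampling rate in Hz.
#' @param nperseg segment length in samples (default 128, i.e. 64 ms at 2 kHz).
#' @return list with \code{freq} (Hz, 0..rate/2) and \code{psd} (non-negative
#'   densities).
#' @export
welch_psd <- function(x, rate, nperseg = 128L) {
  n <- length(x)
  if (n < 8L) stop("segment too short for PSD estimation (need >= 8 samples)",
                   call. = FALSE)
  seg_len <- min(nperseg, n)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- signal::hanning(seg_len)
  scale <- rate * sum(w^2)
  n_bins <- seg_len %/% 2L + 1L
  acc <- numeric(n_bins)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[seq_len(n_bins)]
    # one-sided: double everything except DC (and Nyquist when seg_len even)
    dbl <- rep(2, n_bins)
    dbl[1L] <- 1
    if (seg_len %% 2L == 0L) dbl[n_bins] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(n_bins) - 1) * rate / seg_len,
       psd = acc / length(starts))
}

# Per-cycle interval samples of the denoised signal; NULL if empty.
.cycle_samples <- function(x, row, which_iv) {
  idx <- .interval_idx(row[[paste0(which_iv, "_start")]],
                       row[[paste0(which_iv, "_end")]],
                       x$rate, length(x$samples))
  if (length(idx) == 0L) NULL else x$samples[idx]
}

#' Time-domain features of the closed-valve intervals
#'
#' Per cycle: maximum (positive), minimum (negative) and mean absolute
#' amplitude over the CAV samples and over the CSV samples of the denoised
#' signal; each averaged across all complete cycles.
#'
#' @param x a denoised [pcg_signal()].
#' @param cycles cycle table from [locate_durations()] or a
#'   \code{pcg_segmentation}'s \code{$cycles}.
#' @return named numeric vector of 6 features.
#' @export
time_features <- function(x, cycles) {
  stopifnot(inherits(x, "pcg_signal"))
  per <- lapply(seq_len(nrow(cycles)), function(i) {
    cav <- .cycle_samples(x, cycles[i, ], "cav")
    csv <- .cycle_samples(x, cycles[i, ], "csv")
    if (is.null(cav) || is.null(csv)) return(NULL)
    c(cav_max = max(cav), cav_min = min(cav), cav_meanabs = mean(abs(cav)),
      csv_max = max(csv), csv_min = min(csv), csv_meanabs = mean(abs(csv)))
  })
  ok <- !vapply(per, is.null, logical(1))
  if (sum(!ok) > 0L) warning(sum(!ok), " cycle(s) with empty interval skipped",
                             call. = FALSE)
  if (!any(ok)) stop("no cycle with non-empty CAV and CSV intervals", call. = FALSE)
  colMeans(do.call(rbind, per[ok]))
}

#' Frequency-domain features of the closed-valve intervals
#'
#' Per cycle: Welch power spectral density of the CAV samples and of the CSV
#' samples (full 0 to Nyquist band); the maximum and mean density of each,
#' averaged across cycles.
#'
#' @inheritParams time_features
#' @param nperseg Welch segment length (default 128 samples).
#' @return named numeric vector of 4 features.
#' @export
freq_features <- function(x, cycles, nperseg = 128L) {
  stopifnot(inherits(x, "pcg_signal"))
  per <- lapply(seq_len(nrow(cycles)), function(i) {
    cav <- .cycle_samples(x, cycles[i, ], "cav")
    csv <- .cycle_samples(x, cycles[i, ], "csv")
    if (is.null(cav) || is.null(csv) || length(cav) < 8L || length(csv) < 8L)
      return(NULL)
    pc <- welch_psd(cav, x$rate, nperseg)$psd
    pd <- welch_psd(csv, x$rate, nperseg)$psd
    c(cav_psd_max = max(pc), cav_psd_mean = mean(pc),
      csv_psd_max = max(pd), csv_psd_mean = mean(pd))
  })
  ok <- !vapply(per, is.null, logical(1))
  if (sum(!ok) > 0L) warning(sum(!ok), " cycle(s) with empty/short interval skipped",
                             call. = FALSE)
  if (!any(ok)) stop("no cycle usable for PSD features", call. = FALSE)
  colMeans(do.call(rbind, per[ok]))
}

#' Extract the 10-feature vector of one recording
#'
#' Assembles the 6 time-domain and 4 frequency-domain features of the
#' closed-valve intervals in the fixed order of [pcg_feature_names].
#'
#' @param x a denoised [pcg_signal()].
#' @param seg a \code{pcg_segmentation} (or a cycle table).
#' @return named numeric vector of length 10.
#' @examples
#' sim <- synthesize_pcg(heart_rate = 100, duration = 10,
#'                       murmur_level = 0.8, seed = 2)
#' den <- denoise_pcg(normalize_amplitude(sim$signal))
#' pcg_features(den, segment_pcg(den))
#' @export
pcg_features <- function(x, seg) {
  cycles <- if (inherits(seg, "pcg_segmentation")) seg$cycles else seg
  if (nrow(cycles) == 0L) stop("no complete cycles to extract features from",
                               call. = FALSE)
  out <- c(time_features(x, cycles), freq_features(x, cycles))
  out[pcg_feature_names]
}
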