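# Phonocardiogram container and WAV file I/O.

#' Construct a phonocardiogram signal object
#'
#' The canonical container passed between all processing stages: a numeric
#' amplitude vector plus its sampling rate in Hz.
#'
#' @param samples numeric vector of amplitudes (dimensionless).
#' @param rate sampling frequency in Hz (> 0).
#' @param subject_id optional subject label.
#' @param site optional auscultation-site tag (e.g. "mitral").
#' @return an object of class \code{"pcg_signal"}.
#' @examples
#' x <- pcg_signal(sin(2 * pi * 80 * seq(0, 1, by = 1/2000)), rate = 2000)
#' x
#' @export
pcg_signal <- function(samples, rate, subject_id = NULL, site = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  if (anyNA(samples)) stop("samples contain NA", call. = FALSE)
  structure(list(samples = samples, rate = rate,
                 subject_id = subject_id, site = site),
            class = "pcg_signal")
}

#' @export
print.pcg_signal <- function(x, ...) {
  cat(sprintf("Phonocardiogram: %d samples at %g Hz (%.2f s)%s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id) else ""))
  invisible(x)
}

#' @export
length.pcg_signal <- function(x) length(x$samples)

#' Read a mono PCM WAV file
#'
#' Parses a RIFF/WAVE file (16-bit integer PCM or 32-bit IEEE float). Integer
#' samples are scaled to [-1, 1) by 1/32768. Multi-channel files are reduced
#' to channel 1 with a warning.
#'
#' @param path file path.
#' @param subject_id optional label attached to the returned signal; defaults
#'   to the file name without extension.
#' @return a [pcg_signal()].
#' @export
read_wav <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format    = sum(as.integer(raw_fmt[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(raw_fmt[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(raw_fmt[15:16]) * c(1L, 256L)))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      break
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word-aligned)
    }
  }
  if (is.null(fmt)) stop("malformed WAV: no fmt chunk in ", path, call. = FALSE)
  if (is.null(dat) || length(dat) == 0L)
    stop("zero-length audio in ", path, call. = FALSE)
  n_vals <- length(dat) %/% (fmt$bits %/% 8L)
  if (fmt$format == 1L && fmt$bits == 16L) {
    v <- readBin(dat, "integer", n_vals, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    v <- readBin(dat, "double", n_vals, size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$format, ", ",
         fmt$bits, " bits); expected 16-bit PCM or 32-bit float", call. = FALSE)
  }
  if (fmt$channels > 1L) {
    warning("multi-channel WAV; using channel 1 only", call. = FALSE)
    v <- v[seq(1L, length(v), by = fmt$channels)]
  }
  if (length(v) == 0L) stop("zero-length audio in ", path, call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  pcg_signal(v, fmt$rate, subject_id = subject_id)
}

#' Write a signal to a mono 16-bit PCM WAV file
#'
#' Samples are clipped to [-1, 1] and quantized by 32768 (the same scale
#' [read_wav()] divides by, so a write/read round trip is transparent up to
#' half a quantization step).
#'
#' @param x a [pcg_signal()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "pcg_signal"))
  v <- pmax(pmin(x$samples, 1), -1)
  pcm <- as.integer(pmin(round(v * 32768), 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(i) writeBin(as.integer(i), con, size = 4, endian = "little")
  w16 <- function(i) writeBin(as.integer(i), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L)                      # PCM, mono
  w32(as.integer(x$rate))               # sample rate
  w32(as.integer(x$rate) * 2L)          # byte rate
  w16(2L); w16(16L)                     # block align, bits
  writeChar("data", con, eos = NULL); w32(n_bytes)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample a signal to a lower rate
#'
#' Polyphase FIR rational-ratio resampling (via \code{signal::resample}) with
#' built-in anti-alias low-pass filtering. Only downsampling (or the identity)
#' is supported; the analysis pipeline runs at a canonical 2 kHz.
#'
#' @param x a [pcg_signal()].
#' @param target_rate requested sampling rate in Hz; must not exceed
#'   \code{x$rate}.
#' @return a [pcg_signal()] at \code{target_rate}.
#' @export
resample_to_rate <- function(x, target_rate) {
  stopifnot(inherits(x, "pcg_signal"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be positive", call. = FALSE)
  if (target_rate > x$rate)
    stop("upsampling (", x$rate, " -> ", target_rate,
         " Hz) is not supported", call. = FALSE)
  if (target_rate == x$rate) return(x)
  g <- .gcd(round(target_rate), round(x$rate))
  p <- round(target_rate) / g
  q <- round(x$rate) / g
  y <- signal::resample(x$samples, p, q)
  pcg_signal(as.numeric(y), target_rate, subject_id = x$subject_id, site = x$site)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Peak-normalize a signal to within \eqn{\pm 1}
#'
#' Divides every sample by the maximum absolute amplitude, so the result lies
#' in [-1, 1] with at least one sample at \eqn{\pm 1}. An all-zero recording is
#' rejected: it carries no heart sounds and cannot be processed downstream.
#'
#' @param x a [pcg_signal()].
#' @return a [pcg_signal()] with \code{max(abs(samples)) == 1}.
#' @export
normalize_amplitude <- function(x) {
  stopifnot(inherits(x, "pcg_signal"))
  m <- max(abs(x$samples))
  if (m == 0) stop("all-zero signal cannot be normalized", call. = FALSE)
  pcg_signal(x$samples / m, x$rate, subject_id = x$subject_id, site = x$site)
}
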