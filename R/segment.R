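# Heart-sound segmentation: band recombination, Shannon-energy envelope,
# S1/S2 instant detection, heart rate, labeling, and duration boundaries.

#' Hadamard recombination of detail bands
#'
#' Element-wise product of the D4 and D5 band reconstructions. A component
#' survives only where both bands are simultaneously active, which is the case
#' for the broadband low-frequency S1/S2 bursts but not for murmurs or noise
#' concentrated in a single band; in time, the product vanishes outside the
#' overlap, suppressing murmur energy that leaks into one band alone.
#'
#' @param d4,d5 numeric vectors of equal length (level-4 and level-5 detail
#'   band reconstructions; at 2 kHz nominally 62.5-125 Hz and 31.25-62.5 Hz).
#' @return numeric vector, the recombined signal.
#' @export
recombine_bands <- function(d4, d5) {
  if (length(d4) != length(d5))
    stop("d4 and d5 must have equal length", call. = FALSE)
  d4 * d5
}

#' Average Shannon energy envelope
#'
#' Frames the recombined signal (normalized to \eqn{\pm 1} by its global peak)
#' into sliding windows and computes the average Shannon energy
#' \eqn{E_s = -\frac{1}{N}\sum s^2 \log s^2} per frame (with
#' \eqn{0 \log 0 := 0}), then z-scores the frame series to produce the
#' normalized envelope. Defaults: 20 ms frames, 10 ms hop, hence N = 40
#' samples per frame at 2 kHz. Shannon energy emphasizes medium-intensity
#' components, attenuating both low-level noise and the dominant peaks less
#' aggressively than squared energy would.
#'
#' @param s numeric vector (the recombined signal).
#' @param rate sampling rate in Hz.
#' @param frame_ms,hop_ms frame length and hop in milliseconds.
#' @return object of class \code{"pcg_envelope"}: list with \code{values}
#'   (z-scored envelope), \code{es} (raw average Shannon energy, non-negative),
#'   \code{times} (frame-center times in seconds), and the framing parameters.
#' @export
shannon_envelope <- function(s, rate, frame_ms = 20, hop_ms = 10) {
  n_frame <- round(frame_ms / 1000 * rate)
  n_hop <- round(hop_ms / 1000 * rate)
  if (length(s) < n_frame)
    stop("signal shorter than one ", frame_ms, " ms frame", call. = FALSE)
  m <- max(abs(s))
  s_norm <- if (m > 0) s / m else s
  starts <- seq(1L, length(s) - n_frame + 1L, by = n_hop)
  sq <- s_norm^2
  lsq <- ifelse(sq > 0, sq * log(sq), 0)
  es <- vapply(starts, function(i) -mean(lsq[i:(i + n_frame - 1L)]), numeric(1))
  mu <- mean(es)
  sd_es <- stats::sd(es)
  values <- if (sd_es > 0) (es - mu) / sd_es else es - mu
  structure(list(values = values, es = es,
                 times = (starts - 1 + (n_frame - 1) / 2) / rate,
                 frame_ms = frame_ms, hop_ms = hop_ms, rate = rate),
            class = "pcg_envelope")
}

#' Detect candidate heart-sound instants from the envelope
#'
#' Peaks are sample points where the first difference of the envelope changes
#' sign from positive to negative (plateaus take the leftmost sample). Two
#' constraints filter the candidates: (1) a candidate is kept only if it is
#' the envelope maximum within a 100 ms range centered on it; (2) adjacent
#' candidates closer than 180 ms are resolved by dropping the lower-magnitude
#' one. Surviving gaps longer than 500 ms are flagged (attribute
#' \code{"long_gaps"}) rather than repaired: removing a candidate can only
#' widen a gap, and slow heart rates legitimately produce diastolic gaps
#' beyond 500 ms.
#'
#' @param env a [shannon_envelope()] object.
#' @param local_win width in seconds of the local-maximum window (default 0.1).
#' @param min_sep,max_sep adjacency bounds in seconds (defaults 0.18 and 0.5).
#' @return data frame with columns \code{time} and \code{magnitude}
#'   (z-scored envelope value), in time order; attribute \code{long_gaps}
#'   gives indices of gaps exceeding \code{max_sep}.
#' @export
detect_instants <- function(env, local_win = 0.1, min_sep = 0.18, max_sep = 0.5) {
  stopifnot(inherits(env, "pcg_envelope"))
  v <- env$values
  tt <- env$times
  n <- length(v)
  if (n < 3L) stop("insufficient beats: envelope too short", call. = FALSE)
  # peaks: first difference + -> - , plateau takes the leftmost sample
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  # constraint (1): maximal magnitude within local_win centered on the candidate
  half <- local_win / 2
  keep <- vapply(cand, function(k) {
    w <- which(tt >= tt[k] - half & tt <= tt[k] + half)
    v[k] >= max(v[w])
  }, logical(1))
  cand <- cand[keep]
  # sub-frame refinement: the envelope is sampled at the hop period, so a
  # parabola through the three samples around each peak sharpens the instant
  # well below the 10 ms frame quantization
  hop <- if (length(tt) > 1L) tt[2L] - tt[1L] else 0
  ct <- vapply(cand, function(k) {
    if (k <= 1L || k >= n) return(tt[k])
    den <- v[k - 1L] - 2 * v[k] + v[k + 1L]
    if (den >= 0) return(tt[k])
    delta <- 0.5 * (v[k - 1L] - v[k + 1L]) / den
    tt[k] + max(-0.5, min(0.5, delta)) * hop
  }, numeric(1))
  # constraint (2): drop the lower-magnitude member of pairs closer than min_sep
  repeat {
    if (length(cand) < 2L) break
    gaps <- diff(ct)
    bad <- which(gaps < min_sep)
    if (length(bad) == 0L) break
    b <- bad[1L]
    drop_idx <- if (v[cand[b]] <= v[cand[b + 1L]]) b else b + 1L
    cand <- cand[-drop_idx]
    ct <- ct[-drop_idx]
  }
  if (length(cand) < 3L)
    stop("insufficient beats: fewer than 3 instants detected", call. = FALSE)
  out <- data.frame(time = ct, magnitude = v[cand])
  attr(out, "long_gaps") <- which(diff(out$time) > max_sep)
  out
}

#' Heart rate from heart-sound instants
#'
#' With instants alternating S1, S2, S1, ... each two-step span
#' \eqn{p_{i+2} - p_i} covers one full cardiac cycle; the heart rate is 60
#' divided by the mean span over all \eqn{M - 2} consecutive triples.
#'
#' @param times sorted instant times in seconds (M >= 3).
#' @return heart rate in beats per minute.
#' @export
estimate_heart_rate <- function(times) {
  m <- length(times)
  if (m < 3L) stop("need at least 3 instants to estimate heart rate", call. = FALSE)
  if (is.unsorted(times)) stop("instant times must be ascending", call. = FALSE)
  spans <- times[3:m] - times[1:(m - 2L)]
  60 / mean(spans)
}

#' Label instants as S1 or S2
#'
#' Applies the pediatric systole/diastole rule: at heart rates up to 130 bpm
#' systole (S1 to S2) is the shorter of the two intervals in any three
#' consecutive instants; above 130 bpm it is the longer one (infant diastole
#' shortens faster than systole as rate rises). Each consecutive triple votes
#' for one of the two alternating label assignments; the majority wins, ties
#' or all-equal gaps raise an error.
#'
#' @param times sorted instant times in seconds (>= 3).
#' @param heart_rate beats per minute, e.g. from [estimate_heart_rate()].
#' @param hr_cutoff rate above which systole exceeds diastole (default 130).
#' @return character vector of labels ("S1"/"S2") parallel to \code{times}.
#' @export
label_s1_s2 <- function(times, heart_rate, hr_cutoff = 130) {
  m <- length(times)
  if (m < 3L) stop("need at least 3 instants to label", call. = FALSE)
  votes <- integer(0)  # +1: odd-position instants are S1; -1: they are S2
  for (i in seq_len(m - 2L)) {
    g1 <- times[i + 1L] - times[i]
    g2 <- times[i + 2L] - times[i + 1L]
    if (g1 == g2) next  # uninformative triple
    first_is_s1 <- if (heart_rate <= hr_cutoff) g1 < g2 else g1 > g2
    # instant i is S1 iff first_is_s1; translate to position parity
    odd_is_s1 <- xor(i %% 2L == 0L, first_is_s1)
    votes <- c(votes, if (odd_is_s1) 1L else -1L)
  }
  tally <- sum(votes)
  if (length(votes) == 0L || tally == 0L)
    stop("ambiguous systole/diastole: cannot label S1/S2", call. = FALSE)
  odd_is_s1 <- tally > 0L
  odd <- seq_len(m) %% 2L == 1L
  ifelse(odd == odd_is_s1, "S1", "S2")
}

#' Locate S1/S2 duration boundaries and the closed-valve intervals
#'
#' For each labeled instant a search window (120 ms for S1, 100 ms for S2) is
#' centered on it; envelope points whose raw average Shannon energy falls
#' below 10\% of the energy at the instant are marked, and the marked points
#' nearest the instant on each side become the start and end of the sound's
#' duration. Sides with no sub-threshold point are clamped to the window edge
#' and flagged. The threshold is applied to the non-negative pre-z-score
#' Shannon energy, where a 10\% fraction is well defined. Per cycle, the
#' closed atrioventricular valve interval CAV spans S1 end to S2 start
#' (systole) and the closed semilunar valve interval CSV spans S2 end to the
#' next S1 start (diastole); edge cycles lacking a flanking instant are
#' discarded.
#'
#' @param env a [shannon_envelope()] object.
#' @param instants data frame with columns \code{time} and \code{label}
#'   ("S1"/"S2").
#' @param s1_win,s2_win search-window widths in seconds (defaults 0.12, 0.10).
#' @param rel_thresh boundary threshold as a fraction of the instant's raw
#'   Shannon energy (default 0.1).
#' @return data frame of complete cycles: \code{cycle}, \code{s1_start},
#'   \code{s1_end}, \code{s2_start}, \code{s2_end}, \code{cav_start},
#'   \code{cav_end}, \code{csv_start}, \code{csv_end}, \code{clamped}
#'   (logical: any boundary clamped to its window edge).
#' @export
locate_durations <- function(env, instants, s1_win = 0.12, s2_win = 0.10,
                             rel_thresh = 0.1) {
  stopifnot(inherits(env, "pcg_envelope"))
  stopifnot(all(c("time", "label") %in% names(instants)))
  bounds <- function(t0, half) {
    # raw-energy value at the frame nearest the instant
    k0 <- which.min(abs(env$times - t0))
    thr <- rel_thresh * env$es[k0]
    w <- which(env$times >= t0 - half & env$times <= t0 + half)
    marked <- w[env$es[w] < thr]
    left <- marked[env$times[marked] < t0]
    right <- marked[env$times[marked] > t0]
    clamped <- length(left) == 0L || length(right) == 0L
    c(start = if (length(left)) max(env$times[left]) else t0 - half,
      end = if (length(right)) min(env$times[right]) else t0 + half,
      clamped = as.numeric(clamped))
  }
  s1_idx <- which(instants$label == "S1")
  cycles <- list()
  for (ci in seq_along(s1_idx)) {
    i <- s1_idx[ci]
    if (i + 2L > nrow(instants)) break           # need S2 and the next S1
    if (instants$label[i + 1L] != "S2" || instants$label[i + 2L] != "S1") next
    b1 <- bounds(instants$time[i], s1_win / 2)
    b2 <- bounds(instants$time[i + 1L], s2_win / 2)
    b1n <- bounds(instants$time[i + 2L], s1_win / 2)
    if (b1["end"] >= b2["start"] || b2["end"] >= b1n["start"]) next  # degenerate
    cycles[[length(cycles) + 1L]] <- data.frame(
      cycle = length(cycles) + 1L,
      s1_start = b1[["start"]], s1_end = b1[["end"]],
      s2_start = b2[["start"]], s2_end = b2[["end"]],
      cav_start = b1[["end"]], cav_end = b2[["start"]],
      csv_start = b2[["end"]], csv_end = b1n[["start"]],
      clamped = (b1[["clamped"]] + b2[["clamped"]]) > 0)
  }
  if (length(cycles) == 0L)
    return(data.frame(cycle = integer(0), s1_start = numeric(0),
                      s1_end = numeric(0), s2_start = numeric(0),
                      s2_end = numeric(0), cav_start = numeric(0),
                      cav_end = numeric(0), csv_start = numeric(0),
                      csv_end = numeric(0), clamped = logical(0)))
  do.call(rbind, cycles)
}

#' Segment a denoised phonocardiogram into cardiac cycles
#'
#' Runs the full segmentation chain: 5-level Daubechies-6 band decomposition,
#' Hadamard recombination of the D4 and D5 detail bands, average Shannon
#' energy enveloping, instant detection, heart-rate estimation, S1/S2
#' labeling, and duration/interval location.
#'
#' @param x a denoised, peak-normalized [pcg_signal()] at 2 kHz.
#' @param levels wavelet decomposition depth (default 5).
#' @param wavelet wavelet basis (default \code{"db6"}).
#' @param hr_cutoff systole/diastole heart-rate cutoff in bpm (default 130).
#' @return object of class \code{"pcg_segmentation"}: list with
#'   \code{instants} (labeled data frame), \code{cycles} (see
#'   [locate_durations()]), \code{heart_rate}, \code{envelope}, and
#'   \code{long_gaps}.
#' @examples
#' sim <- synthesize_pcg(heart_rate = 100, duration = 10, seed = 1)
#' seg <- segment_pcg(denoise_pcg(normalize_amplitude(sim$signal)))
#' seg
#' @export
segment_pcg <- function(x, levels = 5L, wavelet = "db6", hr_cutoff = 130) {
  stopifnot(inherits(x, "pcg_signal"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("segmentation failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  bands <- stage("decompose", wavelet_bands(x$samples, levels = levels,
                                            wavelet = wavelet))
  s <- stage("recombine", recombine_bands(bands$D[[4L]], bands$D[[5L]]))
  env <- stage("envelope", shannon_envelope(s, x$rate))
  inst <- stage("detect", detect_instants(env))
  hr <- stage("heart_rate", estimate_heart_rate(inst$time))
  inst$label <- stage("label", label_s1_s2(inst$time, hr, hr_cutoff = hr_cutoff))
  cycles <- stage("durations", locate_durations(env, inst))
  structure(list(instants = inst, cycles = cycles, heart_rate = hr,
                 envelope = env, long_gaps = attr(inst, "long_gaps"),
                 subject_id = x$subject_id),
            class = "pcg_segmentation")
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  cat(sprintf("PCG segmentation%s\n",
              if (!is.null(x$subject_id)) paste0(" of subject ", x$subject_id) else ""))
  cat(sprintf("  %d instants (%d S1, %d S2), %d complete cycles\n",
              nrow(x$instants), sum(x$instants$label == "S1"),
              sum(x$instants$label == "S2"), nrow(x$cycles)))
  cat(sprintf("  heart rate: %.1f bpm\n", x$heart_rate))
  if (length(x$long_gaps))
    cat(sprintf("  note: %d inter-instant gap(s) exceed 500 ms\n", length(x$long_gaps)))
  invisible(x)
}

#' @export
as.data.frame.pcg_segmentation <- function(x, ...) {
  df <- x$cycles
  df$heart_rate <- x$heart_rate
  if (!is.null(x$subject_id)) df <- cbind(subject_id = x$subject_id, df)
  df
}

#' @export
plot.pcg_segmentation <- function(x, ...) {
  env <- x$envelope
  plot(env$times, env$values, type = "l", xlab = "time (s)",
       ylab = "normalized Shannon energy", ...)
  s1 <- x$instants[x$instants$label == "S1", ]
  s2 <- x$instants[x$instants$label == "S2", ]
  graphics::points(s1$time, s1$magnitude, col = "red", pch = 19)
  graphics::points(s2$time, s2$magnitude, col = "blue", pch = 17)
  graphics::legend("topright", legend = c("S1", "S2"), col = c("red", "blue"),
                   pch = c(19, 17), bty = "n")
  invisible(x)
}
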