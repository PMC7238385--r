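test_that("Hadamard recombination is the element-wise product", {
  expect_equal(recombine_bands(c(1, 2, -1), c(3, -1, 2)), c(3, -2, -2))
  expect_equal(recombine_bands(1:5, numeric(5)), numeric(5))
  expect_error(recombine_bands(1:4, 1:5), "equal length")
})

test_that("recombination keeps only intervals where both bands are active", {
  # disjoint-band bursts: one burst lives in D4 only, one in both D4 and D5
  fs <- 2000
  t <- (0:8191) / fs
  both <- exp(-((t - 1) / 0.04)^2) * (sin(2 * pi * 45 * t) + sin(2 * pi * 90 * t))
  d4only <- exp(-((t - 3) / 0.04)^2) * sin(2 * pi * 100 * t)
  b <- wavelet_bands(both + d4only, levels = 5)
  s <- recombine_bands(b$D[[4]], b$D[[5]])
  e_both <- sum(s[t > 0.8 & t < 1.2]^2)
  e_d4 <- sum(s[t > 2.8 & t < 3.2]^2)
  expect_gt(e_both, 100 * e_d4)
})

test_that("frame Shannon energy matches closed forms", {
  fs <- 2000
  # frame 1 holds the global peak (1.0) so later frames are not renormalized;
  # frame 3 holds |s| = exp(-1/2) everywhere, giving Es = exp(-1)
  s <- c(1, numeric(39), numeric(40), rep(exp(-0.5), 40), numeric(80))
  env <- shannon_envelope(s, fs)
  k <- which.min(abs(env$times - (80 + 19.5) / fs))
  expect_equal(env$es[k], exp(-1), tolerance = 1e-12)
  # all-zero frame has zero raw energy (0 log 0 := 0)
  expect_equal(env$es[length(env$es)], 0)
  # a frame of unit amplitude everywhere has zero Shannon energy (log 1 = 0)
  s2 <- c(rep(1, 40), rep(0.5, 40), rep(1, 40))
  env2 <- shannon_envelope(s2, fs)
  expect_equal(env2$es[1], 0, tolerance = 1e-12)
})

test_that("the normalized envelope is z-scored to mean 0 and unit sd", {
  set.seed(8)
  env <- shannon_envelope(rnorm(6000), 2000)
  expect_lt(abs(mean(env$values)), 1e-9)
  expect_lt(abs(sd(env$values) - 1), 1e-9)
})

test_that("instant detection applies the local-maximum and adjacency rules", {
  mk_env <- function(values, hop = 0.01) {
    structure(list(values = values, es = values - min(values) + 0.01,
                   times = (seq_along(values) - 1) * hop,
                   frame_ms = 20, hop_ms = 10, rate = 2000),
              class = "pcg_envelope")
  }
  # clean bursts 400 ms apart: one instant each, at the burst peak
  tri <- c(0, 1, 3, 1, 0)
  v <- c(rep(0, 3), tri, rep(0, 35), tri, rep(0, 35), tri, rep(0, 3))
  inst <- detect_instants(mk_env(v))
  expect_equal(nrow(inst), 3L)
  expect_equal(diff(inst$time), rep(0.4, 2), tolerance = 0.011)

  # two peaks 60 ms apart: only the larger survives the 100 ms local-max rule
  v2 <- numeric(120)
  v2[c(30, 70, 110)] <- 1        # anchor beats 400 ms apart
  v2[36] <- 0.8                  # 60 ms after the first anchor
  inst2 <- detect_instants(mk_env(v2))
  expect_equal(nrow(inst2), 3L)
  expect_false(any(abs(inst2$time - 0.35) < 0.02))

  # peaks 100 ms apart both survive rule (1); adjacency drops the weaker
  v3 <- numeric(150)
  v3[c(20, 60, 100, 140)] <- 1
  v3[70] <- 0.9                  # 100 ms after the peak at index 60
  inst3 <- detect_instants(mk_env(v3))
  expect_equal(nrow(inst3), 4L)
  expect_false(any(abs(inst3$time - 0.69) < 0.02))
})

test_that("heart rate follows the two-step span formula", {
  expect_equal(estimate_heart_rate(c(0, 0.3, 0.8, 1.1, 1.6)), 75)
  expect_equal(estimate_heart_rate(c(0, 0.25, 0.5, 0.75)), 120)
  expect_error(estimate_heart_rate(c(0, 0.5)), "at least 3")
})

test_that("S1/S2 labeling honors the heart-rate-dependent systole rule", {
  # HR 75: gaps alternate 0.3 / 0.5, the short gap is systole
  p <- cumsum(c(0, rep(c(0.3, 0.5), 4)))
  expect_equal(label_s1_s2(p, 75)[1:4], c("S1", "S2", "S1", "S2"))
  # HR 140: gaps alternate 0.20 / 0.23, the SHORT gap is diastole
  q <- cumsum(c(0, rep(c(0.2, 0.23), 4)))
  expect_equal(label_s1_s2(q, 140)[1:4], c("S2", "S1", "S2", "S1"))
  # 130 bpm sits on the low-rate branch: the short gap counts as systole
  expect_equal(label_s1_s2(p, 130)[1], "S1")
  expect_equal(label_s1_s2(q, 130)[1], "S1")
  # equal gaps are unlabelable (exactly representable times)
  expect_error(label_s1_s2((0:5) * 0.5, 75), "ambiguous")
})

test_that("time reversal swaps the S1/S2 labels", {
  p <- cumsum(c(0, rep(c(0.3, 0.5), 5)))
  fwd <- label_s1_s2(p, 75)
  rev_p <- rev(max(p) - p)
  bwd <- label_s1_s2(rev_p, 75)
  expect_equal(rev(bwd), ifelse(fwd == "S1", "S2", "S1"))
})

test_that("duration boundaries come from the 10% Shannon-energy crossing", {
  # triangular raw-energy peak crossing 10% at +/- 30 ms
  hop <- 0.01
  n <- 121
  times <- (seq_len(n) - 1) * hop
  peak_t <- 0.6
  es <- pmax(0, 1 - abs(times - peak_t) / 0.0333)
  env <- structure(list(values = (es - mean(es)) / sd(es), es = es,
                        times = times, frame_ms = 20, hop_ms = 10, rate = 2000),
                   class = "pcg_envelope")
  inst <- data.frame(time = c(0.2, peak_t, 1.0),
                     label = c("S1", "S2", "S1"))
  cyc <- locate_durations(env, inst)
  expect_equal(nrow(cyc), 1L)
  # 10% crossing at 30 ms; frame grid quantizes to the next frame outside
  expect_equal(cyc$s2_end - cyc$s2_start, 0.06, tolerance = 0.021)
  expect_true(abs((cyc$s2_start + cyc$s2_end) / 2 - peak_t) <= 0.011)
  # flat envelope never crossing 10%: clamped to the full window and flagged
  env$es <- rep(1, n)
  cyc2 <- locate_durations(env, inst)
  expect_equal(cyc2$s2_end - cyc2$s2_start, 0.10, tolerance = 0.011)
  expect_true(all(cyc2$clamped))
})

test_that("closed-valve intervals derive from the sound boundaries", {
  sim <- synthesize_pcg(heart_rate = 90, duration = 10, seed = 3)
  seg <- segment_pcg(denoise_pcg(normalize_amplitude(sim$signal)))
  cyc <- seg$cycles
  expect_gt(nrow(cyc), 5L)
  expect_true(all(cyc$cav_start == cyc$s1_end))
  expect_true(all(cyc$cav_end == cyc$s2_start))
  expect_true(all(cyc$csv_start == cyc$s2_end))
  expect_true(all(cyc$cav_start < cyc$cav_end))
  expect_true(all(cyc$csv_start < cyc$csv_end))
})

test_that("segmentation recovers instants on normal and murmur recordings", {
  for (mur in c(0, 1.0)) {
    sim <- synthesize_pcg(heart_rate = 90, duration = 20, murmur_level = mur,
                          seed = 31)
    seg <- segment_pcg(denoise_pcg(normalize_amplitude(sim$signal)))
    truth <- c(rbind(sim$truth$s1_instant, sim$truth$s2_instant))
    err <- vapply(truth, function(t) min(abs(seg$instants$time - t)), numeric(1))
    expect_gte(mean(err <= 0.02), 0.95)
    expect_lt(abs(seg$heart_rate - 90), 2)
  }
})

test_that("estimated heart rate tracks the simulated rate across regimes", {
  for (hr in c(60, 100, 143)) {
    sim <- synthesize_pcg(heart_rate = hr, duration = 20, seed = 17)
    seg <- segment_pcg(denoise_pcg(normalize_amplitude(sim$signal)))
    expect_lt(abs(seg$heart_rate - hr), 2)
    gaps <- diff(seg$instants$time)
    expect_true(all(gaps > 0.18))
  }
})

test_that("a one-beat recording is rejected as insufficient", {
  sim <- synthesize_pcg(heart_rate = 60, duration = 1.05, seed = 2)
  expect_error(segment_pcg(denoise_pcg(normalize_amplitude(sim$signal))),
               "insufficient beats")
})
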