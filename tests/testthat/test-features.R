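mk_cycles <- function(...) {
  # convenience: cycles data frame from named interval times
  df <- data.frame(...)
  df$clamped <- FALSE
  df
}

test_that("time features follow direct interval arithmetic and averaging", {
  fs <- 10
  x <- pcg_signal(c(0, 0.2, -0.4, 0.1, 0, 0.5, -0.1, 0, 0, 0), fs)
  cyc <- mk_cycles(cycle = 1, s1_start = 0, s1_end = 0.1, s2_start = 0.4,
                   s2_end = 0.5, cav_start = 0.1, cav_end = 0.4,
                   csv_start = 0.5, csv_end = 0.7)
  f <- time_features(x, cyc)
  expect_equal(unname(f[c("cav_max", "cav_min", "cav_meanabs")]),
               c(0.2, -0.4, mean(c(0.2, 0.4, 0.1))))
  expect_equal(unname(f[c("csv_max", "csv_min")]), c(0.5, -0.1))

  # two cycles average their per-cycle values
  x2 <- pcg_signal(c(0.2, 0.2, 0.1, 0.1, 0.4, 0.4, 0.3, 0.3), 4)
  cyc2 <- mk_cycles(cycle = 1:2, s1_start = c(0, 1), s1_end = c(0, 1),
                    s2_start = c(0.5, 1.5), s2_end = c(0.5, 1.5),
                    cav_start = c(0, 1), cav_end = c(0.5, 1.5),
                    csv_start = c(0.5, 1.5), csv_end = c(1, 2))
  expect_equal(unname(time_features(x2, cyc2)["cav_max"]), 0.3)

  # an all-zero diastole yields null CSV features
  x3 <- pcg_signal(c(1, -1, 1, -1, 0, 0, 0, 0), 4)
  cyc3 <- mk_cycles(cycle = 1, s1_start = 0, s1_end = 0, s2_start = 1,
                    s2_end = 1, cav_start = 0, cav_end = 1,
                    csv_start = 1, csv_end = 2)
  expect_equal(unname(time_features(x3, cyc3)[c("csv_max", "csv_min", "csv_meanabs")]),
               c(0, 0, 0))
})

test_that("Welch PSD locates tones, vanishes on silence, flattens on noise", {
  fs <- 2000
  t <- (0:999) / fs
  w <- welch_psd(sin(2 * pi * 200 * t), fs)
  expect_equal(w$freq[which.max(w$psd)], 200, tolerance = fs / 128 / 2)
  expect_true(all(w$psd >= 0))
  expect_equal(welch_psd(numeric(64), fs)$psd, rep(0, 33))
  expect_error(welch_psd(rnorm(5), fs), "too short")
  # averaging more segments shrinks the spread of a white-noise PSD
  set.seed(9)
  cv <- function(n) {
    p <- welch_psd(rnorm(n), fs)$psd
    sd(p) / mean(p)
  }
  cv_short <- mean(replicate(20, cv(256)))
  cv_long <- mean(replicate(20, cv(8192)))
  expect_lt(cv_long, cv_short / 2)
})

test_that("spectral features separate a tonal systole from a silent diastole", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  x <- pcg_signal(sin(2 * pi * 300 * t) * (t >= 0.2 & t < 0.8), fs)
  cyc <- mk_cycles(cycle = 1, s1_start = 0.1, s1_end = 0.2, s2_start = 0.8,
                   s2_end = 0.9, cav_start = 0.2, cav_end = 0.8,
                   csv_start = 0.9, csv_end = 1.7)
  f <- freq_features(x, cyc)
  expect_gt(f[["cav_psd_max"]], 100 * f[["csv_psd_max"]])
  expect_lt(f[["csv_psd_mean"]], 1e-6)
  # identical content in both intervals gives identical features
  y <- pcg_signal(rep(sin(2 * pi * 150 * (0:399) / fs), 5), fs)
  cyc2 <- mk_cycles(cycle = 1, s1_start = 0, s1_end = 0, s2_start = 0.2,
                    s2_end = 0.2, cav_start = 0, cav_end = 0.2,
                    csv_start = 0.2, csv_end = 0.4)
  f2 <- freq_features(y, cyc2)
  expect_equal(f2[["cav_psd_max"]], f2[["csv_psd_max"]], tolerance = 1e-9)
  expect_equal(f2[["cav_psd_mean"]], f2[["csv_psd_mean"]], tolerance = 1e-9)
})

test_that("the feature vector has 10 entries, is deterministic and homogeneous", {
  sim <- synthesize_pcg(heart_rate = 95, duration = 12, murmur_level = 0.8,
                        seed = 13)
  den <- denoise_pcg(normalize_amplitude(sim$signal))
  seg <- segment_pcg(den)
  f1 <- pcg_features(den, seg)
  expect_length(f1, 10L)
  expect_named(f1, pcg_feature_names)
  expect_true(all(is.finite(f1)))
  expect_identical(f1, pcg_features(den, seg))
  # amplitude scaling by c scales time features by c and PSD features by c^2
  cc <- 2.5
  scaled <- pcg_signal(den$samples * cc, den$rate)
  f2 <- pcg_features(scaled, seg)
  expect_equal(unname(f2[1:6]), unname(cc * f1[1:6]), tolerance = 1e-10)
  expect_equal(unname(f2[7:10]), unname(cc^2 * f1[7:10]), tolerance = 1e-10)
})

test_that("murmur recordings show larger systolic features than normals", {
  # rank-sum comparison on two simulated groups
  feat <- function(mur, seed) {
    sim <- synthesize_pcg(heart_rate = 100, duration = 10, murmur_level = mur,
                          seed = seed)
    den <- denoise_pcg(normalize_amplitude(sim$signal))
    pcg_features(den, segment_pcg(den))
  }
  normals <- t(vapply(1:20, function(s) feat(0, 100 + s), numeric(10)))
  murmurs <- t(vapply(1:20, function(s) feat(1.0, 200 + s), numeric(10)))
  for (col in c("cav_meanabs", "cav_psd_mean")) {
    p <- wilcox.test(murmurs[, col], normals[, col],
                     alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
  # systolic murmurs raise CAV spectral power above CSV
  expect_gt(mean(murmurs[, "cav_psd_mean"] > murmurs[, "csv_psd_mean"]), 0.9)
})
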