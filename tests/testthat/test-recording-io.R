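make_rec <- function(n_s = 120, seed = 1) {
  set.seed(seed)
  t100 <- seq(0, n_s - 0.01, by = 0.01)
  abp <- 100 + 15 * sin(2 * pi * 2 * t100) + rnorm(length(t100), 0, 0.5)
  icp <- 10 + sin(2 * pi * 2 * t100) + rnorm(length(t100), 0, 0.2)
  t1 <- seq(0, n_s - 1, by = 1)
  raw_recording(
    "nhp01", "fentanyl",
    channels = list(
      abp = list(t = t100, v = abp, units = "mmHg"),
      icp = list(t = t100, v = icp, units = "mmHg"),
      alpha_db = list(t = t1, v = 2e-8 * (1 + 0.05 * rnorm(n_s)),
                      units = "cm^2/s"),
      beta = list(t = t1, v = 0.5 + 0.004 * rnorm(n_s), units = "")),
    markers = data.frame(t_start = 0, t_end = n_s, kind = "baseline",
                         freq_hz = 0, icp_target_mmhg = 10),
    vitals = data.frame(t = c(0, 30, 60), heart_rate_bpm = c(118, 121, 119),
                        etco2_mmhg = c(38, 39, 38.5)))
}

test_that("write followed by read reproduces every value and marker", {
  rec <- make_rec()
  dir <- file.path(tempdir(), "rec-roundtrip")
  write_recording(rec, dir)
  back <- read_recording(dir)
  for (nm in names(rec$channels)) {
    expect_equal(back$channels[[nm]]$t, rec$channels[[nm]]$t)
    expect_equal(back$channels[[nm]]$v, rec$channels[[nm]]$v)
  }
  expect_equal(back$markers$t_start, rec$markers$t_start)
  expect_equal(back$markers$kind, rec$markers$kind)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$group, rec$group)
  expect_false(back$pressure_only)
})

test_that("non-monotonic timestamps are rejected naming the first bad row", {
  t <- c(0, 1, 2, 1.5, 3)
  expect_error(
    raw_recording("x", "fentanyl",
                  channels = list(abp = list(t = t, v = rep(80, 5),
                                             units = "mmHg"))),
    "row 4")
})

test_that("a recording without pressures is a hard error, without optics is pressure-only", {
  dir <- file.path(tempdir(), "rec-degraded")
  rec <- make_rec()
  rec$channels$alpha_db <- NULL
  rec$channels$beta <- NULL
  rec$pressure_only <- TRUE
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_true(back$pressure_only)
  unlink(file.path(dir, "pressures.tsv"))
  expect_error(read_recording(dir), "mandatory")
})

test_that("beat pressures recover sinusoid extrema and degenerate cases", {
  # constant waveform: flat-line warning, systolic equals diastolic
  expect_warning(bp <- estimate_beat_pressures(rep(80, 500), 100), "flat")
  expect_equal(bp$systolic, bp$diastolic)
  # 2 Hz sinusoid 100 +/- 20: every 2-s window sees full cycles
  t <- seq(0, 9.99, by = 0.01)
  bp <- estimate_beat_pressures(100 + 20 * sin(2 * pi * 2 * t), 100)
  # discrete 100 Hz sampling sits within one sample of the true extrema
  expect_true(all(abs(bp$systolic - 120) < 0.05))
  expect_true(all(abs(bp$diastolic - 80) < 0.05))
  # single half-sine beat on a zero baseline
  x <- numeric(400)
  x[101:150] <- 60 * sin(pi * (1:50) / 50)
  bp <- estimate_beat_pressures(x, 100)
  expect_equal(max(bp$systolic), 60, tolerance = 1e-6)
  expect_equal(min(bp$diastolic), 0)
})

test_that("MAP follows the 2/3 diastolic + 1/3 systolic rule", {
  expect_equal(compute_map(120, 60), 80)
  expect_equal(compute_map(90, 90), 90)
  expect_equal(compute_map(120, 80), 93.3333333, tolerance = 1e-6)
  expect_error(compute_map(80, 120), "systolic")
})

test_that("CPP is the elementwise MAP-ICP difference and conserves MAP", {
  expect_equal(compute_cpp(80, 10), 70)
  expect_equal(compute_cpp(85, 0), 85)
  expect_equal(compute_cpp(c(80, 90), c(40, 45)), c(40, 45))
  expect_error(compute_cpp(1:3, 1:2), "length")
  set.seed(3)
  m <- rnorm(100, 90, 5); i <- rnorm(100, 10, 2)
  expect_equal(compute_cpp(m, i) + i, m)
})

test_that("fractional flow change is referenced to the baseline-window mean", {
  a <- rep(2, 100)
  expect_equal(compute_delta_cbf(a), rep(0, 100))
  a2 <- c(rep(2, 70), rep(4, 30))
  d <- compute_delta_cbf(a2, baseline_window = 69)
  expect_equal(d[100], 1.0)
  a3 <- c(1, 3, rep(2, 60), 3)
  d3 <- compute_delta_cbf(a3, baseline_window = 61)
  expect_equal(d3[length(a3)], 0.5)
  expect_error(compute_delta_cbf(rep(0, 100)), "non-positive")
})

test_that("beta quality mask applies the z and median-drop rules jointly", {
  expect_warning(m <- beta_quality_mask(rep(0.5, 5)), "fewer than 10")
  expect_false(any(m))
  # constant series: zero variance, z defined as 0, nothing rejected
  expect_false(any(beta_quality_mask(rep(0.5, 50))))
  # one sample 0.02 below an otherwise constant median
  b <- rep(0.5, 50); b[17] <- 0.48
  m <- beta_quality_mask(b)
  expect_true(m[17])
  # a 10-SD spike is caught by the z rule even above the median
  set.seed(4)
  b2 <- 0.5 + rnorm(200, 0, 0.002)
  b2[60] <- 0.5 + 10 * 0.002 * 10
  m2 <- beta_quality_mask(b2)
  expect_true(m2[60])
  z <- (b2 - mean(b2)) / sd(b2)
  expect_equal(m2, abs(z) > 0.5 | b2 < median(b2) - 0.01)
  # idempotence: masking decisions do not change when reapplied
  expect_identical(beta_quality_mask(b2), m2)
})

test_that("alignment produces a 5 Hz grid with block-averaged pressures", {
  rec <- make_rec(n_s = 60)
  s <- align_resample(rec)
  expect_equal(s$sample_rate, 5)
  expect_equal(length(s$t), 60 * 5)
  expect_equal(s$cpp, s$map - s$icp)
  # a constant channel survives block averaging exactly
  rec2 <- make_rec(n_s = 60)
  rec2$channels$icp$v <- rep(12, length(rec2$channels$icp$v))
  s2 <- align_resample(rec2)
  expect_equal(unique(s2$icp), 12)
  # ramp: first output value is the mean of the first 20 waveform samples
  n <- 1000
  ramp <- seq(0, 1, length.out = n)
  rec3 <- raw_recording("r", "fentanyl", channels = list(
    abp = list(t = seq(0, 9.99, by = 0.01), v = rep(100, n), units = "mmHg"),
    icp = list(t = seq(0, 9.99, by = 0.01), v = ramp, units = "mmHg")))
  s3 <- suppressWarnings(align_resample(rec3))
  expect_equal(s3$icp[1], mean(ramp[1:20]))
  expect_equal(s3$icp[2], mean(ramp[21:40]))
})

test_that("alignment refuses pressure channels with under 50% overlap", {
  t <- seq(0, 99.99, by = 0.01)
  rec <- raw_recording("r", "fentanyl", channels = list(
    abp = list(t = t, v = rep(100, length(t)), units = "mmHg"),
    icp = list(t = t + 80, v = rep(10, length(t)), units = "mmHg")))
  expect_error(align_resample(rec), "overlap")
})

test_that("10-s binning drops partial bins, excludes masked samples", {
  s <- make_aligned(rep(7, 50), dcbf = rep(7, 50))
  b <- bin_average(s)
  expect_length(b$map, 1)
  expect_equal(b$map, 7)
  expect_equal(b$n_valid, 50L)
  # 75 samples: one full bin, remnant dropped
  s2 <- make_aligned(rnorm(75, 90))
  expect_length(bin_average(s2)$map, 1)
  # ramp bins equal consecutive 50-sample block means
  ramp <- seq_len(500)
  s3 <- make_aligned(ramp, dcbf = ramp)
  b3 <- bin_average(s3)
  expect_equal(b3$map, colMeans(matrix(ramp, nrow = 50)))
  # beta-masked samples leave the flow mean but not the pressure mean
  rej <- rep(FALSE, 50); rej[1:10] <- TRUE
  s4 <- make_aligned(rep(90, 50), dcbf = c(rep(100, 10), rep(1, 40)),
                     beta_reject = rej)
  b4 <- bin_average(s4)
  expect_equal(b4$dcbf, 1)
  expect_equal(b4$n_valid, 40L)
  expect_equal(b4$map, 90)
})

test_that("rebinning bin means at the same width is the identity", {
  set.seed(5)
  s <- make_aligned(rnorm(500, 90, 5), dcbf = rnorm(500))
  b <- bin_average(s)
  s2 <- make_aligned(b$map, icp = b$icp, dcbf = b$dcbf, sample_rate = 0.1)
  b2 <- bin_average(s2, 10)
  expect_equal(b2$map, b$map)
  expect_equal(b2$dcbf, b$dcbf)
})

test_that("flow outlier rejection is a strict two-SD rule over bins", {
  b <- make_binned(rep(70, 20), rep(0.5, 20))
  expect_false(any(cbf_outlier_mask(b)$cbf_outlier))
  set.seed(6)
  v <- rnorm(50)
  v[13] <- 5
  b2 <- make_binned(rep(70, 50), v)
  m <- cbf_outlier_mask(b2)$cbf_outlier
  expect_true(m[13])
  # strict inequality: the mask is exactly |z| > 2, so a bin at the
  # threshold is kept
  expect_equal(m, abs((v - mean(v)) / sd(v)) > 2)
  v3 <- v
  v3[13] <- mean(v[-13]) + 2 * sd(v)  # near-threshold, not beyond
  b3 <- make_binned(rep(70, 50), v3)
  expect_false(cbf_outlier_mask(b3)$cbf_outlier[13] &&
                 abs(zscore(v3)[13]) <= 2)
})
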