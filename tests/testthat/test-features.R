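test_that("mean SCL is the arithmetic mean of the tonic trace", {
  expect_equal(mean_scl(rep(6.55, 100)), 6.55)
  expect_equal(mean_scl(c(4, 6, 8)), 6)
  d <- decompose_eda(rep(5, 32 * 60), fs = 32)
  expect_equal(mean_scl(d), 5, tolerance = 1e-3)
  expect_error(mean_scl(numeric(0)), "empty")
})

test_that("SCR summary returns count and zero-safe mean amplitude", {
  none <- scr_features(data.frame(peak_time_s = numeric(0),
                                  amplitude = numeric(0)))
  expect_equal(none$count, 0)
  expect_equal(none$mean_amplitude, 0)
  two <- scr_features(data.frame(peak_time_s = c(1, 2),
                                 amplitude = c(0.02, 0.04)))
  expect_equal(two$count, 2)
  expect_equal(two$mean_amplitude, 0.03)
})

test_that("sympathetic band power recovers sinusoid power and rejects noise", {
  # in-band tone of amplitude a carries power a^2/2
  x <- make_sine(0.1, 32, 512, amplitude = 0.8)
  expect_equal(edasymp(x, 32), 0.8^2 / 2, tolerance = 0.1 * 0.8^2 / 2)

  # out-of-band tone leaks < 5 % of its power into the band
  x5 <- make_sine(0.5, 32, 512)
  expect_lt(edasymp(x5, 32), 0.05 * 0.5)

  expect_lt(edasymp(rep(4.2, 32 * 300), 32), 1e-10)
  expect_error(edasymp(rep(1, 32 * 20), 32), "too short")
})

test_that("z-standardization uses baseline statistics and flags zero SD", {
  feats <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                      label = rep(c("baseline", "walk"), 2),
                      mean_scl = c(4, 8, 6, 6))
  st <- data.frame(subject_id = c("a", "b"), feature = "mean_scl",
                   mean = c(4, 6), sd = c(2, 1))
  z <- z_standardize(feats, stats = st, feature_cols = "mean_scl")
  expect_equal(z$z_mean_scl, c(0, 2, 0, 0))

  st0 <- transform(st, sd = c(0, 1))
  expect_error(z_standardize(feats, stats = st0, feature_cols = "mean_scl"),
               "zero baseline SD")

  zc <- z_standardize(feats, method = "cohort", feature_cols = "mean_scl")
  base_mean <- mean(c(4, 6))
  base_sd <- sd(c(4, 6))
  expect_equal(zc$z_mean_scl[2], (8 - base_mean) / base_sd)
})

test_that("condition differences of z-scores are shift-invariant per subject", {
  feats <- data.frame(subject_id = "a",
                      label = c("baseline", "c1", "c2"),
                      mean_scl = c(5, 7, 9))
  st <- data.frame(subject_id = "a", feature = "mean_scl", mean = 5, sd = 2)
  z1 <- z_standardize(feats, stats = st, feature_cols = "mean_scl")
  shifted <- transform(feats, mean_scl = mean_scl + 3)
  st2 <- transform(st, mean = mean + 3)
  z2 <- z_standardize(shifted, stats = st2, feature_cols = "mean_scl")
  expect_equal(diff(z1$z_mean_scl[2:3]), diff(z2$z_mean_scl[2:3]))
})

test_that("windowed baseline statistics have the documented structure", {
  prof <- subject_profile(baseline_scl = 5, scr_rate = 0.1, noise_sd = 0.02)
  sim <- simulate_recording(prof, condition_schedule("baseline", 180),
                            seed = 9)
  seg <- cut_segments(sim$recording, sim$markers)[[1]]
  seg$eda <- eda_lowpass(seg$eda, seg$fs)
  d <- decompose_eda(seg$eda, seg$fs)
  st <- baseline_window_stats(seg, d, target_duration_s = 180)
  expect_setequal(st$feature,
                  c("mean_scl", "nsscr_count", "mean_amplitude", "edasymp"))
  expect_true(all(st$sd[st$feature == "mean_scl"] > 0))
  # rescaled count mean approximates the 3-minute event count
  cnt <- st[st$feature == "nsscr_count", ]
  expect_equal(cnt$mean, nrow(sim$truth$events), tolerance = 8)
})

test_that("planted SCL offsets are estimated without bias by the pipeline", {
  spec <- cohort_spec(6, condition_schedule(c("a", "b"), 70,
                                            scl_offset = c(0, 2)),
                      seed = 13,
                      profile = subject_profile(scr_rate = 0.05,
                                                noise_sd = 0.02))
  coh <- simulate_cohort(spec)
  res <- run_cohort(coh$recordings, coh$markers, decompose = FALSE)
  m <- rm_matrix(res$features, "mean_scl", labels = c("a", "b"))
  # ramp transition dilutes the contrast by ramp_s/2 / duration
  expect_equal(mean(m[, "b"] - m[, "a"]), 2, tolerance = 0.15)
})
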