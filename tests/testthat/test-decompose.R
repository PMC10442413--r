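test_that("constant input yields a constant tonic and an empty driver", {
  d <- decompose_eda(rep(5, 32 * 60), fs = 32)
  expect_equal(mean(d$tonic), 5, tolerance = 1e-3)
  expect_lte(sum(d$driver), 1e-3)
  expect_lt(sqrt(mean((d$tonic + d$phasic + d$residual - 5)^2)), 1e-6)
})

test_that("a single planted SCR is recovered in time and amplitude", {
  fs <- 32
  prof <- subject_profile(baseline_scl = 5, drift_slope = 0.003,
                          scr_rate = 0, noise_sd = 0.005)
  sim <- simulate_recording(prof, condition_schedule("a", 60), seed = 2)
  h <- scr_kernel_response(scr_kernel(), fs, normalize = "peak")
  y <- sim$recording$eda
  drv <- numeric(length(y))
  drv[30 * fs + 1] <- 0.5
  span <- seq_len(min(length(y) - 30 * fs, length(h)))
  y[30 * fs + span] <- y[30 * fs + span] + 0.5 * h[span]

  d <- decompose_eda(eda_lowpass(y, fs), fs)
  tt <- (seq_along(y) - 1) / fs
  mass_near <- sum(d$driver[abs(tt - 30) <= 1]) / sum(d$driver)
  expect_gte(mass_near, 0.8)

  ev <- detect_scrs(d)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude - 0.5), 0.2 * 0.5)  # within 20 % of planted
  expect_equal(ev$peak_time_s, 30 + scr_kernel_peak_time(scr_kernel()),
               tolerance = 0.5)
})

test_that("the decomposition is additive and the driver non-negative", {
  prof <- subject_profile(scr_rate = 0.08, noise_sd = 0.01)
  sim <- simulate_recording(prof, condition_schedule("a", 80), seed = 5)
  yf <- eda_lowpass(sim$recording$eda, 32)
  d <- decompose_eda(yf, 32)
  expect_lt(sqrt(mean((d$tonic + d$phasic + d$residual - yf)^2)), 1e-6)
  expect_true(all(d$driver >= 0))
})

test_that("scaling input and sparsity weight by c scales the decomposition", {
  prof <- subject_profile(baseline_scl = 4, scr_rate = 0.05, noise_sd = 0.01)
  sim <- simulate_recording(prof, condition_schedule("a", 60), seed = 6)
  yf <- eda_lowpass(sim$recording$eda, 32)
  p1 <- decompose_params(tol = 1e-8)
  p2 <- decompose_params(lambda_sparsity = 3 * p1$lambda_sparsity, tol = 1e-8)
  d1 <- decompose_eda(yf, 32, p1)
  d2 <- decompose_eda(3 * yf, 32, p2)
  expect_lt(max(abs(d2$tonic - 3 * d1$tonic)), 0.02)
  expect_lt(max(abs(d2$phasic - 3 * d1$phasic)), 0.02)
})

test_that("SCR detection applies the strict amplitude threshold", {
  # two phasic bumps, amplitudes 0.005 and 0.02: only one event
  fs <- 32
  t <- (0:(fs * 40 - 1)) / fs
  h <- scr_kernel_response(scr_kernel(), fs, normalize = "peak")
  p <- numeric(length(t))
  p[10 * fs] <- 0.005
  p[25 * fs] <- 0.02
  ph <- stats::convolve(c(p, numeric(length(h))), rev(h),
                        type = "open")[seq_along(t)]
  ev <- detect_scrs(ph, fs = fs, min_amplitude = 0.01)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time_s, 25 + scr_kernel_peak_time(scr_kernel()),
               tolerance = 0.2)

  expect_equal(nrow(detect_scrs(rep(0, 1000), fs = fs)), 0)

  # count is monotone non-increasing in the threshold
  counts <- vapply(c(0.001, 0.005, 0.01, 0.05),
                   function(th) nrow(detect_scrs(ph, fs = fs,
                                                 min_amplitude = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted SCRs well above threshold are all found, none invented", {
  prof <- subject_profile(baseline_scl = 5, scr_rate = 0, noise_sd = 0.01)
  sim <- simulate_recording(prof, condition_schedule("a", 90), seed = 7)
  fs <- 32
  y <- sim$recording$eda
  h <- scr_kernel_response(scr_kernel(), fs, normalize = "peak")
  times <- c(10, 25, 40, 60, 75)
  for (tm in times) {
    span <- seq_len(min(length(y) - tm * fs, length(h)))
    y[tm * fs + span] <- y[tm * fs + span] + 0.3 * h[span]
  }
  d <- decompose_eda(eda_lowpass(y, fs), fs)
  ev <- detect_scrs(d)
  sc <- score_scr_detection(ev, times)
  expect_equal(sc$n_matched, 5)
  expect_equal(sc$fdr, 0)
})
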