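test_that("SCR kernel response matches its closed-form shape", {
  k <- scr_kernel(tau_rise = 0.7, tau_decay = 2.0)
  h <- scr_kernel_response(k, fs = 128, duration = 15)
  expect_equal(h[1], 0)
  expect_true(all(h >= 0))
  expect_lt(h[length(h)], 1e-3)

  # argmax of the sampled response vs the closed form
  t_star <- scr_kernel_peak_time(k)
  expect_equal((which.max(h) - 1) / 128, t_star, tolerance = 1 / 128)

  k2 <- scr_kernel(tau_rise = 0.7, tau_decay = 2.0, gain = 2)
  expect_equal(scr_kernel_response(k2, 32), 2 * scr_kernel_response(k, 32))
  expect_error(scr_kernel(tau_rise = 2, tau_decay = 1), "tau_rise")
})

test_that("simulation with all stochastic parts off returns the tonic", {
  prof <- subject_profile(baseline_scl = 4.2, drift_slope = 0, scr_rate = 0,
                          noise_sd = 0)
  sim <- simulate_recording(prof, condition_schedule("a", 30), seed = 1)
  expect_equal(sim$recording$eda, rep(4.2, 30 * 32))
  expect_equal(sim$recording$eda, sim$truth$tonic)
})

test_that("identical seeds give bit-identical recordings", {
  prof <- subject_profile()
  sched <- condition_schedule(c("a", "b"), 30, scl_offset = c(0, 1))
  s1 <- simulate_recording(prof, sched, seed = 99)
  s2 <- simulate_recording(prof, sched, seed = 99)
  expect_identical(s1$recording$eda, s2$recording$eda)
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- simulate_recording(prof, sched, seed = 100)
  expect_false(identical(s1$recording$eda, s3$recording$eda))
})

test_that("event counts follow the Poisson law despite the spacing floor", {
  # Monte-Carlo mean against Poisson(rate * duration)
  rate <- 0.1
  dur <- 300
  counts <- vapply(1:200, function(s) {
    set.seed(s)
    length(crowdeda:::poisson_times_min_gap(rate, dur, min_gap = 1))
  }, numeric(1))
  expect_lt(abs(mean(counts) - rate * dur), 3 * sqrt(rate * dur) / sqrt(200))

  # chi-square goodness of fit over 500 seeds
  set.seed(2024)
  counts <- replicate(500, length(crowdeda:::poisson_times_min_gap(rate, dur)))
  brk <- c(-Inf, 20:40, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(c(-1, 20:40, Inf), rate * dur))
  keep <- pr * 500 >= 1
  gof <- suppressWarnings(chisq.test(as.numeric(obs[keep]), p = pr[keep] / sum(pr[keep])))
  expect_gt(gof$p.value, 0.01)

  # spacing floor is honoured
  set.seed(5)
  for (i in 1:50) {
    tt <- crowdeda:::poisson_times_min_gap(0.3, 120, min_gap = 1)
    if (length(tt) > 1) expect_true(all(diff(tt) >= 1))
  }
})

test_that("artifact injection implements the three failure modes", {
  prof <- subject_profile(baseline_scl = 5, scr_rate = 0, noise_sd = 0.01)
  sim <- simulate_recording(prof, condition_schedule("a", 30), seed = 3)
  rec <- sim$recording

  out <- inject_artifacts(rec, data.frame(type = "dropout", start_s = 10,
                                          end_s = 15))
  tt <- recording_times(out$recording)
  inside <- tt >= 10 & tt < 15
  expect_true(all(out$recording$eda[inside] == 0))
  expect_gt(mean(out$recording$acc[inside]), mean(rec$acc[!inside]) + 1)

  none <- inject_artifacts(rec, data.frame(type = character(0),
                                           start_s = numeric(0),
                                           end_s = numeric(0)))
  expect_identical(none$recording$eda, rec$eda)

  sp <- inject_artifacts(rec, data.frame(type = "spike", start_s = 5,
                                         end_s = 6), spike_uS = 5)
  jump <- max(abs(diff(sp$recording$eda))) * rec$fs
  expect_gte(jump, 5 * 32 * 0.99)  # one-sample slope of at least 160 µS/s

  expect_error(inject_artifacts(rec, data.frame(type = c("spike", "dropout"),
                                                start_s = c(5, 5.5),
                                                end_s = c(6, 7))),
               "overlapping")
})

test_that("cohorts have per-subject markers and between-subject variance", {
  spec <- cohort_spec(5, condition_schedule(c("a", "b", "c"), 30,
                                            scl_offset = c(0, 2, 1)),
                      seed = 11)
  coh <- simulate_cohort(spec)
  expect_length(coh$recordings, 5)
  expect_equal(nrow(coh$markers), 15)
  base <- vapply(coh$truth, function(tr) tr$tonic[1], numeric(1))
  expect_gt(sd(base), 0)
})

test_that("planted condition offsets appear exactly in noiseless cohorts", {
  spec <- cohort_spec(3, condition_schedule(c("a", "b"), 40,
                                            scl_offset = c(0, 2)),
                      seed = 12,
                      profile = subject_profile(scr_rate = 0, noise_sd = 0))
  coh <- simulate_cohort(spec)
  for (rec in coh$recordings) {
    segs <- cut_segments(rec, coh$markers)
    # compare steady levels away from the boundary ramp
    a <- mean(segs[[1]]$eda[1:(20 * 32)])
    b <- mean(segs[[2]]$eda[(10 * 32):(40 * 32 - 320)])
    expect_equal(b - a, 2, tolerance = 1e-10)
  }
})
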