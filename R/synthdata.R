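#' Biexponential (Bateman) SCR kernel
#'
#' The impulse response used both to synthesize skin-conductance responses
#' and as the convolution kernel of the sparse-driver decomposition:
#' `h(t) = gain * (exp(-t/tau_decay) - exp(-t/tau_rise))`, which starts at 0,
#' rises with time constant `tau_rise` and decays with `tau_decay`.
#'
#' @param tau_rise Rise time constant in s (must be < `tau_decay`).
#' @param tau_decay Decay time constant in s.
#' @param gain Dimensionless multiplier.
#' @return An object of class `scr_kernel`.
#' @export
scr_kernel <- function(tau_rise = 0.7, tau_decay = 2.0, gain = 1) {
  if (!(tau_rise > 0 && tau_decay > tau_rise)) {
    stop("need 0 < tau_rise < tau_decay")
  }
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, gain = gain),
            class = "scr_kernel")
}

#' Sampled impulse response of an SCR kernel
#'
#' @param k An [scr_kernel()].
#' @param fs Sampling rate in Hz.
#' @param duration Length of the sampled response in s; at least
#'   `5 * tau_decay` is recommended so the tail is negligible.
#' @param normalize If `"peak"`, the response is scaled to unit maximum
#'   (so a unit driver impulse produces a phasic deflection of 1 µS peak);
#'   `"none"` returns the raw biexponential times `gain`.
#' @return Numeric vector `h` with `h[1] = 0`, `h >= 0`, decaying to 0.
#' @export
scr_kernel_response <- function(k, fs, duration = 5 * k$tau_decay,
                                normalize = c("none", "peak")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(k, "scr_kernel"), fs > 0, duration > 0)
  t <- seq(0, duration, by = 1 / fs)
  h <- k$gain * (exp(-t / k$tau_decay) - exp(-t / k$tau_rise))
  if (normalize == "peak") h <- h / max(h)
  h
}

#' Time of the kernel maximum (closed form)
#' @param k An [scr_kernel()].
#' @return Peak time `tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)` in s.
#' @export
scr_kernel_peak_time <- function(k) {
  with(k, tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise))
}

#' Subject profile for the synthetic generator
#'
#' Magnitudes are chosen to resemble ambulatory palmar recordings: tonic
#' levels of a few µS, spontaneous response amplitudes of tenths of µS, and
#' sensor noise well below response amplitude. `cond_sd` adds a per-condition
#' tonic fluctuation (a subject's resting level differs between runs), which
#' is what gives repeated-measures tests a realistic within-subject error.
#'
#' @param baseline_scl Tonic level in µS (> 0).
#' @param drift_slope Slow tonic drift in µS/s.
#' @param scr_rate Spontaneous SCR rate in events/s (scaled per condition).
#' @param scr_amp_mean,scr_amp_sd Mean and SD of SCR peak amplitudes in µS.
#' @param noise_sd Gaussian measurement noise SD in µS.
#' @param cond_sd SD of the per-condition random tonic offset in µS.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(baseline_scl = 6, drift_slope = 0,
                            scr_rate = 0.1, scr_amp_mean = 0.3,
                            scr_amp_sd = 0.1, noise_sd = 0.02,
                            cond_sd = 0) {
  stopifnot(baseline_scl > 0, scr_rate >= 0, noise_sd >= 0, cond_sd >= 0)
  structure(list(baseline_scl = baseline_scl, drift_slope = drift_slope,
                 scr_rate = scr_rate, scr_amp_mean = scr_amp_mean,
                 scr_amp_sd = scr_amp_sd, noise_sd = noise_sd,
                 cond_sd = cond_sd),
            class = "subject_profile")
}

#' Condition schedule for one simulated recording
#'
#' @param label Condition labels (character).
#' @param duration_s Duration of each condition in s (> 0).
#' @param scl_offset Additive tonic offset per condition in µS.
#' @param rate_mult Multiplier on the profile's SCR rate per condition.
#' @return Data frame with one row per condition, in temporal order.
#' @export
condition_schedule <- function(label, duration_s, scl_offset = 0, rate_mult = 1) {
  stopifnot(all(duration_s > 0))
  data.frame(label = as.character(label), duration_s = duration_s,
             scl_offset = rep_len(scl_offset, length(label)),
             rate_mult = rep_len(rate_mult, length(label)))
}

# Poisson event times with a minimum spacing. The count is drawn first
# (exactly Poisson(rate * duration)), then the points are placed as sorted
# uniforms on the gap-reduced interval plus deterministic offsets, so the
# count distribution is untouched while consecutive events stay >= min_gap
# apart (possible whenever (n-1)*min_gap < duration; overflowing counts are
# truncated, which at the rates used here never triggers).
poisson_times_min_gap <- function(rate, duration, min_gap = 1) {
  n <- stats::rpois(1L, rate * duration)
  n_max <- floor(duration / min_gap)
  if (n > n_max) n <- n_max
  if (n == 0L) return(numeric(0))
  slack <- duration - (n - 1) * min_gap
  sort(stats::runif(n, 0, slack)) + min_gap * (seq_len(n) - 1)
}

#' Simulate one EDA recording with ground truth
#'
#' The conductance trace is the sum of a continuous tonic component
#' (baseline + linear drift + per-condition offsets, ramped over
#' `ramp_s` seconds so the tonic stays continuous at condition changes),
#' a phasic component (Poisson-timed driver impulses convolved with the
#' peak-normalized kernel, so planted amplitudes are phasic peak heights in
#' µS), and white Gaussian noise. An accelerometer channel around 1 g with
#' small jitter is attached. The same seed always reproduces the same
#' recording bit for bit.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [condition_schedule()].
#' @param kernel An [scr_kernel()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param subject_id Subject label.
#' @param ramp_s Length of the linear ramp smoothing condition offsets, s.
#' @param min_gap Minimum spacing between SCR events in s.
#' @param tonic_floor Lower clip of the tonic trace in µS (skin conductance
#'   cannot fall below a small positive level).
#' @return A list with elements `recording` (an [eda_recording()]),
#'   `markers` (condition marker rows) and `truth` (list with `events`
#'   data frame, `tonic` trace, `artifacts` data frame).
#' @export
simulate_recording <- function(profile, schedule, kernel = scr_kernel(),
                               fs = 32, seed = 1, subject_id = "s1",
                               ramp_s = 4, min_gap = 1, tonic_floor = 0.5) {
  stopifnot(inherits(profile, "subject_profile"), all(schedule$duration_s > 0))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_per <- round(schedule$duration_s * fs)
  n <- sum(n_per)
  t <- (seq_len(n) - 1) / fs
  starts_s <- cumsum(c(0, schedule$duration_s[-nrow(schedule)]))

  # tonic: baseline + drift + smoothed per-condition offsets
  cond_off <- schedule$scl_offset +
    if (profile$cond_sd > 0) stats::rnorm(nrow(schedule), 0, profile$cond_sd) else 0
  step <- rep(cond_off, times = n_per)
  # linear ramp of width ramp_s centred on each condition boundary
  w <- max(1L, round(ramp_s * fs))
  if (w > 1L && nrow(schedule) > 1L) {
    bounds <- cumsum(n_per)[-nrow(schedule)]
    for (j in seq_along(bounds)) {
      i0 <- max(1L, bounds[j] - w %/% 2L + 1L)
      i1 <- min(n, bounds[j] + w %/% 2L)
      step[i0:i1] <- cond_off[j] +
        (cond_off[j + 1] - cond_off[j]) * seq_len(i1 - i0 + 1L) / (i1 - i0 + 1L)
    }
  }
  tonic <- pmax(tonic_floor, profile$baseline_scl + profile$drift_slope * t + step)

  # phasic: Poisson events per condition at the condition's rate
  ev_list <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    rate <- profile$scr_rate * schedule$rate_mult[i]
    times <- if (rate > 0) {
      starts_s[i] + poisson_times_min_gap(rate, schedule$duration_s[i], min_gap)
    } else numeric(0)
    amps <- pmax(0.01, stats::rnorm(length(times), profile$scr_amp_mean,
                                    profile$scr_amp_sd))
    ev_list[[i]] <- data.frame(label = rep(schedule$label[i], length(times)),
                               time_s = times, amplitude = amps)
  }
  events <- do.call(rbind, ev_list)
  phasic <- numeric(n)
  if (nrow(events) > 0L) {
    h <- scr_kernel_response(kernel, fs, normalize = "peak")
    m <- length(h)
    idx <- pmin(n, floor(events$time_s * fs) + 1L)
    for (j in seq_along(idx)) {
      i1 <- min(n, idx[j] + m - 1L)
      span <- seq.int(idx[j], i1)
      phasic[span] <- phasic[span] + events$amplitude[j] * h[seq_along(span)]
    }
  }

  noise <- if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else numeric(n)
  acc <- 1 + stats::rnorm(n, 0, 0.05)

  rec <- eda_recording(tonic + phasic + noise, fs = fs, t0 = 0, acc = acc,
                       subject_id = subject_id)
  markers <- data.frame(subject_id = subject_id, label = schedule$label,
                        start_s = starts_s,
                        end_s = starts_s + schedule$duration_s)
  list(recording = rec, markers = condition_markers(markers),
       truth = list(events = events, tonic = tonic,
                    artifacts = data.frame(type = character(0),
                                           start_s = numeric(0),
                                           end_s = numeric(0))))
}

#' Inject wearable-sensor artifacts into a recording
#'
#' Emulates the failure modes seen in ambulatory EDA: loss of electrode
#' contact (dropout to 0 µS), saturated flat lines, and movement spikes.
#' Spike and dropout artifacts receive a synchronized burst on the
#' accelerometer channel, as motion artifacts do in practice.
#'
#' @param rec An [eda_recording()].
#' @param artifacts Data frame with columns `type` (one of `"flatline"`,
#'   `"spike"`, `"dropout"`), `start_s`, `end_s`; intervals must not overlap.
#' @param seed Integer seed (for the accelerometer burst noise).
#' @param spike_uS Spike step height in µS (>= 5 so the one-sample slope at
#'   32 Hz exceeds any plausible physiological rate of change).
#' @return A list with the modified `recording` and `truth` (the artifact
#'   table).
#' @export
inject_artifacts <- function(rec, artifacts, seed = 1, spike_uS = 6) {
  if (nrow(artifacts) == 0L) return(list(recording = rec, truth = artifacts))
  a <- artifacts[order(artifacts$start_s), , drop = FALSE]
  if (any(a$end_s <= a$start_s)) stop("artifact with end_s <= start_s")
  if (nrow(a) > 1L && any(a$start_s[-1] < a$end_s[-nrow(a)])) {
    stop("overlapping artifact intervals")
  }
  t_end <- rec$t0 + length(rec$eda) / rec$fs
  if (any(a$start_s < rec$t0) || any(a$end_s > t_end)) {
    stop("artifact interval outside recording")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  tt <- recording_times(rec)
  if (is.null(rec$acc)) rec$acc <- rep(1, length(rec$eda))
  for (i in seq_len(nrow(a))) {
    idx <- which(tt >= a$start_s[i] - 1e-9 & tt < a$end_s[i] - 1e-9)
    if (length(idx) == 0L) next
    type <- a$type[i]
    if (type == "flatline") {
      rec$eda[idx] <- rec$eda[idx[1]]
    } else if (type == "dropout") {
      rec$eda[idx] <- 0
      rec$acc[idx] <- rec$acc[idx] + abs(stats::rnorm(length(idx), 2, 0.5))
    } else if (type == "spike") {
      rec$eda[idx] <- rec$eda[idx] + spike_uS
      rec$acc[idx] <- rec$acc[idx] + abs(stats::rnorm(length(idx), 2, 0.5))
    } else {
      stop("unknown artifact type: ", type)
    }
  }
  list(recording = rec, truth = a)
}

#' Cohort specification for the synthetic generator
#'
#' Between-subject variation draws each subject's baseline tonic level from
#' a normal with the given cohort mean and SD, truncated below; subject
#' seeds are derived from the single cohort seed so any sub-simulation can
#' be reproduced in isolation.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule A [condition_schedule()] shared by all subjects.
#' @param seed Integer cohort seed.
#' @param baseline_mean,baseline_sd,baseline_min Cohort distribution of the
#'   per-subject baseline tonic level in µS (normal, truncated at
#'   `baseline_min`).
#' @param profile Template [subject_profile()]; its `baseline_scl` is
#'   replaced per subject.
#' @param kernel An [scr_kernel()].
#' @param fs Sampling rate in Hz.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, schedule, seed = 1,
                        baseline_mean = 6, baseline_sd = 3, baseline_min = 0.5,
                        profile = subject_profile(), kernel = scr_kernel(),
                        fs = 32) {
  stopifnot(n_subjects >= 1, nrow(schedule) >= 1)
  structure(list(n_subjects = as.integer(n_subjects), schedule = schedule,
                 seed = as.integer(seed), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, baseline_min = baseline_min,
                 profile = profile, kernel = kernel, fs = fs),
            class = "cohort_spec")
}

#' Simulate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list with `recordings` (list of [eda_recording()]s), `markers`
#'   (one marker data frame for the whole cohort) and `truth` (per-subject
#'   list of ground-truth objects).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  baselines <- pmax(spec$baseline_min,
                    stats::rnorm(spec$n_subjects, spec$baseline_mean, spec$baseline_sd))
  recs <- vector("list", spec$n_subjects)
  truths <- vector("list", spec$n_subjects)
  marker_list <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    prof <- spec$profile
    prof$baseline_scl <- baselines[i]
    sid <- sprintf("s%02d", i)
    sim <- simulate_recording(prof, spec$schedule, kernel = spec$kernel,
                              fs = spec$fs, seed = subj_seeds[i],
                              subject_id = sid)
    recs[[i]] <- sim$recording
    truths[[i]] <- sim$truth
    marker_list[[i]] <- sim$markers
  }
  names(recs) <- names(truths) <- vapply(recs, `[[`, "", "subject_id")
  list(recordings = recs, markers = do.call(rbind, marker_list),
       truth = truths)
}

#' Study-shaped cohort specifications
#'
#' `study1_spec` emulates the imposed-speed design: a standing baseline, a
#' free-walking condition and four imposed speeds (1.41, 0.86, 0.31,
#' 0.19 m/s), each lasting 3 minutes. Tonic offsets increase with walking
#' speed (physical activation), with the free condition highest, echoing
#' the ordering the paradigm is designed to detect.
#'
#' `study2_spec` emulates the single-file oval design: eight occupancy
#' conditions (4 to 40 walkers on a 14.97 m oval) of about 110 s each.
#' `scl_span` plants a monotone tonic gradient across the density ordering
#' (0 for a null cohort); the default span of 2.3 µS matches the magnitude
#' of the density effect the paradigm targets.
#'
#' @param n_subjects Number of subjects.
#' @param seed Cohort seed.
#' @param scl_span Planted monotone tonic span across conditions in µS.
#' @param duration_s Condition duration in s (study 2).
#' @param cond_sd Within-subject per-condition tonic SD in µS.
#' @param ... Passed on to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
study1_spec <- function(n_subjects = 17, seed = 1, cond_sd = 0.8, ...) {
  sched <- condition_schedule(
    label = c("baseline", "free", "1.41", "0.86", "0.31", "0.19"),
    duration_s = 180,
    scl_offset = c(0, 3.5, 2.4, 1.6, 1.0, 0.6),
    rate_mult = c(1, 1.5, 1.3, 1.1, 1, 1)
  )
  cohort_spec(n_subjects, sched, seed = seed,
              profile = subject_profile(scr_rate = 0.1, cond_sd = cond_sd), ...)
}

#' @rdname study1_spec
#' @export
study2_spec <- function(n_subjects = 44, seed = 1, scl_span = 2.3,
                        duration_s = 110, cond_sd = 0.8, ...) {
  n_cond <- c(4, 8, 16, 20, 24, 32, 36, 40)
  sched <- condition_schedule(
    label = paste0("n=", n_cond),
    duration_s = duration_s,
    scl_offset = seq(0, scl_span, length.out = length(n_cond)),
    rate_mult = 1
  )
  cohort_spec(n_subjects, sched, seed = seed,
              profile = subject_profile(scr_rate = 0.1, cond_sd = cond_sd), ...)
}
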