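# Zero-phase two-pass IIR filtering with odd-symmetric edge padding.
# Plain forward-backward filtering with zero initial conditions rings badly
# at the edges of a signal with a large DC level (conductance sits at
# several µS); reflecting an offset-matched copy of the signal at both ends
# lets the filter settle before it reaches real data.
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xe <- c(front, x, back)
  y <- as.numeric(signal::filter(bf, xe))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' First-order Butterworth low-pass (default cutoff 0.6 Hz) applied
#' forward and backward ([signal::filtfilt()]), so the output has no phase
#' lag relative to the condition markers. The two passes square the
#' single-pass magnitude response: the gain at the nominal cutoff is 0.5
#' rather than 1/sqrt(2). DC gain is exactly 1.
#'
#' @param eda Numeric conductance vector in µS.
#' @param fs Sampling rate in Hz (must exceed `2 * cutoff`).
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order.
#' @return Filtered vector, same length as the input.
#' @export
eda_lowpass <- function(eda, fs, cutoff = 0.6, order = 1) {
  stopifnot(fs > 2 * cutoff)
  warmup <- round(fs / cutoff)
  if (length(eda) < 3 * warmup) {
    stop(sprintf("sequence too short for filtering: %d samples, need >= %d",
                 length(eda), 3 * warmup))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_padded(bf, eda, pad = round(5 * fs / cutoff))
}

#' Resample a sequence with anti-alias filtering
#'
#' Low-passes at `0.45 * fs_out` (4th-order Butterworth, zero phase) and
#' then picks samples on the output grid (direct decimation for integer
#' ratios, linear interpolation otherwise). Used to bring 32 Hz traces to
#' the 2 Hz rate of the sympathetic band-power analysis.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output rates in Hz (`fs_out < fs_in`).
#' @return Resampled vector of length `floor((n - 1) * fs_out / fs_in) + 1`.
#' @export
eda_resample <- function(x, fs_in, fs_out) {
  if (fs_out >= fs_in) stop("fs_out must be smaller than fs_in")
  bf <- signal::butter(4, 0.45 * fs_out / (fs_in / 2), type = "low")
  xf <- filtfilt_padded(bf, x, pad = round(5 * fs_in / (0.45 * fs_out)))
  ratio <- fs_in / fs_out
  n_out <- floor((length(x) - 1) / ratio) + 1
  if (abs(ratio - round(ratio)) < 1e-9) {
    xf[seq(1, by = round(ratio), length.out = n_out)]
  } else {
    t_in <- (seq_along(x) - 1) / fs_in
    t_out <- (seq_len(n_out) - 1) / fs_out
    stats::approx(t_in, xf, xout = t_out)$y
  }
}

#' Rule set for wearable-EDA artifact screening
#'
#' Numeric thresholds follow the rule-based quality literature for wrist /
#' palm wearables: conductance outside a plausible physiological range,
#' one-sample slopes faster than skin can change, and flat stretches
#' indicating electrode saturation or loss. A flagged interval is marked
#' accelerometer-coincident when motion activity near it exceeds a robust
#' burst threshold; a segment is excluded when too much of it is flagged or
#' it contains a long flat/zero stretch.
#'
#' @param min_valid,max_valid Valid conductance range in µS.
#' @param max_slope Maximum plausible one-sample slope in µS/s.
#' @param flat_window Flatline detection window in s.
#' @param flat_eps Range below which a window counts as flat, in µS.
#' @param accel_window Coincidence window around a flagged interval in s.
#' @param max_flagged_fraction Flagged fraction above which a segment is
#'   excluded.
#' @return An object of class `artifact_rules`.
#' @export
artifact_rules <- function(min_valid = 0.05, max_valid = 60, max_slope = 10,
                           flat_window = 5, flat_eps = 1e-4,
                           accel_window = 2, max_flagged_fraction = 0.10) {
  stopifnot(min_valid < max_valid, min_valid > 0, max_slope > 0,
            flat_window > 0, flat_eps > 0, accel_window > 0,
            max_flagged_fraction > 0)
  structure(list(min_valid = min_valid, max_valid = max_valid,
                 max_slope = max_slope, flat_window = flat_window,
                 flat_eps = flat_eps, accel_window = accel_window,
                 max_flagged_fraction = max_flagged_fraction),
            class = "artifact_rules")
}

# O(n) sliding-window max/min (van Herk): value at i is the extremum over
# x[i .. i+w-1], defined for i in 1 .. n-w+1
run_max <- function(x, w) {
  n <- length(x)
  npad <- ceiling(n / w) * w
  xp <- c(x, rep(-Inf, npad - n))
  blocks <- matrix(xp, nrow = w)
  prefix <- as.numeric(apply(blocks, 2, cummax))
  suffix <- as.numeric(matrix(apply(blocks[w:1, , drop = FALSE], 2, cummax),
                              nrow = w)[w:1, , drop = FALSE])
  i <- seq_len(n - w + 1L)
  pmax(suffix[i], prefix[i + w - 1L])
}

run_min <- function(x, w) -run_max(-x, w)

# run-length encode a logical mask into (start, end) sample index intervals
mask_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Rule-based artifact detection with accelerometer coincidence
#'
#' Flags every sample that violates a rule of [artifact_rules()]:
#' out-of-range conductance, one-sample slope above `max_slope`, or
#' membership in a window of length `flat_window` whose range is below
#' `flat_eps` (flat windows are scanned with 75 % overlap). Flagged runs
#' are reported as intervals with the triggering rule; each is marked
#' accelerometer-coincident when the accelerometer magnitude within
#' `accel_window` of it exceeds its median + 3 MAD. The verdict excludes
#' the trace when the flagged fraction exceeds `max_flagged_fraction` or
#' any flat/below-range run lasts at least `flat_window`.
#'
#' @param rec An [eda_recording()] (or segment).
#' @param rules An [artifact_rules()].
#' @return An object of class `artifact_report`: list with `mask` (logical
#'   per sample), `intervals` (data frame: rule, start_s, end_s,
#'   accel_coincident), `flagged_fraction`, and `excluded`.
#' @export
detect_artifacts <- function(rec, rules = artifact_rules()) {
  x <- rec$eda
  n <- length(x)
  fs <- rec$fs

  range_mask <- x < rules$min_valid | x > rules$max_valid
  slope_mask <- c(FALSE, abs(diff(x)) * fs > rules$max_slope)

  w <- max(2L, round(rules$flat_window * fs))
  flat_mask <- rep(FALSE, n)
  if (n >= w) {
    rng <- run_max(x, w) - run_min(x, w)
    flat_starts <- which(rng < rules$flat_eps)
    if (length(flat_starts) > 0L) {
      bump <- numeric(n + 1L)
      bump[flat_starts] <- bump[flat_starts] + 1
      bump[flat_starts + w] <- bump[flat_starts + w] - 1
      flat_mask <- cumsum(bump[seq_len(n)]) > 0
    }
  }

  mask <- range_mask | slope_mask | flat_mask
  rule_masks <- list(range = range_mask, slope = slope_mask, flat = flat_mask)
  iv_list <- lapply(names(rule_masks), function(rn) {
    iv <- mask_intervals(rule_masks[[rn]])
    if (nrow(iv) == 0L) return(NULL)
    data.frame(rule = rn, start_s = rec$t0 + (iv$start - 1L) / fs,
               end_s = rec$t0 + iv$end / fs)
  })
  intervals <- do.call(rbind, iv_list)
  if (is.null(intervals)) {
    intervals <- data.frame(rule = character(0), start_s = numeric(0),
                            end_s = numeric(0))
  }

  intervals$accel_coincident <- logical(nrow(intervals))
  if (!is.null(rec$acc) && nrow(intervals) > 0L) {
    thr <- stats::median(rec$acc) + 3 * stats::mad(rec$acc)
    burst <- rec$acc > thr
    tt <- recording_times(rec)
    for (i in seq_len(nrow(intervals))) {
      near <- tt >= intervals$start_s[i] - rules$accel_window &
              tt <  intervals$end_s[i] + rules$accel_window
      intervals$accel_coincident[i] <- any(burst[near])
    }
  }

  # long flat or below-range (zero-line) run forces exclusion
  low_runs <- mask_intervals(flat_mask | x < rules$min_valid)
  long_flat <- nrow(low_runs) > 0L &&
    any((low_runs$end - low_runs$start + 1L) / fs >= rules$flat_window)
  frac <- mean(mask)

  structure(list(mask = mask, intervals = intervals,
                 flagged_fraction = frac,
                 excluded = frac > rules$max_flagged_fraction || long_flat,
                 subject_id = rec$subject_id, label = rec$label),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %.2f%% flagged, %d interval(s), %s\n",
              100 * x$flagged_fraction, nrow(x$intervals),
              if (x$excluded) "EXCLUDED" else "kept"))
  invisible(x)
}
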