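#' Mean skin conductance level of a segment
#'
#' The SCL summary of a condition segment is the arithmetic mean of the
#' tonic component of its decomposition.
#'
#' @param d An [decompose_eda()] result or a numeric tonic vector.
#' @return Mean tonic level in µS.
#' @export
mean_scl <- function(d) {
  tonic <- if (inherits(d, "eda_decomposition")) d$tonic else as.numeric(d)
  if (length(tonic) == 0L) stop("empty tonic component")
  mean(tonic)
}

#' Count and mean amplitude of detected SCRs
#'
#' @param events Data frame from [detect_scrs()].
#' @return List with `count` and `mean_amplitude` (0 when no events, so
#'   repeated-measures tables stay complete).
#' @export
scr_features <- function(events) {
  n <- nrow(events)
  list(count = n,
       mean_amplitude = if (n == 0L) 0 else mean(events$amplitude))
}

# Welch power spectral density with a Blackman window.
# Returns one-sided PSD in units^2/Hz so that integrating over frequency
# recovers the signal variance.
welch_psd <- function(x, fs, nperseg = 128, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) {
    stop(sprintf("segment too short for spectral analysis: %d samples, need >= %d",
                 n, nperseg))
  }
  w <- as.numeric(signal::blackman(nperseg))
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    X <- stats::fft((seg - mean(seg)) * w)
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  pxx <- acc / (length(starts) * fs * sum(w^2))
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (nperseg %% 2 == 0L) scale2[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = pxx * scale2)
}

#' Sympathetic band power (EDASymp)
#'
#' Downsamples the conductance trace to 2 Hz, removes the mean, estimates
#' the power spectral density by Welch's method (Blackman window, 128-sample
#' segments, 50 % overlap) and integrates it over the sympathetic band
#' 0.045-0.25 Hz by the trapezoid rule. Units are µS² ("area under the
#' curve" of the PSD); set `normalize = TRUE` for the band power as a
#' fraction of total power.
#'
#' @param x Conductance segment in µS (filtered full signal).
#' @param fs Sampling rate of `x` in Hz.
#' @param band Frequency band in Hz.
#' @param fs_target Analysis rate in Hz.
#' @param nperseg Welch segment length in samples at `fs_target`.
#' @param normalize Divide by total power?
#' @return Band power in µS² (dimensionless if normalized).
#' @export
edasymp <- function(x, fs, band = c(0.045, 0.25), fs_target = 2,
                    nperseg = 128, normalize = FALSE) {
  xs <- if (fs > fs_target) eda_resample(x, fs, fs_target) else as.numeric(x)
  xs <- xs - mean(xs)
  spec <- welch_psd(xs, fs_target, nperseg = nperseg)
  inb <- spec$freq >= band[1] & spec$freq <= band[2]
  if (sum(inb) < 2L) stop("band contains fewer than 2 frequency bins")
  f <- spec$freq[inb]
  p <- spec$psd[inb]
  bp <- sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  if (normalize) {
    tot <- sum(diff(spec$freq) * (spec$psd[-1] + spec$psd[-nrow(spec)]) / 2)
    bp <- bp / tot
  }
  bp
}

#' Feature row for one decomposed condition segment
#'
#' Computes the four study parameters of a subject x condition segment:
#' mean tonic SCL, number of Ns.SCRs (amplitude > `min_amplitude`), their
#' mean amplitude, and the sympathetic band power of the filtered signal.
#'
#' @param segment The filtered `eda_segment` the decomposition was run on.
#' @param decomp Its [decompose_eda()] result.
#' @param min_amplitude SCR amplitude threshold in µS.
#' @param edasymp_nperseg Welch segment length for [edasymp()].
#' @return One-row data frame: `subject_id`, `label`, `mean_scl`,
#'   `nsscr_count`, `mean_amplitude`, `edasymp`, `n_valid_samples`.
#' @export
segment_features <- function(segment, decomp, min_amplitude = 0.01,
                             edasymp_nperseg = 128) {
  events <- detect_scrs(decomp, min_amplitude = min_amplitude)
  sf <- scr_features(events)
  data.frame(subject_id = segment$subject_id,
             label = segment$label,
             mean_scl = mean_scl(decomp),
             nsscr_count = sf$count,
             mean_amplitude = sf$mean_amplitude,
             edasymp = edasymp(segment$eda, segment$fs,
                               nperseg = edasymp_nperseg),
             n_valid_samples = length(segment$eda))
}

#' Per-subject baseline statistics from time windows
#'
#' Estimates each subject's own baseline mean and SD per feature from
#' non-overlapping windows of the resting baseline segment, for use in
#' baseline z-standardization: `mean_scl` and `mean_amplitude` are averaged
#' per window; `nsscr_count` is a windowed count rescaled to the target
#' segment duration (mean scaled by the duration ratio, SD by its square
#' root, the Poisson scaling); `edasymp` uses its own longer window
#' (spectral estimates need at least `edasymp_window_s` of signal).
#'
#' @param segment The subject's filtered baseline `eda_segment`.
#' @param decomp Its [decompose_eda()] result.
#' @param window_s Window length in s for SCL, amplitude and counts.
#' @param edasymp_window_s Window length in s for the band-power feature.
#' @param target_duration_s Duration the count statistics are rescaled to
#'   (defaults to the baseline segment duration).
#' @param min_amplitude SCR amplitude threshold in µS.
#' @return Data frame with columns `subject_id`, `feature`, `mean`, `sd`.
#' @export
baseline_window_stats <- function(segment, decomp, window_s = 5,
                                  edasymp_window_s = 64,
                                  target_duration_s = NULL,
                                  min_amplitude = 0.01) {
  fs <- segment$fs
  n <- length(segment$eda)
  if (is.null(target_duration_s)) target_duration_s <- n / fs
  w <- round(window_s * fs)
  if (n < 2L * w) stop("baseline segment shorter than two windows")
  starts <- seq(1L, n - w + 1L, by = w)
  events <- detect_scrs(decomp, min_amplitude = min_amplitude)
  ev_idx <- floor((events$peak_time_s - segment$t0) * fs) + 1L

  scl_w <- vapply(starts, function(s) mean(decomp$tonic[s:(s + w - 1L)]),
                  numeric(1))
  cnt_w <- vapply(starts, function(s) sum(ev_idx >= s & ev_idx < s + w),
                  numeric(1))
  amp_w <- vapply(starts, function(s) {
    inw <- ev_idx >= s & ev_idx < s + w
    if (any(inw)) mean(events$amplitude[inw]) else 0
  }, numeric(1))

  k <- target_duration_s / window_s
  rows <- list(
    data.frame(feature = "mean_scl", mean = mean(scl_w), sd = stats::sd(scl_w)),
    data.frame(feature = "nsscr_count", mean = mean(cnt_w) * k,
               sd = stats::sd(cnt_w) * sqrt(k)),
    data.frame(feature = "mean_amplitude", mean = mean(amp_w),
               sd = stats::sd(amp_w))
  )

  we <- round(edasymp_window_s * fs)
  if (n >= 2L * we) {
    se <- seq(1L, n - we + 1L, by = we)
    # spectral windows are short; use a Welch segment that fits them
    nps <- 2^floor(log2(edasymp_window_s * 2))
    sym_w <- vapply(se, function(s) {
      edasymp(segment$eda[s:(s + we - 1L)], fs, nperseg = nps)
    }, numeric(1))
    rows <- c(rows, list(data.frame(feature = "edasymp", mean = mean(sym_w),
                                    sd = stats::sd(sym_w))))
  }
  out <- do.call(rbind, rows)
  out$subject_id <- segment$subject_id
  out[, c("subject_id", "feature", "mean", "sd")]
}

#' Baseline z-standardization of a feature table
#'
#' Transforms each feature value to `(x - mean) / sd` using baseline
#' statistics, making subjects with different resting conductance levels
#' comparable. With `stats` a per-subject table (from
#' [baseline_window_stats()]), each subject is standardized against their
#' own baseline; with `method = "cohort"` the mean and SD are taken across
#' subjects' baseline-condition rows instead.
#'
#' @param features Feature table from [segment_features()] rows.
#' @param stats Per-subject baseline statistics (`subject_id`, `feature`,
#'   `mean`, `sd`); required for `method = "subject"`.
#' @param baseline_label Label of the baseline condition (cohort method).
#' @param method `"subject"` or `"cohort"`.
#' @param feature_cols Feature columns to standardize.
#' @return The feature table with additional `z_*` columns.
#' @export
z_standardize <- function(features, stats = NULL, baseline_label = "baseline",
                          method = c("subject", "cohort"),
                          feature_cols = c("mean_scl", "nsscr_count",
                                           "mean_amplitude", "edasymp")) {
  method <- match.arg(method)
  if (method == "cohort") {
    base <- features[features$label == baseline_label, , drop = FALSE]
    if (nrow(base) == 0L) stop("no rows with baseline label '", baseline_label, "'")
    st_list <- lapply(feature_cols, function(fc) {
      data.frame(feature = fc, mean = mean(base[[fc]]), sd = stats::sd(base[[fc]]))
    })
    st <- do.call(rbind, st_list)
    for (fc in feature_cols) {
      s <- st[st$feature == fc, ]
      if (!is.finite(s$sd) || s$sd == 0) {
        stop(sprintf("zero baseline SD for feature %s", fc))
      }
      features[[paste0("z_", fc)]] <- (features[[fc]] - s$mean) / s$sd
    }
    return(features)
  }
  if (is.null(stats)) stop("per-subject `stats` required for method = 'subject'")
  for (fc in feature_cols) {
    zcol <- rep(NA_real_, nrow(features))
    for (i in seq_len(nrow(features))) {
      s <- stats[stats$subject_id == features$subject_id[i] &
                 stats$feature == fc, , drop = FALSE]
      if (nrow(s) == 0L) next
      if (!is.finite(s$sd) || s$sd == 0) {
        stop(sprintf("zero baseline SD for subject %s, feature %s",
                     features$subject_id[i], fc))
      }
      zcol[i] <- (features[[fc]][i] - s$mean) / s$sd
    }
    features[[paste0("z_", fc)]] <- zcol
  }
  features
}
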