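#' Construct an EDA recording
#'
#' An `eda_recording` holds a uniformly sampled skin-conductance trace in
#' micro-Siemens, an optional accelerometer-magnitude channel in g, the
#' sampling rate, and a subject label. All downstream stages (filtering,
#' artifact screening, decomposition) operate on this container.
#'
#' @param eda Numeric vector of conductance values in µS (finite, non-empty).
#' @param fs Sampling rate in Hz (nominally 32 for the ambulatory sensors).
#' @param t0 Start time of the first sample in seconds.
#' @param acc Optional numeric vector of accelerometer magnitude in g, same
#'   length as `eda`.
#' @param subject_id Opaque subject label.
#' @return An object of class `eda_recording` with fields `eda`, `fs`, `t0`,
#'   `acc`, `subject_id`.
#' @export
eda_recording <- function(eda, fs, t0 = 0, acc = NULL, subject_id = "s1") {
  eda <- as.numeric(eda)
  if (length(eda) == 0L) stop("`eda` must be non-empty")
  if (!all(is.finite(eda))) stop("`eda` must be finite everywhere")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  if (!is.null(acc)) {
    acc <- as.numeric(acc)
    if (length(acc) != length(eda)) stop("`acc` must have the same length as `eda`")
  }
  structure(
    list(eda = eda, fs = fs, t0 = t0, acc = acc,
         subject_id = as.character(subject_id)),
    class = "eda_recording"
  )
}

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf("<eda_recording> subject %s: %d samples @ %g Hz (%.1f s)%s%s\n",
              x$subject_id, length(x$eda), x$fs, length(x$eda) / x$fs,
              if (!is.null(x$acc)) ", acc channel" else "",
              if (!is.null(x$label)) paste0(", condition '", x$label, "'") else ""))
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec An `eda_recording`.
#' @return Numeric vector of sample times in seconds.
#' @export
recording_times <- function(rec) {
  rec$t0 + (seq_along(rec$eda) - 1L) / rec$fs
}

#' Duration of a recording in seconds
#' @param rec An `eda_recording`.
#' @return Duration in seconds (`n / fs`).
#' @export
recording_duration <- function(rec) length(rec$eda) / rec$fs

#' Read an EDA recording from a delimited text file
#'
#' Expects a comma-separated file with header columns `time_s`, `eda_uS` and
#' optionally `acc_g`; lines beginning with `#` (e.g. a config-hash header)
#' are skipped. Timestamps must be uniform within 0.1 % of the sampling
#' interval; the first offending row is named otherwise.
#'
#' @param path Path to a CSV file.
#' @param fs_expected Expected sampling rate in Hz; if `NULL` it is inferred
#'   from the median timestamp increment.
#' @param subject_id Subject label; defaults to the file name without
#'   extension.
#' @return An [eda_recording()].
#' @export
read_recording <- function(path, fs_expected = NULL, subject_id = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("time_s", "eda_uS")) {
    if (!col %in% names(df)) stop(sprintf("missing column '%s' in %s", col, path))
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  tt <- df$time_s
  if (length(tt) < 2L) {
    fs <- if (is.null(fs_expected)) stop("cannot infer fs from fewer than 2 rows") else fs_expected
  } else {
    dt <- diff(tt)
    fs <- if (is.null(fs_expected)) 1 / stats::median(dt) else fs_expected
    bad <- which(abs(dt - 1 / fs) > 0.001 / fs)
    if (length(bad) > 0L) {
      stop(sprintf("non-uniform sampling at row %d: interval %.6f s, expected %.6f s",
                   bad[1] + 1L, dt[bad[1]], 1 / fs))
    }
  }
  eda_recording(df$eda_uS, fs = fs, t0 = tt[1],
                acc = if ("acc_g" %in% names(df)) df$acc_g else NULL,
                subject_id = subject_id)
}

#' Write an EDA recording to CSV
#'
#' Inverse of [read_recording()]; values round-trip to at least 6 decimals.
#' An optional `# config_hash:` comment line is prepended so pipeline
#' outputs are traceable to the configuration that produced them.
#'
#' @param rec An [eda_recording()].
#' @param path Output path.
#' @param config_hash Optional hash string written as a leading comment line.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, config_hash = NULL) {
  df <- data.frame(time_s = recording_times(rec), eda_uS = rec$eda)
  if (!is.null(rec$acc)) df$acc_g <- rec$acc
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a table of condition markers
#'
#' Markers assign condition labels to half-open time intervals
#' `[start_s, end_s)` of a subject's recording. Intervals of one subject must
#' not overlap.
#'
#' @param markers Data frame with columns `subject_id`, `label`, `start_s`,
#'   `end_s`.
#' @return The validated data frame.
#' @export
condition_markers <- function(markers) {
  need <- c("subject_id", "label", "start_s", "end_s")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0L) stop("markers missing column(s): ", paste(miss, collapse = ", "))
  if (any(markers$end_s <= markers$start_s)) stop("marker with end_s <= start_s")
  for (sid in unique(markers$subject_id)) {
    m <- markers[markers$subject_id == sid, , drop = FALSE]
    m <- m[order(m$start_s), , drop = FALSE]
    if (nrow(m) > 1L && any(m$start_s[-1] < m$end_s[-nrow(m)])) {
      stop(sprintf("overlapping markers for subject %s", sid))
    }
  }
  markers
}

#' Read / write condition-marker files
#'
#' @param path Path to a CSV file with columns `subject_id`, `label`,
#'   `start_s`, `end_s`.
#' @return For `read_markers`, a validated marker data frame.
#' @export
read_markers <- function(path) {
  condition_markers(utils::read.csv(path, comment.char = "#",
                                    colClasses = c(subject_id = "character")))
}

#' @rdname read_markers
#' @param markers Marker data frame.
#' @param config_hash Optional hash string written as a leading comment line.
#' @export
write_markers <- function(markers, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.csv(condition_markers(markers), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cut a recording into labelled condition segments
#'
#' Sample `i` (at time `t_i`) belongs to a marker iff
#' `start_s <= t_i < end_s` (half-open convention, so adjacent markers never
#' share a sample). Markers must lie within the recording span.
#'
#' @param rec An [eda_recording()].
#' @param markers Marker data frame (see [condition_markers()]); rows for
#'   other subjects are ignored.
#' @return A list of `eda_segment` objects (recordings carrying a `label`).
#' @export
cut_segments <- function(rec, markers) {
  markers <- condition_markers(markers)
  markers <- markers[markers$subject_id == rec$subject_id, , drop = FALSE]
  if (nrow(markers) == 0L) return(list())
  n <- length(rec$eda)
  t_end <- rec$t0 + n / rec$fs
  out <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    if (m$start_s < rec$t0 - 1e-9 || m$end_s > t_end + 1e-9) {
      stop(sprintf("marker '%s' [%g, %g) outside recording span [%g, %g)",
                   m$label, m$start_s, m$end_s, rec$t0, t_end))
    }
    # sample i has time t0 + (i-1)/fs; half-open [start, end)
    i0 <- ceiling((m$start_s - rec$t0) * rec$fs - 1e-6) + 1L
    i1 <- ceiling((m$end_s - rec$t0) * rec$fs - 1e-6)
    idx <- seq.int(max(1L, i0), min(n, i1))
    seg <- eda_recording(rec$eda[idx], fs = rec$fs,
                         t0 = rec$t0 + (idx[1] - 1L) / rec$fs,
                         acc = if (!is.null(rec$acc)) rec$acc[idx] else NULL,
                         subject_id = rec$subject_id)
    seg$label <- m$label
    class(seg) <- c("eda_segment", class(seg))
    out[[i]] <- seg
  }
  out
}

#' Equalize segment durations
#'
#' Truncates every segment to the shortest duration among the inputs,
#' keeping the initial portion of each. This mirrors comparing conditions of
#' unequal length on the first common time span (e.g. the first 54 s when
#' the fastest subject finished the course in 54 s).
#'
#' @param segments A list of `eda_segment`s (or recordings).
#' @param policy Only `"shortest"` is defined.
#' @return The list with every element truncated to `min(durations)`.
#' @export
equalize_durations <- function(segments, policy = "shortest") {
  policy <- match.arg(policy, "shortest")
  if (length(segments) == 0L) stop("at least one segment required")
  n_min <- min(vapply(segments, function(s) length(s$eda), integer(1)))
  lapply(segments, function(s) {
    s$eda <- s$eda[seq_len(n_min)]
    if (!is.null(s$acc)) s$acc <- s$acc[seq_len(n_min)]
    s
  })
}
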