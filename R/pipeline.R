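# Polynomial rolling hash of a string, hex-encoded; used to stamp every
# pipeline output with the configuration that produced it (a traceability
# stamp, not a cryptographic digest).
string_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with defaults equal to the module
#' defaults: sampling and filter settings, artifact rules, decomposition
#' parameters, band-power settings, design constants and the seed. The
#' configuration can be serialized to JSON and is hashed into every output
#' file header.
#'
#' @param fs Sampling rate in Hz.
#' @param filter_cutoff,filter_order Low-pass settings.
#' @param rules An [artifact_rules()].
#' @param decompose A [decompose_params()].
#' @param edasymp_band,edasymp_fs Band-power settings.
#' @param circumference,body_depth Oval design constants in m.
#' @param speeds Imposed speeds in m/s.
#' @param min_amplitude SCR threshold in µS.
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 32, filter_cutoff = 0.6, filter_order = 1,
                            rules = artifact_rules(),
                            decompose = decompose_params(),
                            edasymp_band = c(0.045, 0.25), edasymp_fs = 2,
                            circumference = 14.97, body_depth = 0.288,
                            speeds = c(1.41, 0.86, 0.31, 0.19),
                            min_amplitude = 0.01, seed = 1) {
  structure(list(fs = fs, filter_cutoff = filter_cutoff,
                 filter_order = filter_order, rules = rules,
                 decompose = decompose, edasymp_band = edasymp_band,
                 edasymp_fs = edasymp_fs, circumference = circumference,
                 body_depth = body_depth, speeds = speeds,
                 min_amplitude = min_amplitude, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @return For `config_hash`, an 8-character hex hash of the serialized
#'   configuration.
#' @export
config_hash <- function(config) {
  string_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE))
}

#' Write a synthetic study cohort to disk
#'
#' Generates a seeded cohort shaped like one of the two study designs
#' (`"study1"`: baseline + free walking + four imposed speeds, 3 min each;
#' `"study2"`: eight oval occupancy conditions) and writes per-subject
#' recording CSVs, a marker file, and ground-truth event and artifact
#' tables. Outputs are byte-identical for identical seeds and configs.
#'
#' @param study `"study1"` or `"study2"`.
#' @param out_dir Output directory (created if needed).
#' @param n_subjects Cohort size (defaults to the study's analysed n).
#' @param seed Cohort seed.
#' @param config A [pipeline_config()].
#' @param ... Passed to [study1_spec()] / [study2_spec()].
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(study = c("study1", "study2"), out_dir,
                         n_subjects = NULL, seed = 1,
                         config = pipeline_config(seed = seed), ...) {
  study <- match.arg(study)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- if (study == "study1") {
    study1_spec(n_subjects = if (is.null(n_subjects)) 17 else n_subjects,
                seed = seed, fs = config$fs, ...)
  } else {
    study2_spec(n_subjects = if (is.null(n_subjects)) 44 else n_subjects,
                seed = seed, fs = config$fs, ...)
  }
  cohort <- simulate_cohort(spec)
  hash <- config_hash(config)
  paths <- character(0)
  for (sid in names(cohort$recordings)) {
    p <- file.path(out_dir, paste0(sid, ".csv"))
    write_recording(cohort$recordings[[sid]], p, config_hash = hash)
    paths <- c(paths, p)
  }
  mp <- file.path(out_dir, "markers.csv")
  write_markers(cohort$markers, mp, config_hash = hash)
  ev_list <- lapply(names(cohort$truth), function(sid) {
    ev <- cohort$truth[[sid]]$events
    if (nrow(ev) == 0L) return(NULL)
    cbind(subject_id = sid, ev)
  })
  ev <- do.call(rbind, ev_list)
  tp <- file.path(out_dir, "truth_events.csv")
  con <- file(tp, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(ev, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(paths, mp, tp))
}

#' Run the analysis pipeline on one in-memory cohort
#'
#' Executes, per subject: zero-phase low-pass filtering, rule-based
#' artifact screening of the full recording, segmentation by the condition
#' markers, duration equalization across the cohort per condition label,
#' and—unless `decompose = FALSE`—the convex tonic/phasic decomposition
#' with SCR detection and band-power extraction per segment. Segments of
#' excluded recordings are reported in `exclusions` and omitted from the
#' feature table. With `decompose = FALSE` only the tonic-level feature is
#' computed (`mean_scl` of the filtered trace), the fast screening mode
#' used for large simulation sweeps where the planted effect is tonic.
#'
#' @param recordings Named list of [eda_recording()]s.
#' @param markers Cohort marker data frame.
#' @param config A [pipeline_config()].
#' @param decompose Run the full decomposition per segment?
#' @return List with `features` (long table), `exclusions` (subject, label,
#'   reason), `reports` (per-subject artifact reports).
#' @export
run_cohort <- function(recordings, markers, config = pipeline_config(),
                       decompose = TRUE) {
  seg_all <- list()
  reports <- list()
  exclusions <- data.frame(subject_id = character(0), label = character(0),
                           reason = character(0))
  for (sid in names(recordings)) {
    rec <- recordings[[sid]]
    # artifacts are raw-sensor phenomena; screen before smoothing them away
    rep <- detect_artifacts(rec, config$rules)
    reports[[sid]] <- rep
    filt <- rec
    filt$eda <- eda_lowpass(rec$eda, rec$fs, cutoff = config$filter_cutoff,
                            order = config$filter_order)
    segs <- cut_segments(filt, markers)
    if (rep$excluded) {
      exclusions <- rbind(exclusions, data.frame(
        subject_id = sid,
        label = vapply(segs, `[[`, "", "label"),
        reason = sprintf("artifact screening: %.1f%% flagged",
                         100 * rep$flagged_fraction)))
      next
    }
    seg_all <- c(seg_all, segs)
  }
  if (length(seg_all) == 0L) {
    return(list(features = NULL, exclusions = exclusions, reports = reports))
  }
  # equalize durations within each condition label across subjects
  labels <- vapply(seg_all, `[[`, "", "label")
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    seg_all[idx] <- equalize_durations(seg_all[idx])
  }
  feats <- vector("list", length(seg_all))
  for (i in seq_along(seg_all)) {
    seg <- seg_all[[i]]
    if (decompose) {
      d <- decompose_eda(seg$eda, seg$fs, config$decompose)
      feats[[i]] <- segment_features(seg, d,
                                     min_amplitude = config$min_amplitude)
    } else {
      feats[[i]] <- data.frame(subject_id = seg$subject_id, label = seg$label,
                               mean_scl = mean(seg$eda),
                               n_valid_samples = length(seg$eda))
    }
  }
  list(features = do.call(rbind, feats), exclusions = exclusions,
       reports = reports)
}

#' Run the full pipeline on a simulated or recorded data directory
#'
#' Reads every `*.csv` recording and `markers.csv` from `in_dir`, runs
#' [run_cohort()], analyses the features with [analyze_study()], and
#' writes `features.csv`, `exclusions.csv`, `stat_reports.json` and the
#' oval design table `design_table.csv` to `out_dir`, each stamped with
#' the config hash.
#'
#' @param in_dir Input directory (as written by [cmd_simulate()]).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param decompose Run the full decomposition per segment?
#' @param feature_cols Features passed to [analyze_study()].
#' @return Invisibly, the [run_cohort()] result plus `stats`.
#' @export
cmd_run <- function(in_dir, out_dir, config = pipeline_config(),
                    decompose = TRUE,
                    feature_cols = c("mean_scl", "nsscr_count",
                                     "mean_amplitude", "edasymp")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- setdiff(list.files(in_dir, pattern = "\\.csv$"),
                   c("markers.csv", "truth_events.csv"))
  if (length(files) == 0L) stop("no recording CSVs found in ", in_dir)
  recordings <- lapply(file.path(in_dir, files), read_recording,
                       fs_expected = config$fs)
  names(recordings) <- vapply(recordings, `[[`, "", "subject_id")
  markers <- read_markers(file.path(in_dir, "markers.csv"))
  res <- run_cohort(recordings, markers, config, decompose = decompose)
  hash <- config_hash(config)

  write_hashed_csv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$features)) {
    write_hashed_csv(res$features, file.path(out_dir, "features.csv"))
  }
  write_hashed_csv(res$exclusions, file.path(out_dir, "exclusions.csv"))
  write_hashed_csv(oval_conditions(circumference = config$circumference,
                                   body_depth = config$body_depth),
                   file.path(out_dir, "design_table.csv"))

  stats <- NULL
  if (!is.null(res$features)) {
    avail <- intersect(feature_cols, names(res$features))
    stats <- analyze_study(res$features, feature_cols = avail,
                           labels = unique(markers$label))
    ser <- lapply(stats, function(s) {
      list(test = s$omnibus$test, statistic = s$omnibus$statistic,
           df = s$omnibus$df, p = s$omnibus$p,
           epsilon = s$omnibus$epsilon,
           posthoc = as.data.frame(s$posthoc),
           normality_p = as.list(s$normality), test_used = s$test_used)
    })
    jsonlite::write_json(list(config_hash = hash, reports = ser),
                         file.path(out_dir, "stat_reports.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(c(res, list(stats = stats)))
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_config` returns a [pipeline_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- do.call(artifact_rules, raw$rules)
  dec <- raw$decompose
  dec$kernel <- do.call(scr_kernel, dec$kernel)
  dec <- do.call(decompose_params, dec)
  pipeline_config(fs = raw$fs, filter_cutoff = raw$filter_cutoff,
                  filter_order = raw$filter_order, rules = rules,
                  decompose = dec, edasymp_band = raw$edasymp_band,
                  edasymp_fs = raw$edasymp_fs,
                  circumference = raw$circumference,
                  body_depth = raw$body_depth, speeds = raw$speeds,
                  min_amplitude = raw$min_amplitude, seed = raw$seed)
}
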