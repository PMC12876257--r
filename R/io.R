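#' Write a recording as a delimited matrix with side-car metadata
#'
#' The signal is stored as a comma-separated channels x samples matrix
#' (`<prefix>.csv`, no header) and the metadata — sampling rate, identity
#' fields and events — as YAML (`<prefix>.yaml`), since a plain matrix
#' cannot carry them.
#'
#' @param rec an `eeg_recording`.
#' @param prefix output path prefix (without extension).
#' @return the two file paths, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig_path <- paste0(prefix, ".csv")
  meta_path <- paste0(prefix, ".yaml")
  utils::write.table(format(rec$signal, digits = 10, trim = TRUE,
                            scientific = TRUE),
                     sig_path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs,
               participant_id = rec$participant_id,
               modality = rec$modality,
               group = rec$group,
               duration_ms = rec$duration_ms,
               events = if (nrow(rec$events)) {
                 lapply(seq_len(nrow(rec$events)), function(i) {
                   list(label = rec$events$label[i],
                        time_ms = rec$events$time_ms[i])
                 })
               } else {
                 list()
               })
  yaml::write_yaml(meta, meta_path)
  invisible(c(sig_path, meta_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix used at write time.
#' @param layout optional `sensor_layout`; when given, the channel count of
#'   the file is checked against it.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(prefix, layout = NULL) {
  sig_path <- paste0(prefix, ".csv")
  meta_path <- paste0(prefix, ".yaml")
  if (!file.exists(sig_path)) stop("signal file not found: ", sig_path)
  if (!file.exists(meta_path)) stop("side-car metadata not found: ", meta_path)
  sig <- as.matrix(utils::read.table(sig_path, sep = ",", header = FALSE))
  dimnames(sig) <- NULL
  meta <- yaml::read_yaml(meta_path)
  if (!is.null(layout) && nrow(sig) != layout$n_channels) {
    stop("recording has ", nrow(sig), " channels but layout expects ",
         layout$n_channels)
  }
  events <- if (length(meta$events)) {
    data.frame(label = vapply(meta$events, `[[`, "", "label"),
               time_ms = vapply(meta$events, `[[`, 0, "time_ms"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(), time_ms = numeric())
  }
  recording(sig, fs = meta$fs, events = events,
            participant_id = meta$participant_id %||% NA_character_,
            modality = meta$modality %||% NA_character_,
            group = meta$group %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default: band-pass
#' 2-48 Hz, 50 Hz notch, 8 + 14 ms event-timing correction, 500 ms windows,
#' the 4-48 Hz index grid, the default band table, alpha 0.05, and the
#' normalization methods. The resolved configuration is echoed into every
#' run's output directory.
#'
#' @param band band-pass edges in Hz.
#' @param notch_hz,notch_q notch centre and quality factor.
#' @param anti_alias_ms,refresh_ms event-timing corrections.
#' @param window_ms analysis window length.
#' @param bands a `band_table`.
#' @param alpha significance level.
#' @param borderline_as_reject convention for borderline cells in the
#'   combined decision matrix.
#' @param filter_method `"fft"` or `"filtfilt"` (see
#'   [preprocess_recording()]).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(2, 48), notch_hz = 50, notch_q = 30,
                            anti_alias_ms = 8, refresh_ms = 14,
                            window_ms = 500, bands = default_bands(),
                            alpha = 0.05, borderline_as_reject = FALSE,
                            filter_method = "fft") {
  if (window_ms <= 0) stop("window_ms must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(band) != 2 || band[1] >= band[2]) stop("invalid band edges")
  stopifnot(inherits(bands, "band_table"))
  structure(list(band = band, notch_hz = notch_hz, notch_q = notch_q,
                 anti_alias_ms = anti_alias_ms, refresh_ms = refresh_ms,
                 window_ms = window_ms, bands = bands, alpha = alpha,
                 borderline_as_reject = borderline_as_reject,
                 filter_method = filter_method),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Chains preprocess -> event shift -> windowing -> spectra -> indices ->
#' hierarchical aggregation -> group summaries -> pairwise decisions ->
#' combined decision matrices, and (optionally) writes all numeric exports
#' plus a run log to a directory.
#'
#' @param cohort a list with `recordings` and `manifest` as returned by
#'   [simulate_cohort()], or a directory of recordings written with
#'   [write_recording()] (one `<participant>_<modality>` prefix each).
#' @param layout a `sensor_layout`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return invisibly, a list with `frames`, `summaries` (electrode and
#'   participant levels), `group_summary`, `decisions` and `log`.
#' @export
run_pipeline <- function(cohort, layout = load_layout(),
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) {
    prefixes <- unique(sub("\\.(csv|yaml)$", "",
                           list.files(cohort, pattern = "\\.(csv|yaml)$",
                                      full.names = TRUE)))
    recordings <- lapply(prefixes, read_recording, layout = layout)
    names(recordings) <- basename(prefixes)
  } else {
    recordings <- cohort$recordings
  }
  if (!length(recordings)) stop("pipeline input: no recordings")

  log_lines <- c(sprintf("eegstates %s pipeline run, %s",
                         as.character(utils::packageVersion("eegstates")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("recordings: %d", length(recordings)))
  total_flagged <- 0L
  frames <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    rec <- preprocess_recording(rec, band = config$band,
                                notch_hz = config$notch_hz,
                                notch_q = config$notch_q,
                                method = config$filter_method)
    rec <- shift_events(rec, config$anti_alias_ms, config$refresh_ms)
    wrec <- segment_windows(rec, window_ms = config$window_ms)
    fr <- compute_index_frame(wrec, bands = config$bands)
    total_flagged <- total_flagged + attr(fr, "n_flagged")
    frames[[i]] <- fr
  }
  frames <- do.call(rbind, frames)
  log_lines <- c(log_lines, sprintf("flagged zero-power windows: %d",
                                    total_flagged))

  summaries <- hierarchical_means(frames)
  gsum <- group_summaries(summaries$participant, alpha = config$alpha)
  decisions <- cohort_decisions(summaries$participant, alpha = config$alpha,
                                borderline_as_reject =
                                  config$borderline_as_reject)
  log_lines <- c(log_lines,
                 sprintf("participant summaries: %d rows; groups: %s",
                         nrow(summaries$participant),
                         paste(names(decisions), collapse = ", ")))

  result <- list(frames = frames, summaries = summaries,
                 group_summary = gsum, decisions = decisions,
                 log = log_lines, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(frames, file.path(out_dir, "index_frames.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries$electrode,
                     file.path(out_dir, "electrode_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries$participant,
                     file.path(out_dir, "participant_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(gsum, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    for (g in names(decisions)) {
      safe_g <- gsub("[^A-Za-z]", "", g)
      for (ix in setdiff(names(decisions[[g]]), "combined")) {
        dm <- decisions[[g]][[ix]]
        utils::write.csv(dm$decisions,
                         file.path(out_dir,
                                   sprintf("decisions_%s_%s.csv", safe_g, ix)))
        utils::write.csv(dm$p,
                         file.path(out_dir,
                                   sprintf("pvalues_%s_%s.csv", safe_g, ix)))
      }
      utils::write.csv(decisions[[g]]$combined$verdict,
                       file.path(out_dir,
                                 sprintf("combined_%s.csv", safe_g)))
    }
    cfg <- config
    cfg$bands <- as.data.frame(unclass(config$bands))
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}
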