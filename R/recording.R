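#' Construct a multi-channel EEG recording
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (default 1000). Must exceed twice the upper
#'   index frequency (48 Hz).
#' @param events data frame with columns `label` and `time_ms`; times must
#'   lie within `[0, duration]`.
#' @param participant_id participant identifier.
#' @param modality one of `MODALITIES`, or `NA`.
#' @param group one of `GROUPS`, or `NA`.
#' @return an `eeg_recording` object. The duration `L` in ms is derived from
#'   the sample count and `fs`.
#' @export
recording <- function(signal, fs = 1000,
                      events = data.frame(label = character(),
                                          time_ms = numeric()),
                      participant_id = NA_character_,
                      modality = NA_character_,
                      group = NA_character_) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  if (fs <= 2 * max(INDEX_FREQS)) {
    stop("sampling rate ", fs, " Hz too low for the 4-48 Hz index grid")
  }
  duration_ms <- ncol(signal) / fs * 1000
  if (!is.na(modality)) modality <- match.arg(modality, MODALITIES)
  if (!is.na(group)) group <- match.arg(group, GROUPS)
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("label", "time_ms") %in% names(events))) {
      stop("events need columns label, time_ms")
    }
    if (any(events$time_ms < 0 | events$time_ms > duration_ms)) {
      stop("event times outside [0, ", duration_ms, "] ms")
    }
  }
  if (is.null(events$clipped)) events$clipped <- logical(nrow(events))
  structure(
    list(signal = signal, fs = fs, events = events,
         participant_id = participant_id, modality = modality,
         group = group, duration_ms = duration_ms,
         meta = list(preprocessing = character())),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$duration_ms / 1000))
  cat(sprintf("  participant %s | modality %s | group %s | %d events\n",
              x$participant_id, x$modality, x$group, nrow(x$events)))
  if (length(x$meta$preprocessing)) {
    cat("  preprocessing:", paste(x$meta$preprocessing, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Shift event timestamps to the true stimulus time
#'
#' Recorded event markers lag the physical stimulus by the amplifier's
#' anti-alias conversion (8 ms) plus the screen refresh (14 ms); both are
#' added to every event time, a 22 ms shift by default. Events shifted past
#' the end of the recording are retained, clipped to the duration, and
#' flagged with a warning.
#'
#' @param x an `eeg_recording`, or an events data frame (then `duration_ms`
#'   must be supplied for clipping).
#' @param anti_alias_ms anti-alias filter correction, default 8.
#' @param refresh_ms screen-refresh correction, default 14.
#' @param duration_ms recording length for clipping (events-data-frame input).
#' @return same type as `x`, with shifted event times and a `clipped` flag.
#' @export
shift_events <- function(x, anti_alias_ms = 8, refresh_ms = 14,
                         duration_ms = NULL) {
  if (anti_alias_ms < 0 || refresh_ms < 0) {
    stop("timing corrections must be non-negative")
  }
  shift <- anti_alias_ms + refresh_ms
  if (inherits(x, "eeg_recording")) {
    x$events <- shift_events(x$events, anti_alias_ms, refresh_ms,
                             duration_ms = x$duration_ms)
    x$meta$preprocessing <- c(x$meta$preprocessing,
                              sprintf("event shift +%g ms", shift))
    return(x)
  }
  ev <- as.data.frame(x)
  if (!nrow(ev)) return(ev)
  ev$time_ms <- ev$time_ms + shift
  if (is.null(ev$clipped)) ev$clipped <- logical(nrow(ev))
  if (!is.null(duration_ms)) {
    over <- ev$time_ms > duration_ms
    if (any(over)) {
      warning(sum(over), " event(s) shifted past the recording end; clipped")
      ev$clipped <- ev$clipped | over
      ev$time_ms[over] <- duration_ms
    }
  }
  ev
}

#' Segment a recording into fixed windows
#'
#' Splits each channel into contiguous, non-overlapping windows starting at
#' t = 0; a trailing partial window is discarded, so `NW = floor(L / window_ms)`.
#'
#' @param rec an `eeg_recording`.
#' @param window_ms window length in ms, default 500.
#' @return a `windowed_recording` with a 3-d array `windows` of dimension
#'   (channels, NW, samples per window).
#' @export
segment_windows <- function(rec, window_ms = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window_ms <= 0) stop("window_ms must be positive")
  wlen <- round(window_ms * rec$fs / 1000)
  n <- ncol(rec$signal)
  nw <- n %/% wlen
  if (nw < 1) {
    stop("recording shorter (", rec$duration_ms, " ms) than one window (",
         window_ms, " ms)")
  }
  kept <- rec$signal[, seq_len(nw * wlen), drop = FALSE]
  windows <- array(kept, dim = c(nrow(kept), wlen, nw))
  windows <- aperm(windows, c(1, 3, 2))  # channel x window x sample
  structure(
    list(windows = windows, nw = nw, window_ms = window_ms, fs = rec$fs,
         participant_id = rec$participant_id, modality = rec$modality,
         group = rec$group, meta = rec$meta),
    class = "windowed_recording"
  )
}

#' @export
print.windowed_recording <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("windowed_recording: %d channels x %d windows of %g ms @ %g Hz\n",
              d[1], d[2], x$window_ms, x$fs))
  invisible(x)
}
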