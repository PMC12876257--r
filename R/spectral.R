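#' Power spectrum of one 500 ms window
#'
#' Single-taper (Hann) periodogram of one channel segment, zero-padded to a
#' one-second FFT so the spectrum lands on a 1 Hz bin grid; the native
#' resolution of a 0.5 s window is 2 Hz, so the unit-step 4-48 Hz index grid
#' is realised by interpolation through zero-padding. Only the 45 index bins
#' (4-48 Hz) are returned.
#'
#' @param segment numeric vector, one channel's samples for one window
#'   (length `fs / 2`).
#' @param fs sampling rate in Hz (integer).
#' @return a `window_spectrum`: list with `freq` (4:48) and non-negative
#'   `power` (arbitrary units consistent across windows).
#' @export
window_psd <- function(segment, fs) {
  fs <- as.integer(fs)
  if (length(segment) != fs %/% 2) {
    stop("segment must hold ", fs %/% 2, " samples (500 ms at ", fs, " Hz)")
  }
  pw <- psd_cols(matrix(segment, ncol = 1), fs)[, 1]
  if (sum(pw) <= 0) stop("zero total power in window")
  structure(list(freq = INDEX_FREQS, power = pw), class = "window_spectrum")
}

# Hann periodogram for a samples x windows matrix; returns 45 x windows
# power at the 4..48 Hz bins.
psd_cols <- function(segmat, fs) {
  n <- nrow(segmat)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  nfft <- fs  # 1 Hz bin spacing
  padded <- matrix(0, nfft, ncol(segmat))
  padded[seq_len(n), ] <- segmat * w
  X <- stats::mvfft(padded)
  bins <- INDEX_FREQS + 1L  # bin k Hz sits at row k + 1
  (Mod(X[bins, , drop = FALSE])^2) * 2 / sum(w)^2
}

#' Normalize a spectrum into a probability distribution
#'
#' Total power is the sum of the 45 band powers; dividing by it turns the
#' spectrum into an empirical probability distribution over frequency.
#'
#' @param ws a `window_spectrum`, or a numeric vector of band powers (then
#'   `freq` supplies the bin frequencies).
#' @param freq bin frequencies when `ws` is a plain vector.
#' @return a `spectral_distribution`: list with `p` (sums to 1), `freq`, and
#'   `tp` (total power).
#' @export
spectrum_to_distribution <- function(ws, freq = NULL) {
  if (inherits(ws, "window_spectrum")) {
    pw <- ws$power
    freq <- ws$freq
  } else {
    pw <- as.numeric(ws)
    if (is.null(freq)) freq <- seq_along(pw)
  }
  if (any(pw < 0)) stop("band powers must be non-negative")
  tp <- sum(pw)
  if (tp <= 0) stop("zero total power")
  structure(list(p = pw / tp, freq = freq, tp = tp),
            class = "spectral_distribution")
}

as_probs <- function(d) {
  p <- if (inherits(d, "spectral_distribution")) d$p else as.numeric(d)
  if (any(p < -1e-12)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  pmax(p, 0)
}

#' Spectral Shannon entropy
#'
#' `H = -sum(p_i log2 p_i)` in bits, with `0 log 0 = 0`. High values mean a
#' broadband (disordered) spectrum, low values a concentrated one; the
#' maximum over the 45-bin grid is `log2(45)`, about 5.492 bits.
#'
#' @param d a `spectral_distribution` or a probability vector.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(d) {
  p <- as_probs(d)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Pearson's first skewness coefficient of a spectral distribution
#'
#' `PSk = |mean - mode| / SD`, where mean and SD are the probability-weighted
#' first and second moments of frequency and the mode is the frequency of the
#' maximum-probability bin (the dominant frequency). Zero for a symmetric
#' unimodal spectrum; by convention 0 when SD = 0 (degenerate single-bin
#' spectrum, where mean and mode coincide).
#'
#' @param d a `spectral_distribution` or probability vector.
#' @param freq bin frequencies in Hz (taken from `d` when available).
#' @return non-negative dimensionless skewness.
#' @export
pearson_skewness <- function(d, freq = NULL) {
  p <- as_probs(d)
  if (is.null(freq)) {
    freq <- if (inherits(d, "spectral_distribution")) d$freq else seq_along(p)
  }
  m <- sum(freq * p)
  v <- sum(p * (freq - m)^2)
  if (v <= 0) return(0)
  mode <- freq[which.max(p)]
  abs(m - mode) / sqrt(v)
}

#' Dominant frequency and dominant band of a window
#'
#' The dominant frequency (DF) is the bin with maximal power (ties resolved
#' to the lowest frequency). The dominant band is the band of the table with
#' maximal summed power (ties resolved to the lower band).
#'
#' @param ws a `window_spectrum`.
#' @param bands a `band_table`, default [default_bands()].
#' @return list with `df` (Hz) and `band` (label).
#' @export
dominant_frequency_and_band <- function(ws, bands = default_bands()) {
  stopifnot(inherits(ws, "window_spectrum"))
  bf <- band_of_freq(bands, ws$freq)
  bp <- vapply(levels(bf), function(b) sum(ws$power[bf == b]), numeric(1))
  list(df = ws$freq[which.max(ws$power)],
       band = levels(bf)[which.max(bp)])
}

#' Total dominance time per band
#'
#' Converts a per-window dominant-band sequence into the number of seconds
#' each band was dominant (`count x window length`).
#'
#' @param bands_seq character/factor vector of per-window dominant bands.
#' @param window_ms window length in ms, default 500.
#' @param levels band labels to tabulate (defaults to those present, in
#'   band-table order when a factor is given).
#' @return named numeric vector of seconds; sums to `NW x window_ms / 1000`.
#' @export
band_dominance_time <- function(bands_seq, window_ms = 500, levels = NULL) {
  if (!length(bands_seq)) stop("empty dominant-band sequence")
  if (is.null(levels)) {
    levels <- if (is.factor(bands_seq)) base::levels(bands_seq) else unique(bands_seq)
  }
  counts <- table(factor(bands_seq, levels = levels))
  out <- as.numeric(counts) * window_ms / 1000
  names(out) <- names(counts)
  out
}

#' Mean dominant frequency of one electrode
#'
#' Arithmetic mean of the per-window dominant frequencies (spectral modes)
#' of a single electrode.
#'
#' @param modes numeric vector of per-window dominant frequencies in Hz.
#' @return mean mode in Hz.
#' @export
mean_mode_per_electrode <- function(modes) {
  if (!length(modes)) stop("need at least one window")
  mean(modes)
}

#' DFs: spatial dispersion of dominant frequencies
#'
#' Sample standard deviation (n - 1 divisor), across electrodes, of each
#' electrode's mean dominant frequency. Low DFs means the whole scalp peaks
#' at similar frequencies (e.g. global alpha dominance); high DFs means the
#' spectral peak wanders across the scalp.
#'
#' @param mean_modes numeric vector, one mean dominant frequency per
#'   electrode.
#' @return DFs in Hz.
#' @export
dfs_index <- function(mean_modes) {
  if (length(mean_modes) < 2) {
    stop("DFs needs at least two electrodes")
  }
  stats::sd(mean_modes)
}

#' Compute the per-window index frame of a recording
#'
#' For every (electrode, window) pair computes the four classification
#' indices: spectral entropy H (bits), Pearson first skewness PSk, total
#' power TP and dominant frequency DF (Hz), plus the dominant band label.
#' Windows with zero total power are flagged and excluded; if more than half
#' of all windows are flagged the recording is rejected as degenerate.
#'
#' @param wrec a `windowed_recording` (see [segment_windows()]).
#' @param bands a `band_table`.
#' @return data frame with columns `participant`, `modality`, `group`,
#'   `electrode`, `window`, `H`, `PSk`, `TP`, `DF`, `band`. Attributes:
#'   `n_flagged` (excluded windows) and `dfs` (the recording's DFs index).
#' @export
compute_index_frame <- function(wrec, bands = default_bands()) {
  stopifnot(inherits(wrec, "windowed_recording"))
  d <- dim(wrec$windows)  # channel x window x sample
  nch <- d[1]; nw <- d[2]
  segmat <- matrix(aperm(wrec$windows, c(3, 1, 2)), nrow = d[3])
  pw <- psd_cols(segmat, wrec$fs)  # 45 x (nch * nw); col = (w-1)*nch + ch
  f <- INDEX_FREQS

  tp <- colSums(pw)
  flagged <- tp <= 0
  if (sum(flagged) > length(flagged) / 2) {
    stop("degenerate recording: ", sum(flagged), " of ", length(flagged),
         " electrode-windows have zero power")
  }
  tp_safe <- ifelse(flagged, 1, tp)
  p <- sweep(pw, 2, tp_safe, "/")

  plog <- p * log2(p)
  plog[p == 0] <- 0
  H <- -colSums(plog)

  ex <- colSums(f * p)
  ex2 <- colSums(f^2 * p)
  sdv <- sqrt(pmax(ex2 - ex^2, 0))
  mode_idx <- max.col(t(pw), ties.method = "first")
  df_hz <- f[mode_idx]
  psk <- ifelse(sdv > 0, abs(ex - df_hz) / sdv, 0)

  bf <- band_of_freq(bands, f)
  bp <- vapply(levels(bf),
               function(b) colSums(pw[bf == b, , drop = FALSE]),
               numeric(ncol(pw)))
  dom_band <- levels(bf)[max.col(bp, ties.method = "first")]

  out <- data.frame(
    participant = wrec$participant_id,
    modality = wrec$modality,
    group = wrec$group,
    electrode = rep(seq_len(nch), times = nw),
    window = rep(seq_len(nw), each = nch),
    H = H, PSk = psk, TP = tp, DF = df_hz,
    band = factor(dom_band, levels = levels(bf)),
    stringsAsFactors = FALSE
  )
  out <- out[!flagged, , drop = FALSE]
  rownames(out) <- NULL

  mm <- tapply(out$DF, out$electrode, mean)
  attr(out, "dfs") <- if (length(mm) >= 2) dfs_index(as.numeric(mm)) else NA_real_
  attr(out, "n_flagged") <- sum(flagged)
  out
}
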