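#' Canonical modality labels
#'
#' The six experimental conditions, in the display order used throughout the
#' package: meditation (MED), mental arithmetic (MM), scrambled words (WORDS),
#' sentences (SENT), ambiguous images (IMG) and video (VDO).
#'
#' @export
MODALITIES <- c("MED", "MM", "WORDS", "SENT", "IMG", "VDO")

#' Participant group labels
#' @export
GROUPS <- c("Meditator", "Non-Meditator")

#' Index bin grid
#'
#' The spectral indices are computed on 1 Hz bins from 4 to 48 Hz inclusive
#' (45 bins), regardless of the wider 2-48 Hz band-pass applied during
#' preprocessing.
#'
#' @export
INDEX_FREQS <- 4:48

#' Define a frequency band table
#'
#' Bands partition the 4-48 Hz index grid. Each band covers `[low, high)`
#' except the last, which also includes its upper edge so that 48 Hz belongs
#' to Gamma.
#'
#' @param bands named list of `c(low, high)` edges in Hz, ordered by
#'   increasing frequency.
#' @return a `band_table` data frame with columns `band`, `low`, `high`.
#' @examples
#' default_bands()
#' @export
band_table <- function(bands) {
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    stop("bands must be a named list")
  }
  low <- vapply(bands, function(b) b[1], numeric(1))
  high <- vapply(bands, function(b) b[2], numeric(1))
  if (any(high <= low)) stop("each band needs high > low")
  if (is.unsorted(low, strictly = TRUE)) stop("bands must be ordered by frequency")
  if (any(abs(high[-length(high)] - low[-1]) > 1e-9)) {
    stop("bands must tile the frequency axis without gaps or overlap")
  }
  fr <- range(INDEX_FREQS)
  if (low[1] > fr[1] || high[length(high)] < fr[2]) {
    stop(sprintf("bands must cover %d-%d Hz", fr[1], fr[2]))
  }
  out <- data.frame(band = names(bands), low = low, high = high,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("band_table", "data.frame")
  out
}

#' Default EEG band table
#'
#' Theta 4-8, Alpha 8-13, L-Beta 13-20, H-Beta 20-30, Gamma 30-48 Hz.
#' Edges are half-open `[low, high)`; the Gamma band is closed at 48 Hz.
#'
#' @return a `band_table`.
#' @export
default_bands <- function() {
  band_table(list(
    "Theta"  = c(4, 8),
    "Alpha"  = c(8, 13),
    "L-Beta" = c(13, 20),
    "H-Beta" = c(20, 30),
    "Gamma"  = c(30, 48)
  ))
}

#' Assign 1 Hz bins to bands
#'
#' @param bands a `band_table`.
#' @param freqs bin centre frequencies in Hz.
#' @return factor of band labels, one per frequency, with levels in band order.
#' @keywords internal
band_of_freq <- function(bands, freqs = INDEX_FREQS) {
  idx <- findInterval(freqs, c(bands$low, bands$high[nrow(bands)]),
                      rightmost.closed = TRUE)
  if (any(idx < 1 | idx > nrow(bands))) {
    stop("frequencies outside the band table range")
  }
  factor(bands$band[idx], levels = bands$band)
}
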