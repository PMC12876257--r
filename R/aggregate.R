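#' Hierarchical means of the index frame
#'
#' Averages the per-window indices level by level, exactly as the summary
#' hierarchy chains them: windows within electrode, then electrodes within
#' participant. Flagged (zero-power) windows were already excluded upstream,
#' so denominators count valid windows only. The participant level also
#' carries DFs, the across-electrode standard deviation of each electrode's
#' mean dominant frequency.
#'
#' @param frames an index frame (or several row-bound frames) from
#'   [compute_index_frame()].
#' @return list with `electrode` (per participant x modality x electrode
#'   means of H, PSk, TP, DF) and `participant` (per participant x modality
#'   means across electrodes, plus `DFs`).
#' @export
hierarchical_means <- function(frames) {
  if (!nrow(frames)) stop("empty index frame")
  key_e <- interaction(frames$participant, frames$modality, frames$electrode,
                       drop = TRUE, lex.order = TRUE)
  agg <- function(x, key) as.numeric(tapply(x, key, mean))
  first <- function(x, key) as.vector(tapply(x, key, function(v) v[1]))
  electrode <- data.frame(
    participant = first(frames$participant, key_e),
    modality = first(frames$modality, key_e),
    group = first(frames$group, key_e),
    electrode = as.integer(first(frames$electrode, key_e)),
    H = agg(frames$H, key_e), PSk = agg(frames$PSk, key_e),
    TP = agg(frames$TP, key_e), DF = agg(frames$DF, key_e),
    stringsAsFactors = FALSE
  )
  key_p <- interaction(electrode$participant, electrode$modality,
                       drop = TRUE, lex.order = TRUE)
  participant <- data.frame(
    participant = first(electrode$participant, key_p),
    modality = first(electrode$modality, key_p),
    group = first(electrode$group, key_p),
    H = agg(electrode$H, key_p), PSk = agg(electrode$PSk, key_p),
    TP = agg(electrode$TP, key_p), DF = agg(electrode$DF, key_p),
    DFs = as.numeric(tapply(electrode$DF, key_p,
                            function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)),
    stringsAsFactors = FALSE
  )
  rownames(electrode) <- rownames(participant) <- NULL
  list(electrode = electrode, participant = participant)
}

#' Group mean with t-based confidence interval
#'
#' Mean, sample standard deviation and a two-sided `(1 - alpha)` confidence
#' half-width `t(1 - alpha/2, n - 1) * SD / sqrt(n)` for one group's
#' participant-level values.
#'
#' @param values numeric vector, one value per participant (`n >= 2`).
#' @param alpha significance level, default 0.05.
#' @return list with `mean`, `sd`, `n`, `alpha`, `ci_half`.
#' @export
group_summary <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("group summary needs at least 2 participants")
  s <- stats::sd(values)
  list(mean = mean(values), sd = s, n = n, alpha = alpha,
       ci_half = stats::qt(1 - alpha / 2, df = n - 1) * s / sqrt(n))
}

#' Group x modality x index summary table
#'
#' Applies [group_summary()] to every group x modality cell for each of the
#' four indices on the participant-level summary table.
#'
#' @param participant the `participant` data frame from
#'   [hierarchical_means()].
#' @param indices index columns to summarise.
#' @param alpha significance level for the confidence half-width.
#' @return long data frame: `group`, `modality`, `index`, `mean`, `sd`, `n`,
#'   `ci_half`.
#' @export
group_summaries <- function(participant, indices = c("H", "PSk", "TP", "DFs"),
                            alpha = 0.05) {
  combos <- unique(participant[, c("group", "modality")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- participant$group == combos$group[i] &
      participant$modality == combos$modality[i]
    for (ix in indices) {
      gs <- group_summary(participant[[ix]][sel], alpha = alpha)
      rows[[length(rows) + 1]] <- data.frame(
        group = combos$group[i], modality = combos$modality[i], index = ix,
        mean = gs$mean, sd = gs$sd, n = gs$n, ci_half = gs$ci_half,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize index values for cross-modality comparison
#'
#' Entropy is expressed as a fraction of its 45-bin maximum `log2(45)`
#' (entropy ratio); the other indices are scaled by the maximum over the
#' compared collection, so the largest value maps to 1. The method and
#' scaling factor are attached as attributes so the transformation can be
#' inverted.
#'
#' @param values numeric vector of index values.
#' @param index one of `"H"`, `"PSk"`, `"TP"`, `"DFs"`, `"DF"`.
#' @param method `"entropy_ratio"` or `"max"`; defaults to `"entropy_ratio"`
#'   for H and `"max"` otherwise.
#' @return normalized values in `[0, 1]`, with attributes `method` and
#'   `scale`.
#' @export
normalize_index <- function(values, index = c("H", "PSk", "TP", "DFs", "DF"),
                            method = NULL) {
  index <- match.arg(index)
  if (is.null(method)) method <- if (index == "H") "entropy_ratio" else "max"
  method <- match.arg(method, c("entropy_ratio", "max"))
  if (!all(is.finite(values))) stop("values must be finite")
  scale <- if (method == "entropy_ratio") {
    log2(length(INDEX_FREQS))
  } else {
    m <- max(values)
    if (m <= 0) stop("max-scaling needs a positive maximum")
    m
  }
  structure(values / scale, method = method, scale = scale)
}

#' Landscape matrix of electrode means
#'
#' Arranges one participant/modality/index set of per-electrode means on the
#' 12 x 12 scalp grid, preserving the two empty reference cells as `NA`.
#'
#' @param electrode_means numeric vector of per-electrode means, named by
#'   channel id or ordered by channel id; alternatively the `electrode` data
#'   frame from [hierarchical_means()] restricted to one participant and
#'   modality, with `index` naming the column to map.
#' @param layout a `sensor_layout`.
#' @param index index column when a data frame is given.
#' @return 12 x 12 numeric matrix.
#' @export
landscape_matrix <- function(electrode_means, layout, index = "H") {
  if (is.data.frame(electrode_means)) {
    if (nrow(unique(electrode_means[, c("participant", "modality")])) != 1) {
      stop("landscape_matrix expects a single participant and modality")
    }
    v <- electrode_means[[index]]
    names(v) <- electrode_means$electrode
    electrode_means <- v
  }
  map_to_grid(electrode_means, layout)
}
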