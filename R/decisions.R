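#' Unequal-variance (Welch) two-sample t-test with decision
#'
#' Tests H0: equal means between two sets of participant-level index values
#' using the Welch statistic with Satterthwaite degrees of freedom
#' (two-sided). The decision is 1 (reject) iff `p < alpha`. A `borderline`
#' flag marks p-values within 0.005 of `alpha`, mirroring the convention of
#' footnoting decisions that fall very close to the significance level.
#'
#' Degenerate inputs: when both samples have zero variance the test is
#' decided by the means alone (`p = 1` if equal, else decision 1 with the
#' p-value flagged degenerate).
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @param alpha significance level, default 0.05.
#' @return list with `t`, `df`, `p`, `decision` (0/1), `borderline`,
#'   `degenerate`.
#' @export
welch_t_test <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t_test needs at least 2 values per sample")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = NA_real_, p = 1, decision = 0L,
                  borderline = FALSE, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0,
                decision = 1L, borderline = FALSE, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  p <- ht$p.value
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       decision = as.integer(p < alpha),
       borderline = abs(p - alpha) < 0.005,
       degenerate = FALSE)
}

#' Pairwise decision matrix over modalities for one index
#'
#' Runs [welch_t_test()] on every unordered pair of modalities for one
#' group's participant-level values of one index, and stores the binary
#' decisions (with companion p-values and borderline flags) in a symmetric
#' modality x modality matrix with an undefined diagonal.
#'
#' @param data data frame with columns `modality` and `value` (one row per
#'   participant per modality) for a single group and index.
#' @param alpha significance level.
#' @param modalities modality order for the matrix, default [MODALITIES].
#' @param index,group optional labels carried in the result.
#' @return a `decision_matrix`: list with matrices `decisions`, `p`,
#'   `borderline`, plus `alpha`, `index`, `group`.
#' @export
pairwise_decision_matrix <- function(data, alpha = 0.05,
                                     modalities = MODALITIES,
                                     index = NA_character_,
                                     group = NA_character_) {
  missing <- setdiff(modalities, unique(data$modality))
  if (length(missing)) {
    stop("missing modality: ", paste(missing, collapse = ", "))
  }
  vals <- split(data$value, factor(data$modality, levels = modalities))
  small <- names(vals)[vapply(vals, length, integer(1)) < 2]
  if (length(small)) {
    stop("need >= 2 participants per modality; too few in: ",
         paste(small, collapse = ", "))
  }
  k <- length(modalities)
  dm <- matrix(NA_integer_, k, k, dimnames = list(modalities, modalities))
  pm <- matrix(NA_real_, k, k, dimnames = list(modalities, modalities))
  bm <- matrix(FALSE, k, k, dimnames = list(modalities, modalities))
  diag(bm) <- NA
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      w <- welch_t_test(vals[[i]], vals[[j]], alpha = alpha)
      dm[i, j] <- dm[j, i] <- w$decision
      pm[i, j] <- pm[j, i] <- w$p
      bm[i, j] <- bm[j, i] <- w$borderline
    }
  }
  structure(list(decisions = dm, p = pm, borderline = bm, alpha = alpha,
                 index = index, group = group),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat("decision_matrix (index", x$index, ", group", x$group,
      ", alpha", x$alpha, ")\n")
  print(x$decisions)
  invisible(x)
}

#' Combine four per-index decisions into one verdict
#'
#' The conservative overall criterion over the four indices (H, PSk, TP,
#' DFs): Reject H0 when 3 or 4 individual tests reject, Neutral (ambiguous)
#' when exactly 2 reject, Accept when 0 or 1 reject.
#'
#' @param d vector of exactly four binary decisions (0/1).
#' @return `"Accept"`, `"Neutral"` or `"Reject"`.
#' @examples
#' combine_decisions(c(1, 1, 1, 1))  # Reject
#' combine_decisions(c(1, 1, 0, 0))  # Neutral
#' combine_decisions(c(0, 0, 0, 0))  # Accept
#' @export
combine_decisions <- function(d) {
  if (length(d) != 4 || !all(d %in% c(0, 1))) {
    stop("combine_decisions expects four 0/1 entries")
  }
  n <- sum(d)
  if (n >= 3) "Reject" else if (n == 2) "Neutral" else "Accept"
}

#' Combined decision matrix over all four indices
#'
#' Applies [combine_decisions()] cell-wise to four decision matrices (H,
#' PSk, TP, DFs) that share group and modality order. Rejection counts are
#' retained for audit. With `borderline_as_reject = TRUE`, accepted cells
#' flagged borderline (p just above alpha) count as rejections — a
#' convention under which a cell with two clear rejections plus a borderline
#' acceptance is classified Reject rather than Neutral.
#'
#' @param dms list of four `decision_matrix` objects.
#' @param borderline_as_reject count borderline acceptances as rejections.
#' @return a `combined_decision_matrix`: list with `verdict` (character
#'   matrix), `counts` (rejections per cell), `group`, `indices`.
#' @export
combined_matrix <- function(dms, borderline_as_reject = FALSE) {
  if (length(dms) != 4) stop("need exactly four decision matrices")
  mods <- colnames(dms[[1]]$decisions)
  for (dm in dms[-1]) {
    if (!identical(colnames(dm$decisions), mods)) {
      stop("decision matrices disagree on modality sets")
    }
    if (!identical(dm$group, dms[[1]]$group)) {
      stop("decision matrices disagree on group")
    }
  }
  eff <- lapply(dms, function(dm) {
    d <- dm$decisions
    if (borderline_as_reject) {
      flip <- !is.na(d) & d == 0L & !is.na(dm$borderline) & dm$borderline
      d[flip] <- 1L
    }
    d
  })
  counts <- Reduce(`+`, eff)
  verdict <- matrix(NA_character_, length(mods), length(mods),
                    dimnames = list(mods, mods))
  off <- which(!is.na(counts))
  verdict[off] <- c("Accept", "Accept", "Neutral", "Reject", "Reject")[counts[off] + 1L]
  structure(list(verdict = verdict, counts = counts,
                 group = dms[[1]]$group,
                 indices = vapply(dms, function(d) d$index, character(1)),
                 borderline_as_reject = borderline_as_reject),
            class = "combined_decision_matrix")
}

#' @export
print.combined_decision_matrix <- function(x, ...) {
  cat("combined_decision_matrix (group", x$group, ")\n")
  print(x$verdict, quote = FALSE)
  invisible(x)
}

#' Decision matrices of the full cohort
#'
#' Builds, for each group, the four per-index decision matrices and their
#' combined matrix from a participant-level summary table.
#'
#' @param participant the `participant` data frame from
#'   [hierarchical_means()].
#' @param alpha significance level.
#' @param indices index columns to test.
#' @param borderline_as_reject passed to [combined_matrix()].
#' @return named list per group: list of `decision_matrix` per index plus
#'   `combined`.
#' @export
cohort_decisions <- function(participant, alpha = 0.05,
                             indices = c("H", "PSk", "TP", "DFs"),
                             borderline_as_reject = FALSE) {
  out <- list()
  for (g in unique(participant$group)) {
    sub <- participant[participant$group == g, ]
    dms <- lapply(indices, function(ix) {
      pairwise_decision_matrix(
        data.frame(modality = sub$modality, value = sub[[ix]]),
        alpha = alpha, modalities = intersect(MODALITIES, unique(sub$modality)),
        index = ix, group = g)
    })
    names(dms) <- indices
    out[[g]] <- c(dms, list(combined = combined_matrix(
      dms, borderline_as_reject = borderline_as_reject)))
  }
  out
}

#' Bundled reference decision tables
#'
#' Loads the reference set of pairwise test outcomes (per index and group)
#' and the published combined verdicts shipped with the package, as
#' `decision_matrix` objects without p-values (the source tables print only
#' the binary outcomes plus borderline footnotes).
#'
#' @return list with `matrices` (per group, per index `decision_matrix`) and
#'   `combined` (per group verdict matrix).
#' @export
reference_decisions <- function() {
  path <- system.file("extdata", "reference_decisions.csv",
                      package = "eegstates")
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cpath <- system.file("extdata", "reference_combined.csv",
                       package = "eegstates")
  craw <- utils::read.csv(cpath, comment.char = "#", stringsAsFactors = FALSE)
  mods <- MODALITIES
  mk <- function(sub, index, group) {
    dm <- matrix(NA_integer_, 6, 6, dimnames = list(mods, mods))
    bm <- matrix(FALSE, 6, 6, dimnames = list(mods, mods))
    diag(bm) <- NA
    for (i in seq_len(nrow(sub))) {
      a <- sub$mod_a[i]; b <- sub$mod_b[i]
      dm[a, b] <- dm[b, a] <- sub$decision[i]
      bm[a, b] <- bm[b, a] <- sub$borderline[i]
    }
    structure(list(decisions = dm, p = matrix(NA_real_, 6, 6,
                                              dimnames = list(mods, mods)),
                   borderline = bm, alpha = 0.05, index = index, group = group),
              class = "decision_matrix")
  }
  matrices <- list()
  for (g in unique(raw$group)) {
    matrices[[g]] <- lapply(split(raw[raw$group == g, ],
                                  raw$index[raw$group == g]),
                            function(sub) mk(sub, sub$index[1], g))
    # keep canonical index order
    matrices[[g]] <- matrices[[g]][c("H", "PSk", "TP", "DFs")]
  }
  combined <- list()
  for (g in unique(craw$group)) {
    vm <- matrix(NA_character_, 6, 6, dimnames = list(mods, mods))
    sub <- craw[craw$group == g, ]
    for (i in seq_len(nrow(sub))) {
      vm[sub$mod_a[i], sub$mod_b[i]] <- vm[sub$mod_b[i], sub$mod_a[i]] <-
        sub$verdict[i]
    }
    combined[[g]] <- vm
  }
  list(matrices = matrices, combined = combined)
}
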