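#' D'Agostino K-squared normality test
#'
#' Omnibus normality test combining the transformed sample skewness (Z1) and
#' kurtosis (Z2) into `K2 = Z1^2 + Z2^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom (D'Agostino, Belanger & D'Agostino
#' 1990). Provided here because no installed package exposes it.
#'
#' @param x numeric vector, `n >= 8` (the kurtosis transformation is
#'   unstable below that).
#' @return list with `statistic` (K2), `z_skew`, `z_kurt`, `p`.
#' @export
dagostino_k2 <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 8) stop("dagostino_k2 needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness transform
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / a + sqrt((Y / a)^2 + 1))

  # kurtosis transform
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2, z_skew = z1, z_kurt = z2,
       p = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Robustness battery over modalities
#'
#' Orchestrates the standard statistical checks around the pairwise Welch
#' decisions for one group and index: omnibus modality effects (one-way
#' ANOVA, repeated-measures ANOVA, Friedman), pairwise Welch t-tests with
#' Bonferroni correction, pairwise Wilcoxon signed-rank tests, and four
#' normality diagnostics per modality (Shapiro-Wilk, Anderson-Darling,
#' D'Agostino K-squared, Kolmogorov-Smirnov against a fitted normal).
#' The bespoke content is the orchestration and report schema; each entry is
#' computed by the established base-R / nortest routine.
#'
#' Repeated-measures entries (RM-ANOVA, Friedman, paired Wilcoxon) require a
#' complete participant x modality design; with unbalanced input they are
#' marked unavailable and the rest is still computed.
#'
#' @param data data frame with columns `participant`, `modality`, `value`
#'   for a single group and index.
#' @param alpha significance level used for the summary flags.
#' @return a `robustness_report` list with elements `omnibus`,
#'   `pairwise_bonferroni`, `pairwise_wilcoxon`, `normality`, `alpha`.
#' @export
robustness_battery <- function(data, alpha = 0.05) {
  data$modality <- factor(data$modality,
                          levels = intersect(MODALITIES, unique(data$modality)))
  mods <- levels(data$modality)
  if (length(mods) < 2) stop("need at least two modalities")

  balanced <- {
    tab <- table(data$participant, data$modality)
    all(tab == 1)
  }

  omnibus <- list()
  aw <- stats::oneway.test(value ~ modality, data = data, var.equal = FALSE)
  omnibus$oneway_anova <- list(statistic = unname(aw$statistic),
                               df = unname(aw$parameter),
                               p = aw$p.value)
  if (balanced) {
    rm_fit <- stats::aov(value ~ modality + Error(factor(participant)),
                         data = data)
    smry <- summary(rm_fit)[["Error: Within"]][[1]]
    omnibus$rm_anova <- list(statistic = smry[["F value"]][1],
                             df = unname(smry[["Df"]]),
                             p = smry[["Pr(>F)"]][1])
    fr <- stats::friedman.test(value ~ modality | participant, data = data)
    omnibus$friedman <- list(statistic = unname(fr$statistic),
                             df = unname(fr$parameter), p = fr$p.value)
  } else {
    omnibus$rm_anova <- omnibus$friedman <-
      list(statistic = NA_real_, df = NA_real_, p = NA_real_,
           note = "unavailable: unbalanced repeated-measures design")
  }

  npair <- choose(length(mods), 2)
  pairs <- utils::combn(mods, 2)
  bonf <- data.frame(mod_a = pairs[1, ], mod_b = pairs[2, ],
                     p = NA_real_, p_adj = NA_real_, wilcoxon_p = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(npair)) {
    xa <- data$value[data$modality == bonf$mod_a[i]]
    xb <- data$value[data$modality == bonf$mod_b[i]]
    bonf$p[i] <- welch_t_test(xa, xb, alpha = alpha)$p
    if (balanced) {
      pa <- data[data$modality == bonf$mod_a[i], ]
      pb <- data[data$modality == bonf$mod_b[i], ]
      pb <- pb[match(pa$participant, pb$participant), ]
      bonf$wilcoxon_p[i] <- suppressWarnings(
        stats::wilcox.test(pa$value, pb$value, paired = TRUE)$p.value)
    }
  }
  bonf$p_adj <- pmin(bonf$p * npair, 1)
  bonf$significant <- bonf$p_adj < alpha

  normality <- lapply(mods, function(m) {
    v <- data$value[data$modality == m]
    list(
      shapiro_wilk = tryCatch(stats::shapiro.test(v)$p.value,
                              error = function(e) NA_real_),
      anderson_darling = tryCatch(nortest::ad.test(v)$p.value,
                                  error = function(e) NA_real_),
      dagostino_k2 = tryCatch(dagostino_k2(v)$p,
                              error = function(e) NA_real_),
      kolmogorov_smirnov = tryCatch(
        suppressWarnings(stats::ks.test(v, "pnorm", mean(v),
                                        stats::sd(v))$p.value),
        error = function(e) NA_real_)
    )
  })
  names(normality) <- mods

  structure(list(omnibus = omnibus,
                 pairwise_bonferroni = bonf[, c("mod_a", "mod_b", "p",
                                                "p_adj", "significant")],
                 pairwise_wilcoxon = bonf[, c("mod_a", "mod_b", "wilcoxon_p")],
                 normality = normality, alpha = alpha,
                 balanced = balanced),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("robustness_report (alpha", x$alpha, ")\n")
  cat(sprintf("  one-way ANOVA p = %.4g; RM-ANOVA p = %.4g; Friedman p = %.4g\n",
              x$omnibus$oneway_anova$p, x$omnibus$rm_anova$p,
              x$omnibus$friedman$p))
  cat("  Bonferroni-significant pairs:",
      sum(x$pairwise_bonferroni$significant), "of",
      nrow(x$pairwise_bonferroni), "\n")
  invisible(x)
}
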