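toy_frame <- function() {
  # 1 participant, 1 modality, 2 electrodes x 3 windows with known means
  data.frame(
    participant = "P01", modality = "MED", group = "Meditator",
    electrode = rep(1:2, each = 3), window = rep(1:3, 2),
    H = c(1, 2, 3, 3, 4, 5), PSk = rep(0.5, 6),
    TP = c(2, 2, 2, 4, 4, 4), DF = c(8, 10, 12, 10, 10, 10),
    band = "Alpha", stringsAsFactors = FALSE)
}

test_that("hierarchical means chain window -> electrode -> participant", {
  hm <- hierarchical_means(toy_frame())
  expect_equal(hm$electrode$H, c(2, 4))
  expect_equal(hm$participant$H, 3)
  expect_equal(hm$participant$TP, 3)
  # DFs = sd of electrode mean DF values (10, 10)
  expect_equal(hm$participant$DFs, 0)
  # means stay within the window-value range
  expect_true(all(hm$electrode$H >= c(1, 3) & hm$electrode$H <= c(3, 5)))
  expect_error(hierarchical_means(toy_frame()[0, ]), "empty")
})

test_that("means are invariant to row order", {
  fr <- toy_frame()
  hm1 <- hierarchical_means(fr)
  hm2 <- hierarchical_means(fr[sample(nrow(fr)), ])
  expect_equal(hm1$electrode, hm2$electrode)
  expect_equal(hm1$participant, hm2$participant)
})

test_that("group summary reproduces the t-quantile confidence interval", {
  gs <- group_summary(c(1, 2, 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sd, 1)
  expect_equal(gs$ci_half, 4.30265 / sqrt(3), tolerance = 1e-5)

  same <- group_summary(c(2, 2, 2, 2))
  expect_equal(same$ci_half, 0)
  expect_error(group_summary(5), "at least 2")
})

test_that("the confidence half-width shrinks with group size at fixed SD", {
  widths <- vapply(c(3, 5, 9, 11, 20), function(n) {
    stats::qt(0.975, n - 1) / sqrt(n)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("normalization uses the entropy ratio for H and max for others", {
  h <- normalize_index(log2(45), "H")
  expect_equal(as.numeric(h), 1)
  expect_equal(attr(h, "method"), "entropy_ratio")

  tp <- normalize_index(c(2, 4), "TP")
  expect_equal(as.numeric(tp), c(0.5, 1))

  psk <- normalize_index(c(0.3, 0.3), "PSk")
  expect_equal(as.numeric(psk), c(1, 1))
  expect_error(normalize_index(c(0, 0), "TP"), "positive maximum")

  # denormalization via the stored factor recovers the input
  v <- c(0.12, 3.4, 2.2)
  nv <- normalize_index(v, "DFs")
  expect_equal(as.numeric(nv) * attr(nv, "scale"), v, tolerance = 1e-12)
})

test_that("landscape matrices preserve sentinels and detect missing electrodes", {
  lay <- test_layout()
  g <- landscape_matrix(stats::setNames(rep(2.5, 128), 1:128), lay)
  expect_equal(sum(is.na(g)), 2)
  expect_true(all(g[!is.na(g)] == 2.5))
  expect_error(landscape_matrix(stats::setNames(rep(1, 127), 1:127), lay))
})

test_that("occipital alpha boost lowers posterior H relative to frontal", {
  lay <- test_layout()
  rec <- simulate_recording(state_profile("MED"), lay, 4000, seed = 9,
                            participant_id = "P01", group = "Meditator")
  fr <- compute_index_frame(segment_windows(preprocess_recording(rec)))
  hm <- hierarchical_means(fr)
  grid <- landscape_matrix(hm$electrode, lay, index = "H")
  frontal <- mean(grid[2:3, ], na.rm = TRUE)
  occipital <- mean(grid[10:12, ], na.rm = TRUE)
  expect_lt(occipital, frontal)
})
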