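test_that("welch_t_test matches the textbook oracle and handles edge cases", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  w <- welch_t_test(x, y)
  o <- welch_oracle(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-9)
  expect_equal(w$df, o$df, tolerance = 1e-9)
  expect_equal(w$p, o$p, tolerance = 1e-9)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$decision, 0L)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")

  const <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
  expect_true(const$degenerate)
  shifted <- welch_t_test(c(2, 2), c(3, 3))
  expect_equal(shifted$decision, 1L)
  expect_true(shifted$degenerate)
})

test_that("welch_t_test is antisymmetric in its arguments", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(6, 0.5)
    a <- welch_t_test(x, y); b <- welch_t_test(y, x)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
  }
})

test_that("p-values fall monotonically with the mean shift", {
  set.seed(22)
  x <- rnorm(10)
  y0 <- rnorm(10)
  y0 <- y0 - mean(y0) + mean(x)  # anchored at equal means
  shifts <- seq(0, 3, by = 0.5)
  ps <- vapply(shifts, function(s) welch_t_test(x, y0 + s)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("pairwise decision matrices detect separation and reject bad input", {
  set.seed(30)
  mods <- MODALITIES
  vals <- do.call(rbind, lapply(mods, function(m) {
    data.frame(modality = m, value = rnorm(11, mean = 0, sd = 1))
  }))
  # shift one pair apart by 5 pooled SDs
  vals$value[vals$modality == "VDO"] <- vals$value[vals$modality == "VDO"] + 5
  dm <- pairwise_decision_matrix(vals, index = "H", group = "Meditator")
  expect_equal(dm$decisions["MED", "VDO"], 1L)
  expect_equal(dm$decisions, t(dm$decisions))
  expect_true(all(is.na(diag(dm$decisions))))

  expect_error(pairwise_decision_matrix(vals[vals$modality != "IMG", ]),
               "missing modality: IMG")
  one <- do.call(rbind, lapply(mods, function(m) {
    data.frame(modality = m, value = 1)
  }))
  expect_error(pairwise_decision_matrix(one), ">= 2 participants")
})

test_that("the combination rule follows the 3-of-4 criterion", {
  expect_equal(combine_decisions(c(1, 1, 1, 1)), "Reject")
  expect_equal(combine_decisions(c(0, 0, 0, 0)), "Accept")
  expect_equal(combine_decisions(c(1, 1, 0, 0)), "Neutral")
  expect_equal(combine_decisions(c(1, 1, 1, 0)), "Reject")
  expect_equal(combine_decisions(c(1, 0, 0, 0)), "Accept")
  expect_error(combine_decisions(c(1, 1, 1)), "four")
  expect_error(combine_decisions(c(1, 1, 1, 2)), "0/1")
})

test_that("combined matrices aggregate cell-wise with audit counts", {
  mods <- MODALITIES
  mk <- function(v, index) {
    d <- matrix(v, 6, 6, dimnames = list(mods, mods))
    diag(d) <- NA_integer_
    structure(list(decisions = d,
                   p = matrix(NA_real_, 6, 6),
                   borderline = matrix(FALSE, 6, 6),
                   alpha = 0.05, index = index, group = "Meditator"),
              class = "decision_matrix")
  }
  allz <- combined_matrix(lapply(c("H", "PSk", "TP", "DFs"), mk, v = 0L))
  expect_true(all(allz$verdict[upper.tri(allz$verdict)] == "Accept"))
  allo <- combined_matrix(lapply(c("H", "PSk", "TP", "DFs"), mk, v = 1L))
  expect_true(all(allo$verdict[upper.tri(allo$verdict)] == "Reject"))
  expect_true(all(allo$counts[upper.tri(allo$counts)] == 4))

  bad <- mk(0L, "H")
  bad$group <- "Non-Meditator"
  expect_error(combined_matrix(list(bad, mk(0L, "PSk"), mk(0L, "TP"),
                                    mk(0L, "DFs"))), "group")
})

test_that("the bundled reference tables reproduce the published verdicts", {
  ref <- reference_decisions()
  for (g in GROUPS) {
    cm <- combined_matrix(ref$matrices[[g]])
    agree <- cm$verdict == ref$combined[[g]]
    if (g == "Meditator") {
      # one published cell is internally inconsistent with the 3-of-4 rule
      expect_equal(sum(!agree, na.rm = TRUE), 2)  # symmetric cell counted twice
      expect_false(agree["MM", "VDO"])
      expect_equal(cm$counts["MM", "VDO"], 2)
      # the borderline-counts-as-reject convention recovers the published cell
      cm2 <- combined_matrix(ref$matrices[[g]], borderline_as_reject = TRUE)
      expect_true(all(cm2$verdict == ref$combined[[g]], na.rm = TRUE))
    } else {
      expect_true(all(agree, na.rm = TRUE))
    }
  }
})
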