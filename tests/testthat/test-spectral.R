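test_that("window_psd peaks at the tone frequency", {
  fs <- 1000
  t <- (0:499) / fs
  ws <- window_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(ws$freq, 4:48)
  expect_equal(length(ws$power), 45)
  expect_equal(ws$freq[which.max(ws$power)], 10)

  # two tones: bins 10 and 30 dominate, cross-checked with a plain DFT
  # oracle; the Hann main lobe of a 0.5 s window spans about +/- 2 Hz, so
  # neighbours within 2 Hz of a tone are part of its peak
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t)
  ws2 <- window_psd(x, fs)
  near <- ws2$freq %in% c(8:12, 28:32)
  expect_gt(ws2$power[ws2$freq == 10], 10 * max(ws2$power[!near]))
  expect_gt(ws2$power[ws2$freq == 30], 10 * max(ws2$power[!near]))
  orc <- dft_power_oracle(x, fs, 4:48)
  expect_setequal(ws2$freq[order(ws2$power, decreasing = TRUE)[1:2]],
                  (4:48)[order(orc, decreasing = TRUE)[1:2]])

  expect_error(window_psd(rep(0, 500), fs), "zero total power")
})

test_that("spectrum normalization yields a probability distribution and TP", {
  d <- spectrum_to_distribution(rep(1, 45), freq = 4:48)
  expect_equal(d$tp, 45)
  expect_equal(d$p, rep(1 / 45, 45))
  expect_equal(sum(d$p), 1, tolerance = 1e-12)

  toy <- spectrum_to_distribution(c(3, 1), freq = c(10, 20))
  expect_equal(toy$p, c(0.75, 0.25))
  expect_equal(toy$tp, 4)

  expect_error(spectrum_to_distribution(c(1, -1)), "non-negative")
  expect_error(spectrum_to_distribution(c(0, 0)), "zero total power")
})

test_that("entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(1 / 45, 45)), log2(45))
  expect_equal(shannon_entropy(c(1, rep(0, 44))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
})

test_that("entropy is maximal only at uniformity and falls toward a delta", {
  u <- rep(1 / 45, 45)
  hmax <- shannon_entropy(u)
  delta <- c(1, rep(0, 44))
  lambdas <- seq(0, 1, by = 0.1)
  hs <- vapply(lambdas, function(l) shannon_entropy((1 - l) * u + l * delta),
               numeric(1))
  expect_equal(hs[1], hmax)
  expect_true(all(diff(hs) < 0))
  set.seed(3)
  for (i in 1:20) {
    p <- stats::runif(45); p <- p / sum(p)
    expect_lt(shannon_entropy(p), hmax + 1e-12)
  }
})

test_that("Pearson skewness matches hand-computed moments", {
  expect_equal(pearson_skewness(c(0.25, 0.5, 0.25), freq = c(10, 11, 12)), 0)
  expect_equal(pearson_skewness(c(0.75, 0.25), freq = c(10, 20)),
               abs(12.5 - 10) / 4.330127, tolerance = 1e-6)
  expect_equal(pearson_skewness(c(1, rep(0, 10)), freq = 4:14), 0)
})

test_that("dominant frequency and band follow the stated tie rules", {
  mk <- function(pw) structure(list(freq = 4:48, power = pw),
                               class = "window_spectrum")
  pw <- rep(0.01, 45); pw[4:48 == 10] <- 1
  r <- dominant_frequency_and_band(mk(pw))
  expect_equal(r$df, 10)
  expect_equal(r$band, "Alpha")

  pw2 <- rep(0.01, 45); pw2[4:48 %in% c(10, 20)] <- 1
  expect_equal(dominant_frequency_and_band(mk(pw2))$df, 10)

  # flat spectrum: the band with most bins wins by summed power (Gamma)
  r3 <- dominant_frequency_and_band(mk(rep(1, 45)))
  expect_equal(r3$band, "Gamma")
  expect_equal(r3$df, 4)  # all-tie resolves to the lowest frequency
})

test_that("band dominance time counts half-second windows", {
  seqs <- rep(c("Alpha", "Theta"), c(760, 80))
  out <- band_dominance_time(seqs, levels = c("Theta", "Alpha"))
  expect_equal(out[["Alpha"]], 380)
  expect_equal(sum(out), 840 * 0.5)

  one <- band_dominance_time(rep("Alpha", 10))
  expect_equal(one[["Alpha"]], 5)
  expect_error(band_dominance_time(character(0)), "empty")
})

test_that("mean modes and DFs behave as stated", {
  expect_equal(mean_mode_per_electrode(rep(10, 5)), 10)
  expect_equal(mean_mode_per_electrode(c(8, 10, 12)), 10)
  expect_equal(mean_mode_per_electrode(c(4, 48)), 26)
  expect_equal(dfs_index(rep(7, 128)), 0)
  expect_equal(dfs_index(c(8, 10, 12)), 2)
  expect_error(dfs_index(10), "two electrodes")
})

test_that("index frame has the right shape and treats channels identically", {
  fs <- 1000
  t <- (0:2999) / fs
  x <- sin(2 * pi * 10 * t) + 0.3 * sin(2 * pi * 21 * t)
  rec <- recording(matrix(x, 3, 3000, byrow = TRUE), fs = fs)
  fr <- compute_index_frame(segment_windows(rec))
  expect_equal(nrow(fr), 3 * 6)
  expect_equal(attr(fr, "n_flagged"), 0)
  # identical channels -> identical index values
  for (col in c("H", "PSk", "TP", "DF")) {
    expect_equal(tapply(fr[[col]], fr$window, function(v) diff(range(v))),
                 tapply(fr[[col]] * 0, fr$window, sum))
  }
  expect_true(all(fr$band == "Alpha"))
})

test_that("scaling a signal scales TP by c^2 and fixes H, PSk, DF", {
  set.seed(5)
  sig <- matrix(rnorm(2 * 1000), 2, 1000)
  f1 <- compute_index_frame(segment_windows(recording(sig, fs = 1000)))
  cc <- 3.2
  f2 <- compute_index_frame(segment_windows(recording(cc * sig, fs = 1000)))
  expect_equal(f2$TP, cc^2 * f1$TP, tolerance = 1e-9)
  expect_equal(f2$H, f1$H, tolerance = 1e-9)
  expect_equal(f2$PSk, f1$PSk, tolerance = 1e-9)
  expect_identical(f2$DF, f1$DF)
})

test_that("an all-zero recording is rejected as degenerate", {
  rec <- recording(matrix(0, 2, 1000), fs = 1000)
  expect_error(compute_index_frame(segment_windows(rec)), "degenerate")
})

test_that("a seeded alpha-profile recording is predominantly alpha-dominant", {
  lay <- test_layout()
  rec <- simulate_recording(state_profile("MED"), lay, 3000, seed = 42)
  fr <- compute_index_frame(segment_windows(preprocess_recording(rec)))
  expect_equal(names(which.max(table(fr$band))), "Alpha")
  expect_lte(nrow(fr), 6 * 128)
})
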