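test_that("state profiles have the constructed spectral shapes", {
  med <- state_profile("MED")
  expect_equal(names(which.max(med$band_weights)), "Alpha")
  expect_gt(med$band_weights["Alpha"], 2 * max(med$band_weights[-2]))

  vdo <- state_profile("VDO")
  expect_lt(max(vdo$band_weights), 2 * min(vdo$band_weights))

  expect_error(state_profile("XYZ"), "unknown state profile")

  # total oscillatory power ranks MED highest, VDO lowest
  tots <- vapply(MODALITIES, function(m) sum(state_profile(m)$band_weights),
                 numeric(1))
  expect_equal(names(which.max(tots)), "MED")
  expect_equal(names(which.min(tots)), "VDO")
})

test_that("simulation is deterministic given a seed", {
  lay <- test_layout()
  r1 <- simulate_recording(state_profile("MED"), lay, 1000, seed = 13)
  r2 <- simulate_recording(state_profile("MED"), lay, 1000, seed = 13)
  expect_identical(r1$signal, r2$signal)
  expect_error(simulate_recording(state_profile("MED"), lay, 500),
               "at least 1000 ms")
})

test_that("generated spectra match the profile's band fractions within 15%", {
  lay <- test_layout()
  for (m in c("VDO", "MM")) {
    prof <- state_profile(m)
    rec <- simulate_recording(prof, lay, 60000, seed = 3)
    fr <- segment_windows(rec)
    d <- dim(fr$windows)
    segmat <- matrix(aperm(fr$windows, c(3, 1, 2)), nrow = d[3])
    pw <- rowMeans(eegstates:::psd_cols(segmat, fr$fs))
    bf <- eegstates:::band_of_freq(default_bands(), INDEX_FREQS)
    meas <- tapply(pw, bf, sum)
    meas <- as.numeric(meas) / sum(meas)
    expected <- expected_band_fractions(prof)
    expect_equal(meas, as.numeric(expected), tolerance = 0.15)
  }
})

test_that("MED recordings are recovered as alpha-dominant across seeds", {
  lay <- test_layout()
  hits <- vapply(1:50, function(s) {
    rec <- simulate_recording(state_profile("MED"), lay, 2000, seed = 1000 + s)
    fr <- compute_index_frame(segment_windows(rec))
    names(which.max(table(fr$band))) == "Alpha"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("occipital channels are alpha-dominant nearly all the time in MED", {
  lay <- test_layout()
  rec <- simulate_recording(state_profile("MED"), lay, 60000, seed = 1)
  fr <- compute_index_frame(segment_windows(preprocess_recording(rec)))
  occ <- which(eegstates:::channel_regions(lay) == "occipital")
  sub <- fr[fr$electrode %in% occ, ]
  expect_gte(mean(sub$band == "Alpha"), 0.8)
})

test_that("cohorts have the stated cardinality and reproduce bit-identically", {
  lay <- test_layout()
  co <- simulate_cohort(cohort_spec(seed = 5), lay, modalities = "MED",
                        duration_scale = 1 / 420)
  expect_equal(length(co$recordings), 20)
  expect_equal(nrow(co$manifest), 20)
  expect_equal(sum(co$manifest$group == "Meditator"), 11)
  expect_equal(sum(co$manifest$group == "Non-Meditator"), 9)

  co2 <- simulate_cohort(cohort_spec(seed = 5), lay, modalities = "MED",
                         duration_scale = 1 / 420)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$recordings[[1]]$signal, co2$recordings[[1]]$signal)

  expect_error(cohort_spec(n_meditators = 1), "at least 2")
})

test_that("meditators show lower entropy than non-meditators in MED", {
  lay <- test_layout()
  rejections <- vapply(1:50, function(s) {
    co <- simulate_cohort(cohort_spec(seed = 3000 + s), lay,
                          modalities = "MED", duration_scale = 1 / 420)
    h <- vapply(co$recordings, function(rec) {
      mean(compute_index_frame(segment_windows(rec))$H)
    }, numeric(1))
    med <- h[co$manifest$group == "Meditator"]
    non <- h[co$manifest$group == "Non-Meditator"]
    w <- welch_t_test(med, non)
    w$decision == 1L && mean(med) < mean(non)
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("experiment schedules carry the protocol constants", {
  expect_equal(nrow(experiment_schedule("WORDS")$trials), 20)
  expect_equal(nrow(experiment_schedule("IMG")$trials), 12)
  expect_equal(nrow(experiment_schedule("SENT")$trials), 20)
  mm <- experiment_schedule("MM")
  expect_equal(nrow(mm$trials), 28)
  expect_true(all(mm$trials$expected %in% 1:9))
  med <- experiment_schedule("MED")
  expect_equal(med$duration_ms, 420000)
  expect_equal(nrow(med$trials), 0)
  vdo <- experiment_schedule("VDO")
  expect_equal(vdo$duration_ms, 120000)
  expect_equal(nrow(vdo$trials), 0)
  expect_error(experiment_schedule("REST"), "unknown modality")

  for (m in c("WORDS", "IMG", "SENT", "MM")) {
    sc <- experiment_schedule(m)
    expect_true(all(diff(sc$trials$onset_ms) > 0))
    expect_true(all(sc$trials$onset_ms <= sc$duration_ms))
  }
})

test_that("digit reduction equals the digital root closed form", {
  expect_equal(mm_digit_reduce(7, 7), 4)
  expect_equal(mm_digit_reduce(2, 3), 6)
  expect_equal(mm_digit_reduce(9, 9), 9)
  for (a in 1:12) for (b in 1:12) {
    expect_equal(mm_digit_reduce(a, b), 1 + (a * b - 1) %% 9)
  }
  expect_error(mm_digit_reduce(0, 3), "positive")
})
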