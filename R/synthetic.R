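#' Spectral state profile of a modality
#'
#' Frozen generator profiles for the six experimental conditions. Each
#' profile holds band weights (target oscillatory power per band, arbitrary
#' units), a `1/f^beta` background exponent, a noise scale, and an optional
#' region modulation (multiplier on the profile's dominant band for channels
#' in given scalp regions).
#'
#' MED is narrowly alpha-dominant with the highest total power (eyes-closed
#' relaxation, posterior alpha boost); VDO is the broadest mixture with the
#' lowest total power; SENT, WORDS, MM and IMG are intermediate, ordered so
#' the expected spectral spread ranks MED < SENT < WORDS ~ MM < IMG < VDO.
#'
#' @param name one of `MODALITIES`.
#' @return an `eeg_state_profile`.
#' @export
state_profile <- function(name) {
  profiles <- list(
    MED   = list(weights = c("Theta" = 0.5, "Alpha" = 8.0, "L-Beta" = 0.4,
                             "H-Beta" = 0.3, "Gamma" = 0.2),
                 noise_scale = 0.3,
                 region_modulation = c(occipital = 1.6, parietal = 1.3)),
    SENT  = list(weights = c("Theta" = 0.9, "Alpha" = 5.2, "L-Beta" = 0.8,
                             "H-Beta" = 0.5, "Gamma" = 0.3),
                 noise_scale = 0.5, region_modulation = NULL),
    WORDS = list(weights = c("Theta" = 1.2, "Alpha" = 3.6, "L-Beta" = 1.1,
                             "H-Beta" = 0.7, "Gamma" = 0.4),
                 noise_scale = 0.6, region_modulation = NULL),
    MM    = list(weights = c("Theta" = 1.25, "Alpha" = 3.3, "L-Beta" = 1.15,
                             "H-Beta" = 0.8, "Gamma" = 0.4),
                 noise_scale = 0.6, region_modulation = NULL),
    IMG   = list(weights = c("Theta" = 1.2, "Alpha" = 2.0, "L-Beta" = 1.2,
                             "H-Beta" = 1.0, "Gamma" = 0.6),
                 noise_scale = 0.7, region_modulation = NULL),
    VDO   = list(weights = c("Theta" = 1.1, "Alpha" = 1.4, "L-Beta" = 1.2,
                             "H-Beta" = 1.1, "Gamma" = 0.9),
                 noise_scale = 0.8, region_modulation = NULL)
  )
  if (!name %in% names(profiles)) {
    stop("unknown state profile: ", name)
  }
  pr <- profiles[[name]]
  structure(list(name = name, band_weights = pr$weights,
                 one_over_f_exponent = 1, noise_scale = pr$noise_scale,
                 region_modulation = pr$region_modulation),
            class = "eeg_state_profile")
}

#' @export
print.eeg_state_profile <- function(x, ...) {
  cat("eeg_state_profile:", x$name, "\n")
  print(round(x$band_weights, 3))
  cat(sprintf("  1/f exponent %g, noise scale %g\n",
              x$one_over_f_exponent, x$noise_scale))
  invisible(x)
}

#' Expected spectral power density of a profile
#'
#' Ground-truth one-sided power density (per Hz) the generator synthesises:
#' band weights spread uniformly over their band, a `1/f^beta` background,
#' and a small white floor.
#'
#' @param profile an `eeg_state_profile`.
#' @param freq frequencies in Hz.
#' @param bands a `band_table`.
#' @param band_scale optional multiplier applied to the dominant band (used
#'   for region modulation and group effects).
#' @return numeric density at `freq`.
#' @keywords internal
profile_density <- function(profile, freq, bands = default_bands(),
                            band_scale = 1) {
  w <- profile$band_weights
  dom <- names(w)[which.max(w)]
  w[dom] <- w[dom] * band_scale
  dens <- profile$noise_scale * pmax(freq, 1)^(-profile$one_over_f_exponent) +
    profile$noise_scale * 0.02
  for (i in seq_len(nrow(bands))) {
    b <- bands$band[i]
    if (!b %in% names(w)) next
    inb <- freq >= bands$low[i] &
      (freq < bands$high[i] | (i == nrow(bands) & freq <= bands$high[i]))
    dens[inb] <- dens[inb] + w[[b]] / (bands$high[i] - bands$low[i])
  }
  dens
}

#' Expected band-power fractions of a profile
#'
#' Integrates the generator's ground-truth density over each band of the
#' index grid and normalizes to fractions; the reference for spectral
#' fidelity checks of generated signals.
#'
#' @param profile an `eeg_state_profile`.
#' @param bands a `band_table`.
#' @return named numeric vector of band-power fractions summing to 1.
#' @export
expected_band_fractions <- function(profile, bands = default_bands()) {
  f <- seq(min(INDEX_FREQS), max(INDEX_FREQS), by = 0.05)
  dens <- profile_density(profile, f, bands)
  bf <- band_of_freq(bands, f)
  tot <- tapply(dens, bf, sum)
  out <- as.numeric(tot) / sum(tot)
  names(out) <- names(tot)
  out
}

#' Simulate one multi-channel EEG recording
#'
#' Frequency-domain synthesis: each channel is an independent realisation of
#' random-phase noise whose power density follows the profile (band-limited
#' oscillatory power over a `1/f^beta` background plus a white floor), so
#' band bins fill realistically rather than as pure sine lines. Channels in
#' regions named by the profile's `region_modulation` get the stated
#' multiplier on the profile's dominant band. Deterministic given `seed`.
#'
#' @param profile an `eeg_state_profile`.
#' @param layout a `sensor_layout` (provides channel count and regions).
#' @param duration_ms recording length in ms (>= 1000).
#' @param fs sampling rate in Hz, default 1000.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param amplitude overall signal scale multiplier.
#' @param participant_id,modality,group metadata carried on the recording.
#' @param events optional event data frame.
#' @return an `eeg_recording`.
#' @export
simulate_recording <- function(profile, layout, duration_ms, fs = 1000,
                               seed = NULL, amplitude = 1,
                               participant_id = NA_character_,
                               modality = profile$name,
                               group = NA_character_,
                               events = data.frame(label = character(),
                                                   time_ms = numeric())) {
  stopifnot(inherits(profile, "eeg_state_profile"),
            inherits(layout, "sensor_layout"))
  if (duration_ms < 1000) stop("duration must be at least 1000 ms")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_ms * fs / 1000)
  nch <- layout$n_channels
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  df <- fs / n

  regions <- channel_regions(layout)
  mod <- profile$region_modulation
  scales <- rep(1, nch)
  if (!is.null(mod)) {
    for (r in names(mod)) scales[regions == r] <- mod[[r]]
  }

  # one density column per distinct region scale
  uniq <- sort(unique(scales))
  dens_by_scale <- vapply(uniq, function(s) profile_density(profile, f,
                                                           band_scale = s),
                          numeric(nf))
  amp <- sqrt(dens_by_scale * df / 2) * n  # |Z_k| per bin

  phases <- matrix(stats::runif(nf * nch, 0, 2 * pi), nf, nch)
  Z <- amp[, match(scales, uniq), drop = FALSE] * exp(1i * phases)
  X <- matrix(0i, n, nch)
  X[2:(nf + 1), ] <- Z
  if (n %% 2 == 0) {
    X[n:(n - nf + 2), ] <- Conj(Z[seq_len(nf - 1), , drop = FALSE])
    X[nf + 1, ] <- Mod(Z[nf, ])  # Nyquist bin must be real
  } else {
    X[n:(n - nf + 1), ] <- Conj(Z)
  }
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n * amplitude

  recording(t(x), fs = fs, events = events,
            participant_id = participant_id, modality = modality,
            group = group)
}

#' Cohort specification
#'
#' @param n_meditators,n_nonmeditators group sizes, defaults 11 and 9.
#' @param group_effect multiplicative alpha-weight boost (and broadband
#'   noise reduction) for meditator recordings; 1 means no group difference.
#' @param participant_sd log-normal SD of the per-recording participant
#'   variability applied to the dominant band weight and overall amplitude.
#' @param seed master seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_meditators = 11, n_nonmeditators = 9,
                        group_effect = 1.5, participant_sd = 0.15,
                        seed = 1) {
  if (n_meditators < 2 || n_nonmeditators < 2) {
    stop("need at least 2 participants per group")
  }
  structure(list(n_meditators = n_meditators,
                 n_nonmeditators = n_nonmeditators,
                 group_effect = group_effect,
                 participant_sd = participant_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a full cohort
#'
#' Generates one recording per participant x modality. Meditator recordings
#' carry the group effect: the Alpha band weight is multiplied by
#' `group_effect` and the broadband noise scale divided by it. Per-recording
#' variability (log-normal multipliers on the dominant band weight and the
#' overall amplitude) makes participant-level index values vary realistically.
#'
#' Sub-seeds are derived from the master seed by a fixed splitting rule,
#' `seed + 1009 * participant + 9973 * modality_index`, so cohorts are
#' reproducible and extensible; all randomness of a recording flows from its
#' sub-seed, independently across participant x modality cells.
#'
#' @param spec a [cohort_spec()].
#' @param layout a `sensor_layout`.
#' @param modalities modalities to simulate, default all six.
#' @param duration_scale multiplier on the protocol durations (use < 1 for
#'   reduced-scale experiments; recordings never drop below 1 s).
#' @param profiles named list of `eeg_state_profile` overrides; defaults to
#'   [state_profile()] per modality.
#' @return list with `recordings` (named list of `eeg_recording`) and
#'   `manifest` (ground-truth data frame).
#' @export
simulate_cohort <- function(spec = cohort_spec(), layout = load_layout(),
                            modalities = MODALITIES, duration_scale = 1,
                            profiles = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_meditators + spec$n_nonmeditators
  groups <- rep(GROUPS, c(spec$n_meditators, spec$n_nonmeditators))
  recordings <- list()
  manifest <- list()
  for (p in seq_len(n_total)) {
    pid <- sprintf("P%02d", p)
    for (m in modalities) {
      mi <- match(m, MODALITIES)
      sub_seed <- spec$seed + 1009L * p + 9973L * mi
      set.seed(sub_seed)
      prof <- if (!is.null(profiles) && m %in% names(profiles)) {
        profiles[[m]]
      } else {
        state_profile(m)
      }
      traits <- stats::rlnorm(2, 0, spec$participant_sd)
      dom <- names(prof$band_weights)[which.max(prof$band_weights)]
      prof$band_weights[dom] <- prof$band_weights[dom] * traits[1]
      if (groups[p] == "Meditator" && spec$group_effect != 1) {
        prof$band_weights["Alpha"] <- prof$band_weights["Alpha"] *
          spec$group_effect
        prof$noise_scale <- prof$noise_scale / spec$group_effect
      }
      sched <- experiment_schedule(m)
      dur <- max(1000, round(sched$duration_ms * duration_scale))
      ev <- sched$trials
      events <- if (nrow(ev)) {
        data.frame(label = ev$stimulus,
                   time_ms = pmin(ev$onset_ms * duration_scale, dur))
      } else {
        data.frame(label = character(), time_ms = numeric())
      }
      rec <- simulate_recording(prof, layout, duration_ms = dur,
                                seed = NULL, amplitude = traits[2],
                                participant_id = pid, modality = m,
                                group = groups[p], events = events)
      key <- paste(pid, m, sep = "_")
      recordings[[key]] <- rec
      manifest[[key]] <- data.frame(
        participant = pid, group = groups[p], modality = m,
        sub_seed = sub_seed, duration_ms = dur, n_trials = nrow(ev),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(recordings = recordings, manifest = manifest)
}

#' Experiment schedule of a modality
#'
#' The protocol constants: 7 min of meditation (MED) and about 2 min of
#' video (VDO) with no discrete trials; 20 scrambled words, 12 ambiguous
#' images, 28 spoken arithmetic items (Math Mind) and 20 sentences, each as
#' evenly spaced trials after a 2 s lead-in. Math Mind trials carry the
#' operand pair and the ground-truth single-digit answer obtained by
#' repeated digit summation.
#'
#' @param modality one of `MODALITIES`.
#' @return an `experiment_schedule`: list with `modality`, `duration_ms`,
#'   `trials` (data frame `stimulus`, `onset_ms`, `expected`).
#' @export
experiment_schedule <- function(modality) {
  if (!modality %in% MODALITIES) stop("unknown modality: ", modality)
  lead <- 2000
  trials <- switch(
    modality,
    MED = data.frame(stimulus = character(), onset_ms = numeric(),
                     expected = integer()),
    VDO = data.frame(stimulus = character(), onset_ms = numeric(),
                     expected = integer()),
    WORDS = data.frame(
      stimulus = sprintf("word_%02d", 1:20),
      onset_ms = lead + (0:19) * 4000,
      expected = rep(c(1L, 2L), 10)),
    IMG = data.frame(
      stimulus = sprintf("image_%02d", 1:12),
      onset_ms = lead + (0:11) * 10000,
      expected = NA_integer_),
    SENT = data.frame(
      stimulus = sprintf("sentence_%02d", 1:20),
      onset_ms = lead + (0:19) * 6000,
      expected = rep(1:3, length.out = 20)),
    MM = {
      ops <- expand.grid(b = 4:7, a = 3:9)
      data.frame(
        stimulus = sprintf("%d x %d", ops$a, ops$b),
        onset_ms = lead + (seq_len(28) - 1) * 8000,
        expected = mapply(mm_digit_reduce, ops$a, ops$b))
    })
  duration_ms <- switch(modality,
                        MED = 420000, VDO = 120000,
                        WORDS = lead + 20 * 4000,
                        IMG = lead + 12 * 10000,
                        SENT = lead + 20 * 6000,
                        MM = lead + 28 * 8000)
  structure(list(modality = modality, duration_ms = duration_ms,
                 trials = trials),
            class = "experiment_schedule")
}

#' Math Mind digit reduction
#'
#' Multiplies the operands and repeatedly sums the decimal digits of the
#' result until a single digit remains (the digital root): 7 x 7 = 49,
#' 4 + 9 = 13, 1 + 3 = 4.
#'
#' @param a,b positive integers.
#' @return a single digit 1-9.
#' @examples
#' mm_digit_reduce(7, 7)  # 4
#' @export
mm_digit_reduce <- function(a, b) {
  if (a < 1 || b < 1 || a != round(a) || b != round(b)) {
    stop("operands must be positive integers")
  }
  r <- a * b
  while (r > 9) {
    r <- sum(as.integer(strsplit(as.character(r), "")[[1]]))
  }
  as.integer(r)
}
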