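---
title: "Spectral indices and multi-index decisions for EEG cognitive states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral indices and multi-index decisions for EEG cognitive states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstates)
```

## The problem and the model

Relaxed, eyes-closed meditative states concentrate EEG power in the Alpha
band (roughly 8–13 Hz), most strongly over posterior cortex, while engaged
cognitive states spread power across Theta, Beta and Gamma. This package
quantifies that difference through four indices computed on 500 ms windows
of the power spectrum of every electrode of a 128-channel recording:

* **H** — spectral Shannon entropy, $H = -\sum_i p_i \log_2 p_i$, where
  $p_i = PW_i / TP$ is the normalized power in the 1 Hz bin at $i$ Hz,
  $i = 4, \dots, 48$ (45 bins). Low H means a concentrated (ordered)
  spectrum; the maximum is $\log_2 45 \approx 5.492$ bits.
* **TP** — total power, $TP = \sum_i PW_i$.
* **PSk** — Pearson's first skewness coefficient of the spectral
  distribution, $PSk = |\mathrm{mean} - \mathrm{mode}| / \mathrm{SD}$,
  with mean and SD the probability-weighted frequency moments and the mode
  the dominant frequency (the max-power bin). Zero for symmetric unimodal
  spectra.
* **DF / DFs** — the dominant frequency per window, its per-electrode mean
  across windows, and **DFs**, the sample standard deviation of those means
  across the 128 electrodes: a spatial dispersion measure of where the
  spectrum peaks.

Alpha-dominant states yield low H, PSk and DFs with high TP; broadband
engaged states the reverse. No single index separates every pair of
conditions, which motivates the combination rule below.

## Processing chain and its assumptions

Raw signals (channels × samples, 1000 Hz) are linearly detrended over the
whole recording, notch-filtered at 50 Hz (Q = 30) and band-passed 2–48 Hz
with a 4th-order Butterworth design applied at zero phase, so event
alignment is never skewed by filter delay. Event timestamps are shifted by
8 ms (amplifier anti-alias) + 14 ms (screen refresh) = 22 ms. The recording
is then cut into contiguous, non-overlapping 500 ms windows
($NW = \lfloor L / 500 \rfloor$, trailing remainder discarded).

Two zero-phase implementations are provided. The default multiplies each
channel's spectrum by the squared magnitude response of the filter cascade
— exactly the response a forward–backward pass realises — in one vectorised
FFT operation across all channels; `method = "filtfilt"` does the classic
per-channel forward–backward pass. They differ only in boundary handling
(circular vs. reflective) and agree away from the recording edges; the FFT
form is the default because it filters 128 channels two orders of magnitude
faster, which matters for the Monte-Carlo validation below.

The spectral estimator is a single-taper (Hann) periodogram per window,
zero-padded from 500 to 1000 samples. A 0.5 s window natively resolves
2 Hz; the unit-step 4–48 Hz index grid therefore requires an interpolation
choice, and zero-padding is the simplest, documented and swappable one.
Consequences worth knowing: adjacent 1 Hz bins are correlated, and the Hann
main lobe spans about ±2 Hz, so band powers bleed slightly across steep
band boundaries. Although the band-pass admits 2–48 Hz, the indices use
bins 4–48 Hz only; the 2–4 Hz content merely stabilises the filter edge.

Windows with zero total power are flagged and excluded from every
denominator; a recording with more than half of its electrode-windows
flagged is rejected as degenerate. Ties in the dominant frequency resolve
to the lowest frequency, ties between band powers to the lower band, and a
degenerate single-bin spectrum has $PSk = 0$ by convention (mean = mode).

The 128 channels map onto a 12 × 12 scalp grid (row 1 frontal, columns
split 6 + 6 by hemisphere) with cells (1,3) and (1,10) left empty as
prefrontal reference markers; 14 electrodes are doubled to fill the
remaining 142 cells symmetrically. The exact channel-to-cell table is
montage-specific and not published, so it is *data*: the bundled default is
a documented, replaceable construction that respects the region layout and
mirror symmetry, and any user table in the same CSV format is accepted and
validated (completeness, no collisions, reserved cells untouched).

## Aggregation and decisions

Indices are averaged level by level — windows within electrode, electrodes
within participant — exactly as the summary hierarchy chains them; with
unbalanced window counts the levels are *not* pooled. Group summaries carry
the two-sided t-based confidence half-width
$t_{1-\alpha/2,\,n-1}\, s / \sqrt{n}$. The printed formulas index the
t-quantile by $npg$; we read that as notational shorthand and use
$npg - 1$ degrees of freedom, the standard construction.

For cross-modality comparison H is normalized by its maximum $\log_2 45$
(an absolute ceiling, so the ratio is comparable across any collection),
while PSk, TP and DFs are scaled by the maximum over the compared
collection. Which collection defines the maximum is genuinely open in the
source material; we normalize jointly across both groups and all compared
modalities, and every normalized output carries its method and scale factor
so the choice is auditable and invertible.

Modality pairs are compared per index with two-sided unequal-variance
(Welch) t-tests at $\alpha = 0.05$ on participant-level values (n = 11
meditators, 9 non-meditators), giving a binary decision matrix per index
and group. The four matrices combine cell-wise: **Reject** when 3–4 indices
reject H0, **Neutral** when exactly 2, **Accept** when 0–1. Over the 16
possible four-index outcomes this yields 5 Reject, 6 Neutral and 5 Accept
patterns. Decisions with $|p - \alpha| < 0.005$ are flagged borderline, and
`borderline_as_reject = TRUE` lets such acceptances count as rejections —
the convention under which the one internally inconsistent cell of the
bundled reference tables (two rejections printed yet classified Reject)
becomes consistent. The package reconstructs 29 of the 30 reference
verdict cells under the plain rule and 30 under the borderline rule, and
flags the discrepant cell rather than silently matching it.

A robustness battery wraps the standard checks around the decision
matrices: one-way and repeated-measures ANOVA and Friedman omnibus tests,
Bonferroni-corrected pairwise comparisons, paired Wilcoxon tests, and four
normality diagnostics (Shapiro-Wilk, Anderson-Darling, D'Agostino K²,
Kolmogorov-Smirnov against a fitted normal). All are established routines
from base R and nortest except D'Agostino K², which no installed package
provides and which is implemented from the standard 1990 transforms and
cross-checked against an independent implementation's values. With an
unbalanced design the repeated-measures entries are reported unavailable
and the rest still computed.

## The synthetic generator

Because the source raw EEG is unreleased, validation runs on a seeded
generator that emulates the study conditions: 128 channels at 1000 Hz,
state-dependent band-power profiles, a $1/f$ background with a small white
floor, and the six modality schedules with their protocol constants (7 min
meditation, ~2 min video, 20 words, 12 images, 28 arithmetic items whose
ground truth is the digital root of the product, 20 sentences).

Each channel is synthesised in the frequency domain: random-phase noise
whose power density is the profile's band weights spread uniformly over
each band plus the background. Oscillations are band-limited noise, not
sine lines, so band bins fill realistically. Profiles are frozen
constants chosen once so that MED is narrowly alpha-dominant with the
highest total power, VDO the broadest mixture with the lowest, and
SENT < WORDS ≈ MM < IMG in between — the qualitative ordering reported for
these conditions; no claim is made of matching any published numeric
values. MED boosts the Alpha weight over occipital (×1.6) and parietal
(×1.3) channels, emulating posterior alpha dominance. Meditator recordings
multiply the Alpha weight by `group_effect` (default 1.5) and divide the
broadband noise by it. Per-recording log-normal multipliers (sd 0.15) on
the dominant band weight and the overall amplitude create realistic
between-participant spread.

Sub-seeds derive from the master seed as
`seed + 1009 * participant + 9973 * modality_index`, so every
participant × modality cell is reproducible and statistically independent
of the others. That independence is deliberate: the pairwise Welch test
treats modality samples as independent, and the null-calibration check
(type-I error ≈ α) is only well-posed when they are. It is also the main
idealisation — the generator does not model within-participant correlation
across conditions, artifacts (blinks, muscle, line transients beyond 50 Hz),
non-stationarity within a recording, or volume-conduction correlation
between neighbouring channels. Passing tests therefore demonstrate that the
analysis chain recovers known spectral structure and calibrates correctly
on clean, independent data; they do not certify artifact robustness on real
recordings.

## Validation scale and numerical choices

The test suite exercises the full chain end to end at desk scale: the
Monte-Carlo state-separation check runs 50 master seeds of the default
11 + 9 cohort with 2 s meditation and 1 s video recordings per participant,
and the null calibration runs 200 replicates of an 11-participant group
with identical profiles and `group_effect = 1` at 1 s per recording. Group
sizes, effect sizes and replicate counts are never reduced — only recording
durations, which enter the indices as the number of averaged windows. The
acceptance script repeats the same computations from scratch at one seed
and writes every headline quantity as JSON.

Other numerical conventions: probabilities are validated to sum to 1 within
1e-8 and $0 \log 0 = 0$; DFs uses the $n-1$ divisor and requires at least
two electrodes; Welch tests with two zero-variance samples fall back to the
stated degenerate contract (p = 1 on equal means, forced rejection flagged
degenerate otherwise); max-scaling refuses all-zero collections; and all
exports are plain delimited text with `NA` sentinels for the two empty grid
cells.

## Known limitations

* The channel-to-cell table and the identity of the 14 doubled electrodes
  are a documented guess; analyses that depend on exact electrode
  positions should supply their own layout file.
* EDF input is not supported in this build; recordings travel as delimited
  matrices with a YAML side-car.
* The entropy correction variant, Hilbert-transform methodology,
  heart-rate coherence index and source modelling are out of scope.
* The zero-padded Hann periodogram trades spectral independence of bins
  for the 1 Hz grid; swap `window_psd()` if a multitaper or Welch-averaged
  estimator is preferred.
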