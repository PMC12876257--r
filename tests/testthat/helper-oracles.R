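# Independent oracles used to cross-check the implementation paths.

# Textbook Welch statistic with Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# Brute-force elementwise summations for the spectral indices.
entropy_oracle <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

psk_oracle <- function(p, f) {
  m <- 0
  for (i in seq_along(p)) m <- m + f[i] * p[i]
  v <- 0
  for (i in seq_along(p)) v <- v + p[i] * (f[i] - m)^2
  if (v == 0) return(0)
  mode <- f[which.max(p)]
  abs(m - mode) / sqrt(v)
}

tp_oracle <- function(pw) {
  s <- 0
  for (w in pw) s <- s + w
  s
}

# Plain rectangular-window DFT power, for locating spectral peaks
# independently of the package's Hann periodogram.
dft_power_oracle <- function(x, fs, freqs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  vapply(freqs, function(f) {
    Mod(sum(x * exp(-2i * pi * f * t)))^2
  }, numeric(1))
}

# Small layout-backed cohort helpers (cached layout for speed).
test_layout <- local({
  lay <- NULL
  function() {
    if (is.null(lay)) lay <<- load_layout()
    lay
  }
})

# A deterministic constant-signal recording for structural tests.
flat_recording <- function(n_channels = 4, duration_ms = 1000, fs = 1000) {
  sig <- matrix(sin(2 * pi * 10 * (seq_len(duration_ms * fs / 1000) - 1) / fs),
                n_channels, duration_ms * fs / 1000, byrow = TRUE)
  recording(sig, fs = fs)
}
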