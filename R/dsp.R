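# Internal zero-phase spectral filtering and analytic-signal helpers.
#
# No IIR/FIR coefficient machinery is used: all filters are applied in the
# frequency domain as real, symmetric magnitude responses (zero phase, no
# group delay, output length == input length). Band filters use the SQUARED
# Butterworth magnitude — the response that forward-backward (filtfilt)
# application of an order-`order` Butterworth would have. Squared low- and
# high-pass responses at a shared cutoff sum to exactly 1, which makes the
# channel filterbank almost perfectly reconstructing in-band.

# Squared Butterworth low-pass magnitude at frequency f (Hz), cutoff fc.
.butter_lp_pow <- function(f, fc, order) {
  1 / (1 + (f / fc)^(2 * order))
}

# Squared Butterworth high-pass magnitude; 0 at DC.
.butter_hp_pow <- function(f, fc, order) {
  out <- numeric(length(f))
  pos <- f > 0
  out[pos] <- 1 / (1 + (fc / f[pos])^(2 * order))
  out
}

# FFT size: next power of two covering n plus a wrap-around guard.
.fft_size <- function(n, fs) {
  stats::nextn(n + max(1024L, as.integer(fs %/% 4)), 2)
}

# Frequency (Hz) of each DFT bin, folded to [0, fs/2].
.bin_freqs <- function(nfft, fs) {
  k <- 0:(nfft - 1)
  pmin(k, nfft - k) / nfft * fs
}

# Apply a real symmetric gain (function of frequency in Hz) with zero phase.
.fft_gain_filter <- function(x, fs, gain_fun) {
  n <- length(x)
  nfft <- .fft_size(n, fs)
  g <- gain_fun(.bin_freqs(nfft, fs))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * g, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Zero-phase low-pass (squared Butterworth magnitude), e.g. envelope smoothing.
.fft_lowpass <- function(x, fs, fc, order = 2) {
  .fft_gain_filter(x, fs, function(f) .butter_lp_pow(f, fc, order))
}

# Complex analytic band signal: one-sided spectrum weighted by the band's
# squared Butterworth magnitude. Re() is the zero-phase band-passed signal,
# Mod() its envelope (peak amplitude for a tone).
.analytic_band <- function(x, fs, f_lo_hz = 0, f_hi_hz = Inf, order = 4) {
  n <- length(x)
  nfft <- .fft_size(n, fs)
  f <- .bin_freqs(nfft, fs)
  g <- rep(1, nfft)
  if (f_lo_hz > 0) g <- g * .butter_hp_pow(f, f_lo_hz, order)
  if (is.finite(f_hi_hz)) g <- g * .butter_lp_pow(f, f_hi_hz, order)
  # analytic weighting: double positive frequencies, zero negative ones
  k <- 0:(nfft - 1)
  w <- numeric(nfft)
  w[k > 0 & k < nfft / 2] <- 2
  w[k == 0 | k == nfft / 2] <- 1
  z <- stats::fft(stats::fft(c(x, numeric(nfft - n))) * g * w, inverse = TRUE) / nfft
  z[seq_len(n)]
}

# Hilbert envelope of the full-band signal.
.hilbert_env <- function(x, fs) {
  Mod(.analytic_band(x, fs))
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All stochastic generators in the package route
# their randomness through this, so they are pure functions of (args, seed).
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}
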