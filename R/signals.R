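#' Calibrated waveform container
#'
#' A mono waveform with a digital-to-acoustic calibration convention: a
#' full-scale sinusoid (peak amplitude 1) is assigned
#' `calibration_db_spl_at_fullscale` dB SPL (default 100). All level-dependent
#' processing (compression thresholds, recruitment, limiting) interprets sample
#' values through this convention.
#'
#' @param samples numeric vector of samples, all finite, `|sample| <= 1`.
#' @param sample_rate_hz sampling rate in Hz; must be at least 16000 so that
#'   the 8-kHz top channel edge is representable.
#' @param calibration_db_spl_at_fullscale dB SPL assigned to a full-scale sine.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate_hz = 22050,
                     calibration_db_spl_at_fullscale = 100) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  if (any(abs(samples) > 1 + 1e-9)) {
    stop("waveform samples must lie within [-1, 1] (full scale)")
  }
  if (sample_rate_hz < 16000) {
    stop("sample_rate_hz must be >= 16000 Hz (channel edges extend to 8 kHz)")
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      calibration_db_spl_at_fullscale = calibration_db_spl_at_fullscale
    ),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz (%.3f s), full scale = %g dB SPL, RMS level = %.1f dB SPL>\n",
    length(x$samples), x$sample_rate_hz, length(x$samples) / x$sample_rate_hz,
    x$calibration_db_spl_at_fullscale, wf_level_db_spl(x)
  ))
  invisible(x)
}

# rms -> dB SPL under the full-scale-sine convention (full-scale sine RMS is
# 1/sqrt(2)); amplitude floor keeps silence finite.
.rms_to_spl <- function(rms, cal) {
  cal + 20 * log10(pmax(rms * sqrt(2), 1e-9))
}

.spl_to_rms <- function(spl, cal) {
  10^((spl - cal) / 20) / sqrt(2)
}

#' RMS level of a waveform in dB SPL
#'
#' @param x a [waveform()].
#' @param from_s,to_s optional analysis window in seconds (defaults: whole
#'   signal); used to meter steady-state segments while skipping transients.
#' @return Level in dB SPL.
#' @export
wf_level_db_spl <- function(x, from_s = 0, to_s = Inf) {
  stopifnot(inherits(x, "waveform"))
  n <- length(x$samples)
  i0 <- max(1L, floor(from_s * x$sample_rate_hz) + 1L)
  i1 <- min(n, if (is.finite(to_s)) floor(to_s * x$sample_rate_hz) else n)
  s <- x$samples[i0:i1]
  .rms_to_spl(sqrt(mean(s^2)), x$calibration_db_spl_at_fullscale)
}

#' Generate a calibrated pure tone
#'
#' The tone's RMS level in dB SPL equals `level_db_spl` under the waveform
#' calibration convention (full-scale sine = `calibration_db_spl_at_fullscale`).
#'
#' @param freq_hz tone frequency; must be below Nyquist.
#' @param level_db_spl target RMS level (dB SPL); must not exceed the
#'   full-scale calibration level.
#' @param duration_s duration in seconds.
#' @param sample_rate_hz sampling rate (Hz).
#' @param calibration_db_spl_at_fullscale calibration convention.
#' @param phase starting phase in radians.
#' @return A [waveform()].
#' @export
make_tone <- function(freq_hz, level_db_spl, duration_s,
                      sample_rate_hz = 22050,
                      calibration_db_spl_at_fullscale = 100, phase = 0) {
  if (freq_hz >= sample_rate_hz / 2) {
    stop("freq_hz must be below the Nyquist frequency (aliasing)")
  }
  if (level_db_spl > calibration_db_spl_at_fullscale + 1e-9) {
    stop("requested level exceeds the full-scale calibration level")
  }
  n <- round(duration_s * sample_rate_hz)
  peak <- 10^((level_db_spl - calibration_db_spl_at_fullscale) / 20)
  t <- (seq_len(n) - 1) / sample_rate_hz
  waveform(peak * sin(2 * pi * freq_hz * t + phase), sample_rate_hz,
           calibration_db_spl_at_fullscale)
}

#' Generate a phase-continuous level step
#'
#' A sinusoid at `level1_db_spl` before `t_step_s` and `level2_db_spl` after,
#' with a continuous phase ramp across the step. This is the probe used to
#' measure compressor attack and release times.
#'
#' @inheritParams make_tone
#' @param level1_db_spl,level2_db_spl levels before/after the step (dB SPL).
#' @param t_step_s step time in seconds; `0` yields a pure `level2` tone.
#' @return A [waveform()].
#' @export
make_level_step <- function(freq_hz, level1_db_spl, level2_db_spl, t_step_s,
                            duration_s, sample_rate_hz = 22050,
                            calibration_db_spl_at_fullscale = 100, phase = 0) {
  if (freq_hz >= sample_rate_hz / 2) {
    stop("freq_hz must be below the Nyquist frequency (aliasing)")
  }
  cal <- calibration_db_spl_at_fullscale
  if (max(level1_db_spl, level2_db_spl) > cal + 1e-9) {
    stop("requested level exceeds the full-scale calibration level")
  }
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  amp <- ifelse(t < t_step_s,
                10^((level1_db_spl - cal) / 20),
                10^((level2_db_spl - cal) / 20))
  waveform(amp * sin(2 * pi * freq_hz * t + phase), sample_rate_hz, cal)
}

# One speech-surrogate item: alternating vowel-like (harmonic, formant-shaped)
# and consonant-like (high-pass noise burst) segments under a slow syllabic
# modulation. Randomness must already be seeded by the caller.
.surrogate_item <- function(duration_s, sample_rate_hz, level_db_spl, cal,
                            cv_offset_db, mod_rate_hz) {
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  x <- numeric(n)
  seg_type <- character(0)
  seg_bounds <- integer(0)
  pos <- 1L
  is_vowel <- TRUE
  f0 <- stats::runif(1, 100, 160)
  while (pos <= n) {
    seg_len <- round(stats::runif(1, 0.09, 0.16) * fs)
    i1 <- min(n, pos + seg_len - 1L)
    m <- i1 - pos + 1L
    t <- (seq_len(m) - 1) / fs
    if (is_vowel) {
      # harmonic complex with spectral tilt, shaped by two formant resonances
      formants <- c(stats::runif(1, 300, 900), stats::runif(1, 1100, 2500))
      harmonics <- seq(f0, 8000, by = f0)
      w <- (harmonics / f0)^(-0.6)
      for (fm in formants) {
        w <- w * (1 + 3 * exp(-((harmonics - fm) / 250)^2))
      }
      ph <- stats::runif(length(harmonics), 0, 2 * pi)
      seg <- drop(sin(outer(t, 2 * pi * harmonics) +
                        matrix(ph, m, length(harmonics), byrow = TRUE)) %*% w)
    } else {
      seg <- stats::rnorm(m)
      seg <- Re(.analytic_band(seg, fs, f_lo_hz = 1800, f_hi_hz = 8000, order = 2))
    }
    seg <- seg / max(sqrt(mean(seg^2)), 1e-12)
    if (!is_vowel) seg <- seg * 10^(cv_offset_db / 20)
    # raised-cosine segment on/off ramps (10 ms)
    nr <- min(m %/% 2, round(0.01 * fs))
    if (nr > 1) {
      ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
      seg[seq_len(nr)] <- seg[seq_len(nr)] * ramp
      seg[(m - nr + 1):m] <- seg[(m - nr + 1):m] * rev(ramp)
    }
    x[pos:i1] <- seg
    seg_type <- c(seg_type, if (is_vowel) "vowel" else "consonant")
    seg_bounds <- c(seg_bounds, pos)
    is_vowel <- !is_vowel
    pos <- i1 + 1L
  }
  # syllabic-rate envelope modulation
  tt <- (seq_len(n) - 1) / fs
  x <- x * (1 + 0.5 * sin(2 * pi * mod_rate_hz * tt + stats::runif(1, 0, 2 * pi)))
  x <- x * .spl_to_rms(level_db_spl, cal) / sqrt(mean(x^2))
  peak <- max(abs(x))
  if (peak > 1) x <- x / (peak * 1.001) # headroom guard; shifts level < 1 dB
  wf <- waveform(x, fs, cal)
  attr(wf, "segments") <- data.frame(start = seg_bounds, type = seg_type)
  wf
}

#' Generate seeded speech-surrogate stimuli
#'
#' Speech-like test items standing in for recorded word lists: alternating
#' vowel-like harmonic segments and consonant-like high-frequency noise bursts
#' (consonants `cv_offset_db` below vowels, default -12 dB), under a syllabic
#' (~4 Hz) envelope modulation. Deterministic for fixed arguments and seed.
#'
#' @param n_items number of stimuli.
#' @param seed integer seed; each item uses a seed derived from `(seed, index)`
#'   so item `i` is reproducible independently of `n_items`.
#' @param duration_s item duration (s).
#' @param level_db_spl overall RMS presentation level (dB SPL), default 65.
#' @param sample_rate_hz sampling rate (Hz).
#' @param calibration_db_spl_at_fullscale calibration convention.
#' @param cv_offset_db consonant-minus-vowel level offset in dB.
#' @param mod_rate_hz syllabic modulation rate (Hz).
#' @return List of [waveform()]s; each carries a `segments` attribute with
#'   segment starts and types for metering.
#' @export
make_speech_surrogate <- function(n_items, seed, duration_s = 0.6,
                                  level_db_spl = 65, sample_rate_hz = 22050,
                                  calibration_db_spl_at_fullscale = 100,
                                  cv_offset_db = -12, mod_rate_hz = 4) {
  stopifnot(n_items >= 1)
  lapply(seq_len(n_items), function(i) {
    .with_seed((as.integer(seed) * 131L + i) %% .Machine$integer.max,
               .surrogate_item(duration_s, sample_rate_hz, level_db_spl,
                               calibration_db_spl_at_fullscale,
                               cv_offset_db, mod_rate_hz))
  })
}

#' Measure settling time of a level trajectory after a step
#'
#' The meter used to verify compressor attack/release calibration: the time
#' from the step until the level trajectory enters (and stays within)
#' `tol_db` of `target_db_spl`.
#'
#' @param level_db per-sample level trajectory in dB SPL.
#' @param sample_rate_hz sampling rate of the trajectory.
#' @param t_step_s time of the level step (s).
#' @param target_db_spl final (post-step) steady-state level.
#' @param tol_db settling corridor half-width in dB (3 dB for attack, 4 dB for
#'   release under the ANSI-style convention).
#' @return Settling time in seconds.
#' @export
measure_settling_time <- function(level_db, sample_rate_hz, t_step_s,
                                  target_db_spl, tol_db) {
  i0 <- floor(t_step_s * sample_rate_hz) + 1L
  seg <- level_db[i0:length(level_db)]
  outside <- which(abs(seg - target_db_spl) > tol_db)
  if (length(outside) == 0) return(0)
  if (max(outside) == length(seg)) {
    stop("trajectory never settles within tolerance; lengthen the probe")
  }
  max(outside) / sample_rate_hz
}
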