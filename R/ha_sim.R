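# Five-channel hearing-aid simulator: zero-phase analysis filterbank,
# per-channel wide-dynamic-range compressor with attack/release envelope
# dynamics, series limiter, resynthesis by summation.

# global optimizer bounds for time constants (ms)
.AT_BOUNDS <- c(10, 500)
.RT_BOUNDS <- c(300, 2000)

# dB-domain one-pole calibration: on a 55<->90 dB step the smoothed level is
# within 3 dB of the final level after exactly t = tau*ln(35/3) (attack) and
# within 4 dB after t = tau*ln(35/4) (release), so nominal ANSI-style times
# map to poles via these constants.
.ATT_SETTLE_FACTOR <- log(35 / 3)
.REL_SETTLE_FACTOR <- log(35 / 4)

#' Per-channel attack and release times
#'
#' The parameter vector optimized by the random search: one attack and one
#' release time (ms) per compression channel, constrained to the slow-
#' compression search ranges 10-500 ms (attack) and 300-2000 ms (release).
#'
#' @param attack_ms attack times (ms), one per channel.
#' @param release_ms release times (ms), one per channel.
#' @return An object of class `time_constants`.
#' @export
time_constants <- function(attack_ms, release_ms) {
  a <- as.numeric(attack_ms)
  r <- as.numeric(release_ms)
  if (length(a) != length(r)) stop("attack and release need equal lengths")
  if (any(a < .AT_BOUNDS[1] - 1e-9 | a > .AT_BOUNDS[2] + 1e-9)) {
    stop("attack times must lie within ", .AT_BOUNDS[1], "-", .AT_BOUNDS[2], " ms")
  }
  if (any(r < .RT_BOUNDS[1] - 1e-9 | r > .RT_BOUNDS[2] + 1e-9)) {
    stop("release times must lie within ", .RT_BOUNDS[1], "-", .RT_BOUNDS[2], " ms")
  }
  structure(list(attack_ms = a, release_ms = r), class = "time_constants")
}

#' Default slow-compression time constants
#'
#' Attack 200, 100, 100, 100, 100 ms and release 2000, 1500, 1200, 1000,
#' 1000 ms for channels 1-5: the fixed compression speeds against which
#' optimized constants are compared.
#'
#' @return A [time_constants()] object.
#' @export
default_time_constants <- function() {
  time_constants(c(200, 100, 100, 100, 100), c(2000, 1500, 1200, 1000, 1000))
}

#' @export
print.time_constants <- function(x, ...) {
  cat("<time_constants>\n")
  print(data.frame(channel = seq_along(x$attack_ms),
                   attack_ms = x$attack_ms, release_ms = x$release_ms),
        row.names = FALSE)
  invisible(x)
}

#' Hearing-aid configuration
#'
#' Per-channel insertion gains anchored at 65- and 85-dB-SPL input levels,
#' compression thresholds, the five channel edges, limiter settings and the
#' compression time constants. Gains and thresholds are inputs (prescribed by
#' a fitting rule); only the time constants are optimized here.
#'
#' @param ig65_db,ig85_db per-channel insertion gains (dB) for 65- and
#'   85-dB-SPL input; `ig65 >= ig85` (compressive) per channel.
#' @param ct_db_spl per-channel compression thresholds (dB SPL), each below
#'   65 so the 65-dB anchor sits in the compressive region.
#' @param channel_edges_khz six ascending band edges; default
#'   0.1, 0.7, 1.4, 2.8, 5.6, 8 kHz.
#' @param limiter_threshold_db_spl,limiter_ratio limiter stage; `Inf`
#'   threshold disables it. Ratio must be at least 10 (a limiter, not a mild
#'   compressor).
#' @param limiter_attack_ms,limiter_release_ms fixed fast limiter dynamics.
#' @param tc a [time_constants()] object (default slow-compression values).
#' @param filter_order analysis-filter Butterworth order (squared magnitude
#'   applied with zero phase).
#' @return An object of class `ha_config`.
#' @export
ha_config <- function(ig65_db, ig85_db, ct_db_spl,
                      channel_edges_khz = c(0.1, 0.7, 1.4, 2.8, 5.6, 8),
                      limiter_threshold_db_spl = 100, limiter_ratio = 10,
                      limiter_attack_ms = 5, limiter_release_ms = 50,
                      tc = default_time_constants(), filter_order = 16) {
  n_ch <- length(channel_edges_khz) - 1
  if (n_ch != 5) stop("exactly 5 channels required (6 band edges)")
  if (any(diff(channel_edges_khz) <= 0)) stop("channel edges must ascend")
  for (nm in c("ig65_db", "ig85_db", "ct_db_spl")) {
    if (length(get(nm)) != n_ch) stop(nm, " needs one value per channel")
  }
  if (any(ig65_db < ig85_db - 1e-9)) {
    stop("ig65 must be >= ig85 per channel (compressive or linear gain-level slope)")
  }
  if (any(ig85_db - ig65_db <= -20)) {
    stop("ig85 - ig65 <= -20 dB implies an infinite or negative compression ratio")
  }
  if (any(ct_db_spl >= 65)) {
    stop("compression thresholds must be below 65 dB SPL")
  }
  if (is.finite(limiter_threshold_db_spl) && limiter_ratio < 10) {
    stop("limiter_ratio must be >= 10")
  }
  if (length(tc$attack_ms) != n_ch) {
    stop("time constants must have one attack/release pair per channel")
  }
  structure(
    list(ig65_db = as.numeric(ig65_db), ig85_db = as.numeric(ig85_db),
         ct_db_spl = as.numeric(ct_db_spl),
         channel_edges_khz = as.numeric(channel_edges_khz),
         limiter_threshold_db_spl = limiter_threshold_db_spl,
         limiter_ratio = limiter_ratio,
         limiter_attack_ms = limiter_attack_ms,
         limiter_release_ms = limiter_release_ms,
         tc = tc, filter_order = filter_order),
    class = "ha_config"
  )
}

#' Static compression curve from the two gain anchors
#'
#' Builds the input-level-to-gain function (dB in, dB gain) of one channel:
#' a single compressive segment through the anchors `(65, ig65)` and
#' `(85, ig85)` at and above the compression threshold, and constant gain
#' below it (linear region, gain frozen at its value at CT). The implied
#' compression ratio is `20 / (20 + ig85 - ig65)` and is attached as the
#' `"cr"` attribute.
#'
#' @param ig65_db,ig85_db insertion gains (dB) at 65 and 85 dB SPL input.
#' @param ct_db_spl compression threshold (dB SPL).
#' @return A vectorized function `level_db_spl -> gain_db`.
#' @export
derive_static_curve <- function(ig65_db, ig85_db, ct_db_spl) {
  if (ig85_db - ig65_db <= -20) {
    stop("ig85 - ig65 <= -20 dB: compression ratio undefined")
  }
  slope <- (ig85_db - ig65_db) / 20
  gain_at <- function(L) ig65_db + slope * (L - 65)
  f <- function(level_db_spl) {
    ifelse(level_db_spl < ct_db_spl, gain_at(ct_db_spl), gain_at(level_db_spl))
  }
  attr(f, "cr") <- 20 / (20 + ig85_db - ig65_db)
  f
}

# pole magnitudes for the dB-domain asymmetric smoother
.smoother_coefs <- function(attack_ms, release_ms, fs) {
  if (attack_ms <= 0 || release_ms <= 0) {
    stop("time constants must be positive")
  }
  tau_a <- attack_ms / 1000 / .ATT_SETTLE_FACTOR
  tau_r <- release_ms / 1000 / .REL_SETTLE_FACTOR
  c(exp(-1 / (fs * tau_a)), exp(-1 / (fs * tau_r)))
}

#' Envelope follower with attack/release dynamics
#'
#' Tracks the level (dB SPL) of a band signal: the Hilbert-magnitude envelope
#' is converted to an RMS-equivalent level and smoothed by a one-pole
#' asymmetric filter in the dB domain. The poles are calibrated so that on a
#' 55 to 90 dB SPL step the tracked level is within 3 dB of the final level
#' after the nominal attack time, and on a 90 to 55 dB step within 4 dB after
#' the nominal release time (ANSI-style settling criteria).
#'
#' @param x a [waveform()] (typically one analysis band).
#' @param attack_ms,release_ms nominal time constants (ms), positive.
#' @return Per-sample level trajectory in dB SPL.
#' @export
envelope_follower <- function(x, attack_ms, release_ms) {
  stopifnot(inherits(x, "waveform"))
  env <- .hilbert_env(x$samples, x$sample_rate_hz)
  .follow_level(env, x$sample_rate_hz, x$calibration_db_spl_at_fullscale,
                attack_ms, release_ms)
}

# same, from a precomputed envelope (Mod of the analytic band signal)
.follow_level <- function(env, fs, cal, attack_ms, release_ms) {
  lev <- .rms_to_spl(env / sqrt(2), cal)
  co <- .smoother_coefs(attack_ms, release_ms, fs)
  asym_smooth(lev, co[1], co[2])
}

# WDRC stage on one analytic band: gain from the static curve evaluated at the
# followed level, applied per sample. Returns the processed real band and its
# (gain-scaled) envelope for the limiter stage.
.compress_band <- function(z, fs, cal, curve, attack_ms, release_ms) {
  env <- Mod(z)
  lev <- .follow_level(env, fs, cal, attack_ms, release_ms)
  g <- 10^(curve(lev) / 20)
  list(x = Re(z) * g, env = env * g)
}

# limiter stage: second compressor in series with fast fixed dynamics; unity
# gain below threshold, `ratio`-limited above
.limit_band <- function(x, env, fs, cal, threshold_db_spl, ratio,
                        attack_ms, release_ms) {
  if (!is.finite(threshold_db_spl)) return(x)
  lev <- .follow_level(env, fs, cal, attack_ms, release_ms)
  gain_db <- pmin(0, (1 / ratio - 1) * (lev - threshold_db_spl))
  x * 10^(gain_db / 20)
}

#' Compress one band with a static curve and time constants
#'
#' The first of the two series compressors: per-sample gain equals the static
#' curve evaluated at the [envelope_follower()] level. A stationary tone at
#' `L` dB SPL reaches steady-state output `L + curve(L)` dB SPL.
#'
#' @param x a [waveform()] band signal.
#' @param curve a static curve from [derive_static_curve()].
#' @param attack_ms,release_ms channel time constants (ms).
#' @return The compressed [waveform()].
#' @export
compress_channel <- function(x, curve, attack_ms, release_ms) {
  stopifnot(inherits(x, "waveform"))
  z <- .analytic_band(x$samples, x$sample_rate_hz)
  out <- .compress_band(z, x$sample_rate_hz,
                        x$calibration_db_spl_at_fullscale, curve,
                        attack_ms, release_ms)
  waveform(pmin(pmax(out$x, -1), 1), x$sample_rate_hz,
           x$calibration_db_spl_at_fullscale)
}

#' Apply the limiter stage to one band
#'
#' @param x a [waveform()] band signal.
#' @param threshold_db_spl limiter threshold (dB SPL); `Inf` disables.
#' @param ratio limiting ratio (>= 10).
#' @param attack_ms,release_ms limiter dynamics (default 5 / 50 ms).
#' @return The limited [waveform()].
#' @export
limit_channel <- function(x, threshold_db_spl = 100, ratio = 10,
                          attack_ms = 5, release_ms = 50) {
  stopifnot(inherits(x, "waveform"))
  if (is.finite(threshold_db_spl) && ratio < 10) stop("limiter ratio must be >= 10")
  z <- .analytic_band(x$samples, x$sample_rate_hz)
  y <- .limit_band(Re(z), Mod(z), x$sample_rate_hz,
                   x$calibration_db_spl_at_fullscale,
                   threshold_db_spl, ratio, attack_ms, release_ms)
  waveform(pmin(pmax(y, -1), 1), x$sample_rate_hz,
           x$calibration_db_spl_at_fullscale)
}

#' Amplify a waveform through the five-channel hearing aid
#'
#' Analysis into five bands (zero-phase squared-Butterworth filterbank at the
#' channel edges), per-band compression then limiting, and resynthesis by
#' summation. Deterministic; output length equals input length and no group
#' delay is introduced (all filters are zero phase).
#'
#' @param x a calibrated [waveform()]; sample rate at least 16 kHz.
#' @param cfg an [ha_config()].
#' @return The amplified [waveform()].
#' @export
amplify <- function(x, cfg) {
  stopifnot(inherits(x, "waveform"), inherits(cfg, "ha_config"))
  fs <- x$sample_rate_hz
  if (fs < 16000) stop("sample rate must be >= 16 kHz")
  cal <- x$calibration_db_spl_at_fullscale
  edges_hz <- cfg$channel_edges_khz * 1000
  if (edges_hz[length(edges_hz)] > fs / 2) {
    stop("top channel edge exceeds the Nyquist frequency")
  }
  y <- numeric(length(x$samples))
  for (ch in seq_along(cfg$ig65_db)) {
    z <- .analytic_band(x$samples, fs, edges_hz[ch], edges_hz[ch + 1],
                        cfg$filter_order)
    curve <- derive_static_curve(cfg$ig65_db[ch], cfg$ig85_db[ch],
                                 cfg$ct_db_spl[ch])
    b <- .compress_band(z, fs, cal, curve,
                        cfg$tc$attack_ms[ch], cfg$tc$release_ms[ch])
    y <- y + .limit_band(b$x, b$env, fs, cal,
                         cfg$limiter_threshold_db_spl, cfg$limiter_ratio,
                         cfg$limiter_attack_ms, cfg$limiter_release_ms)
  }
  waveform(pmin(pmax(y, -1), 1), fs, cal)
}
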