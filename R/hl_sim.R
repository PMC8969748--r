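# Hearing-loss simulator: loudness recruitment by multiband envelope
# expansion, followed by a zero-phase linear filter realizing the elevation of
# hearing thresholds. The two stages do not commute; recruitment-first is the
# fixed, documented order (the expansion is defined on the *presented* levels,
# before audibility is removed).

# standard audiometric design frequencies the threshold filter needs
.HL_DESIGN_FREQS <- c(0.125, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)

#' Hearing-loss simulator configuration
#'
#' @param recruitment_edges_khz analysis band edges for envelope expansion;
#'   defaults to the five hearing-aid channel bands.
#' @param normal_dynamic_ceiling_db_spl level treated as equally loud for
#'   normal-hearing and impaired listeners (default 100 dB SPL); every band
#'   threshold must stay below it.
#' @param envelope_cutoff_hz envelope smoothing cutoff (default 32 Hz).
#' @param filter_order analysis-filter order, as in [ha_config()].
#' @return An object of class `hl_sim_config`.
#' @export
hl_sim_config <- function(recruitment_edges_khz = c(0.1, 0.7, 1.4, 2.8, 5.6, 8),
                          normal_dynamic_ceiling_db_spl = 100,
                          envelope_cutoff_hz = 32, filter_order = 16) {
  if (any(diff(recruitment_edges_khz) <= 0)) stop("band edges must ascend")
  if (recruitment_edges_khz[1] < 0.1 - 1e-9 ||
      recruitment_edges_khz[length(recruitment_edges_khz)] > 8 + 1e-9) {
    stop("recruitment band edges must lie within [0.1, 8] kHz")
  }
  structure(
    list(recruitment_edges_khz = as.numeric(recruitment_edges_khz),
         normal_dynamic_ceiling_db_spl = normal_dynamic_ceiling_db_spl,
         envelope_cutoff_hz = envelope_cutoff_hz,
         filter_order = filter_order),
    class = "hl_sim_config"
  )
}

#' Linear filter realizing elevated hearing thresholds
#'
#' Builds a zero-phase linear filter whose magnitude response at each
#' audiometric frequency is minus the hearing loss there (attenuation equal to
#' the threshold elevation), interpolated linearly on log-frequency between
#' audiometric points and held flat beyond them.
#'
#' @param ag an [audiogram()] containing all standard design frequencies
#'   (0.125-8 kHz); complete sparse audiograms with [complete_audiogram()]
#'   first.
#' @param sample_rate_hz sampling rate the filter will be applied at.
#' @return An object of class `threshold_filter`; apply with
#'   [apply_threshold_filter()].
#' @export
threshold_filter <- function(ag, sample_rate_hz) {
  stopifnot(inherits(ag, "audiogram"))
  idx <- .ag_match(ag, .HL_DESIGN_FREQS)
  if (anyNA(idx)) {
    stop("audiogram is missing design frequencies (",
         paste(.HL_DESIGN_FREQS[is.na(idx)], collapse = ", "),
         " kHz); run complete_audiogram first")
  }
  structure(
    list(ag = ag, sample_rate_hz = sample_rate_hz,
         gain_db = function(freq_hz) -.ag_interp(ag, pmax(freq_hz, 1) / 1000)),
    class = "threshold_filter"
  )
}

#' Apply a threshold-elevation filter
#'
#' @param filt a [threshold_filter()].
#' @param x a [waveform()] at the filter's sample rate.
#' @return The filtered [waveform()].
#' @export
apply_threshold_filter <- function(filt, x) {
  stopifnot(inherits(filt, "threshold_filter"), inherits(x, "waveform"))
  if (x$sample_rate_hz != filt$sample_rate_hz) {
    stop("waveform sample rate does not match the filter design rate")
  }
  y <- .fft_gain_filter(x$samples, x$sample_rate_hz,
                        function(f) 10^(filt$gain_db(f) / 20))
  waveform(pmin(pmax(y, -1), 1), x$sample_rate_hz,
           x$calibration_db_spl_at_fullscale)
}

#' Simulate loudness recruitment by envelope expansion
#'
#' Per band, the signal is decomposed into a smoothed Hilbert envelope and
#' carrier; the envelope level L (dB SPL) is mapped to
#' `ceiling - alpha * (ceiling - L)` with expansion exponent
#' `alpha = ceiling / (ceiling - HL_b)`, where `HL_b` is the band's hearing
#' loss. Levels at the ceiling are preserved; levels near threshold are pushed
#' toward inaudibility, emulating abnormally rapid loudness growth. Bands are
#' resynthesized by summation.
#'
#' @param x a calibrated [waveform()].
#' @param ag an [audiogram()]; band losses are interpolated at the geometric
#'   band centers (audiogram is completed internally if sparse).
#' @param cfg an [hl_sim_config()].
#' @return The recruited [waveform()].
#' @export
recruit <- function(x, ag, cfg = hl_sim_config()) {
  stopifnot(inherits(x, "waveform"), inherits(ag, "audiogram"),
            inherits(cfg, "hl_sim_config"))
  fs <- x$sample_rate_hz
  cal <- x$calibration_db_spl_at_fullscale
  ceiling_db <- cfg$normal_dynamic_ceiling_db_spl
  edges_hz <- cfg$recruitment_edges_khz * 1000
  n_band <- length(edges_hz) - 1
  centers_khz <- sqrt(cfg$recruitment_edges_khz[-1] *
                        cfg$recruitment_edges_khz[-(n_band + 1)])
  hl_b <- .ag_interp(ag, centers_khz)
  if (any(hl_b >= ceiling_db)) {
    stop("band hearing loss reaches the normal dynamic ceiling (",
         ceiling_db, " dB SPL): no residual dynamic range")
  }
  y <- numeric(length(x$samples))
  for (b in seq_len(n_band)) {
    z <- .analytic_band(x$samples, fs, edges_hz[b], edges_hz[b + 1],
                        cfg$filter_order)
    env <- pmax(.fft_lowpass(Mod(z), fs, cfg$envelope_cutoff_hz), 0)
    alpha <- ceiling_db / (ceiling_db - hl_b[b])
    lev <- .rms_to_spl(env / sqrt(2), cal)
    gain_db <- (ceiling_db - alpha * (ceiling_db - lev)) - lev
    y <- y + Re(z) * 10^(gain_db / 20)
  }
  waveform(pmin(pmax(y, -1), 1), fs, cal)
}

#' Degrade a waveform according to an audiogram
#'
#' The full hearing-loss simulation: loudness recruitment ([recruit()]) first,
#' threshold-elevation filtering ([threshold_filter()]) second. Sparse
#' audiograms are completed to the standard design frequencies internally.
#' Deterministic.
#'
#' @inheritParams recruit
#' @return The degraded [waveform()].
#' @export
simulate_hl <- function(x, ag, cfg = hl_sim_config()) {
  stopifnot(inherits(ag, "audiogram"))
  if (anyNA(.ag_match(ag, .HL_DESIGN_FREQS))) {
    ag <- complete_audiogram(ag, .HL_DESIGN_FREQS)
  }
  filt <- threshold_filter(ag, x$sample_rate_hz)
  apply_threshold_filter(filt, recruit(x, ag, cfg))
}
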