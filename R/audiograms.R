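#' Audiometric profile (pure-tone thresholds)
#'
#' Hearing thresholds in dB HL as a function of frequency. Frequencies must be
#' strictly increasing within the audiometric band 0.125-8 kHz; thresholds are
#' restricted to the physical range -10 to 120 dB HL.
#'
#' @param frequencies_khz audiometric frequencies (kHz), strictly increasing.
#' @param thresholds_dbhl hearing thresholds (dB HL), one per frequency.
#' @param label free-text identifier.
#' @return An object of class `audiogram`.
#' @export
audiogram <- function(frequencies_khz, thresholds_dbhl, label = "") {
  f <- as.numeric(frequencies_khz)
  t <- as.numeric(thresholds_dbhl)
  if (length(f) != length(t)) {
    stop("frequencies and thresholds must have equal length")
  }
  if (length(f) < 2) stop("an audiogram needs at least 2 points")
  if (any(diff(f) <= 0)) stop("frequencies must be strictly increasing")
  if (any(f < 0.125 - 1e-9 | f > 8 + 1e-9)) {
    stop("frequencies must lie within [0.125, 8] kHz")
  }
  if (any(t < -10 - 1e-9 | t > 120 + 1e-9)) {
    stop("thresholds must lie within [-10, 120] dB HL")
  }
  structure(
    list(frequencies_khz = f, thresholds_dbhl = t, label = as.character(label)),
    class = "audiogram"
  )
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf("<audiogram%s: %d frequencies>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$frequencies_khz)))
  print(data.frame(frequency_khz = x$frequencies_khz,
                   threshold_dbhl = x$thresholds_dbhl), row.names = FALSE)
  invisible(x)
}

# index of frequency f in ag, or NA; matches within a relative tolerance so
# e.g. 0.75 written through CSV still matches
.ag_match <- function(ag, f) {
  vapply(f, function(fi) {
    hit <- which(abs(ag$frequencies_khz - fi) <= 1e-6 * max(fi, 1))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

# linear interpolation of thresholds on log2-frequency, flat beyond endpoints;
# used by the hearing-loss simulator between audiometric points
.ag_interp <- function(ag, freq_khz) {
  stats::approx(log2(ag$frequencies_khz), ag$thresholds_dbhl,
                xout = log2(freq_khz), rule = 2)$y
}

#' Complete an audiogram by cubic regression in log-frequency
#'
#' Thresholds missing at `target_freqs_khz` are intra- or extrapolated with a
#' degree-3 least-squares polynomial fitted on log2(frequency) versus dB HL
#' over all input points. Thresholds already present are retained verbatim, so
#' completion is idempotent. Predicted values are clamped to the physical
#' range -10 to 120 dB HL.
#'
#' @param ag an [audiogram()] with at least 4 points (a cubic fit needs 4).
#' @param target_freqs_khz frequencies (kHz) at which thresholds are required;
#'   defaults to the standard audiometric set 0.125-8 kHz.
#' @return An [audiogram()] covering the union of input and target
#'   frequencies.
#' @export
complete_audiogram <- function(ag,
                               target_freqs_khz = c(0.125, 0.25, 0.5, 0.75, 1,
                                                    1.5, 2, 3, 4, 6, 8)) {
  stopifnot(inherits(ag, "audiogram"))
  if (length(ag$frequencies_khz) < 4) {
    stop("insufficient points for cubic fit (need at least 4)")
  }
  if (any(target_freqs_khz < 0.125 - 1e-9 | target_freqs_khz > 8 + 1e-9)) {
    stop("target frequency outside the audiometric band [0.125, 8] kHz")
  }
  x <- log2(ag$frequencies_khz)
  fit <- stats::lm(ag$thresholds_dbhl ~ x + I(x^2) + I(x^3))
  missing <- target_freqs_khz[is.na(.ag_match(ag, target_freqs_khz))]
  if (length(missing) == 0) return(ag)
  xm <- log2(missing)
  pred <- stats::predict(fit, newdata = data.frame(x = xm))
  pred <- pmin(pmax(pred, -10), 120)
  f_all <- c(ag$frequencies_khz, missing)
  t_all <- c(ag$thresholds_dbhl, pred)
  ord <- order(f_all)
  audiogram(f_all[ord], t_all[ord], ag$label)
}

#' Pure-tone average
#'
#' Arithmetic mean threshold over a stated frequency set. The default set
#' (0.5, 0.75, 1, 1.5, 2, 3 and 4 kHz) is the seven-frequency PTA used to
#' grade severity of age-related losses.
#'
#' @param ag an [audiogram()] containing every requested frequency.
#' @param freqs_khz frequencies (kHz) over which to average.
#' @return Mean threshold in dB HL.
#' @export
pta <- function(ag, freqs_khz = c(0.5, 0.75, 1, 1.5, 2, 3, 4)) {
  stopifnot(inherits(ag, "audiogram"))
  idx <- .ag_match(ag, freqs_khz)
  if (anyNA(idx)) {
    stop("frequency not in audiogram; run complete_audiogram first (missing: ",
         paste(freqs_khz[is.na(idx)], collapse = ", "), " kHz)")
  }
  mean(ag$thresholds_dbhl[idx])
}

# severity -> PTA band (dB HL); conventional clinical banding
.severity_bands <- list(
  mild = c(20, 34),
  moderate = c(35, 49),
  moderately_severe = c(50, 64),
  severe = c(65, 80)
)

#' Synthesize a sloping age-related audiogram
#'
#' Generates a seeded audiogram with thresholds generally increasing with
#' frequency, typical of age-related sensorineural loss. The seven-frequency
#' [pta()] falls inside a severity band: mild 20-34, moderate 35-49,
#' moderately severe 50-64, severe 65-80 dB HL. Deterministic for fixed
#' `(severity, seed)`.
#'
#' @param severity `"mild"`, `"moderate"`, `"moderately_severe"` or
#'   `"severe"`.
#' @param seed integer seed.
#' @return An [audiogram()] at the 11 standard audiometric frequencies.
#' @export
synth_audiogram <- function(severity = c("mild", "moderate",
                                         "moderately_severe", "severe"),
                            seed = 1) {
  severity <- match.arg(severity)
  band <- .severity_bands[[severity]]
  freqs <- c(0.125, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
  pta_freqs <- c(0.5, 0.75, 1, 1.5, 2, 3, 4)
  .with_seed(seed, {
    # sloping shape in dB relative to its own 7-frequency PTA
    slope <- stats::runif(1, 6, 12) # dB per octave above 1 kHz
    shape <- pmax(0, log2(freqs / 1)) * slope -
      pmax(0, log2(0.5 / freqs)) * stats::runif(1, 0, 3)
    shape <- shape + stats::rnorm(length(freqs), 0, 2) # small jitter
    target <- stats::runif(1, band[1] + 2, band[2] - 2)
    thr <- shape - mean(shape[freqs %in% pta_freqs]) + target
    thr <- round(pmin(pmax(thr, -10), 115) / 5) * 5 # 5-dB audiometric steps
    # nudge back into the severity band if rounding/clamping drifted the PTA
    drift <- mean(thr[freqs %in% pta_freqs]) - target
    if (abs(drift) > 2.5) thr <- thr - round(drift / 5) * 5
    audiogram(freqs, pmin(pmax(thr, -10), 120),
              label = sprintf("synthetic %s (seed %d)", severity,
                              as.integer(seed)))
  })
}

#' Read / write audiograms as two-column CSV
#'
#' The text format is a CSV with header `frequency_khz,threshold_dbhl`.
#'
#' @param path file path.
#' @param label label for the audiogram read back.
#' @return `read_audiogram`: an [audiogram()]; `write_audiogram`: `path`,
#'   invisibly.
#' @export
read_audiogram <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  need <- c("frequency_khz", "threshold_dbhl")
  if (!all(need %in% names(d))) {
    stop("audiogram CSV must have columns: ", paste(need, collapse = ", "))
  }
  audiogram(d$frequency_khz, d$threshold_dbhl, label)
}

#' @rdname read_audiogram
#' @param ag an [audiogram()].
#' @export
write_audiogram <- function(ag, path) {
  stopifnot(inherits(ag, "audiogram"))
  utils::write.csv(
    data.frame(frequency_khz = ag$frequencies_khz,
               threshold_dbhl = ag$thresholds_dbhl),
    path, row.names = FALSE
  )
  invisible(path)
}
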