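# Scoring contract consumed by the optimizer, plus two desk-scale scorers
# that replace an external speech recognizer: an envelope-correlation
# intelligibility proxy, and a known-optimum oracle for optimizer testing.

#' Objective value with log-likelihood tie-break
#'
#' @param score_pct primary objective in percent, within \[0, 100\].
#' @param mean_loglik secondary criterion (finite; higher is better), used to
#'   break exact score ties.
#' @param degenerate flag set by scorers for pathological inputs (e.g.
#'   silence).
#' @return An object of class `score_result`.
#' @export
score_result <- function(score_pct, mean_loglik, degenerate = FALSE) {
  if (!is.finite(score_pct) || score_pct < -1e-9 || score_pct > 100 + 1e-9) {
    stop("score_pct must be finite and within [0, 100]")
  }
  if (!is.finite(mean_loglik)) stop("mean_loglik must be finite")
  structure(
    list(score_pct = min(max(score_pct, 0), 100),
         mean_loglik = mean_loglik, degenerate = isTRUE(degenerate)),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result: %.2f%% (loglik %.4f)%s>\n", x$score_pct,
              x$mean_loglik, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Score stimuli with a scorer
#'
#' Generic scoring interface: every scorer is deterministic and pure (no
#' hidden state across calls) and returns a [score_result()].
#'
#' @param scorer a scorer object ([proxy_scorer()] or similar).
#' @param stimuli non-empty list of [waveform()]s with one common sample rate.
#' @param ... passed to methods.
#' @return A [score_result()].
#' @export
score <- function(scorer, stimuli, ...) UseMethod("score")

.check_stimuli <- function(stimuli) {
  if (length(stimuli) == 0) stop("stimulus list must be non-empty")
  fs <- vapply(stimuli, function(w) w$sample_rate_hz, numeric(1))
  if (length(unique(fs)) != 1) stop("stimuli must share one sample rate")
  invisible(fs[1])
}

# band envelopes for the proxy: smoothed Hilbert magnitudes per analysis
# band, decimated to ~200 Hz (the envelope is already band-limited to
# `cutoff_hz`, so decimation loses nothing the correlation needs)
.proxy_envelopes <- function(w, edges_hz, cutoff_hz, order) {
  fs <- w$sample_rate_hz
  dec <- max(1L, as.integer(fs %/% 200))
  idx <- seq(1L, length(w$samples), by = dec)
  lapply(seq_len(length(edges_hz) - 1), function(b) {
    env <- .fft_lowpass(Mod(.analytic_band(w$samples, fs, edges_hz[b],
                                           edges_hz[b + 1], order)),
                        fs, cutoff_hz)
    env[idx]
  })
}

#' Envelope-correlation intelligibility proxy
#'
#' A desk-scale surrogate for a speech-recognition objective, in the spirit of
#' short-time envelope-correlation intelligibility metrics: the degraded and
#' clean band envelopes (five analysis bands, smoothed Hilbert magnitudes) are
#' compared by Pearson correlation per band and item; correlations are clipped
#' to \[0, 1\] and averaged, and the score is 100 times that average. The
#' secondary `mean_loglik` is the mean log of the per-item proxy values —
#' a stand-in that exercises the tie-break path, not an acoustic likelihood.
#' Silent degraded items score 0 and set the `degenerate` flag. The score is
#' invariant to global gain on the degraded signal (correlation is
#' scale-free).
#'
#' @param clean_refs list of clean reference [waveform()]s.
#' @param band_edges_khz analysis band edges (default: the HA channel bands).
#' @param envelope_cutoff_hz envelope smoothing cutoff (default 32 Hz).
#' @param filter_order analysis-filter order.
#' @return A scorer object of class `proxy_scorer`; use with [score()]
#'   passing the degraded stimuli aligned 1:1 with `clean_refs`.
#' @export
proxy_scorer <- function(clean_refs,
                         band_edges_khz = c(0.1, 0.7, 1.4, 2.8, 5.6, 8),
                         envelope_cutoff_hz = 32, filter_order = 16) {
  .check_stimuli(clean_refs)
  edges_hz <- band_edges_khz * 1000
  ref_envs <- lapply(clean_refs, .proxy_envelopes, edges_hz = edges_hz,
                     cutoff_hz = envelope_cutoff_hz, order = filter_order)
  structure(
    list(clean_refs = clean_refs, ref_envs = ref_envs, edges_hz = edges_hz,
         envelope_cutoff_hz = envelope_cutoff_hz, filter_order = filter_order),
    class = "proxy_scorer"
  )
}

#' @export
score.proxy_scorer <- function(scorer, stimuli, ...) {
  .check_stimuli(stimuli)
  if (length(stimuli) != length(scorer$clean_refs)) {
    stop("degraded and clean reference lists must be aligned 1:1")
  }
  degenerate <- FALSE
  item_vals <- vapply(seq_along(stimuli), function(i) {
    w <- stimuli[[i]]
    if (length(w$samples) != length(scorer$clean_refs[[i]]$samples)) {
      stop("item ", i, ": degraded and clean lengths differ")
    }
    if (sqrt(mean(w$samples^2)) < 1e-7) {
      degenerate <<- TRUE
      return(0)
    }
    envs <- .proxy_envelopes(w, scorer$edges_hz, scorer$envelope_cutoff_hz,
                             scorer$filter_order)
    r <- vapply(seq_along(envs), function(b) {
      e1 <- scorer$ref_envs[[i]][[b]]
      e2 <- envs[[b]]
      if (stats::sd(e1) < 1e-12 || stats::sd(e2) < 1e-12) return(0)
      stats::cor(e1, e2)
    }, numeric(1))
    mean(pmin(pmax(r, 0), 1))
  }, numeric(1))
  score_result(100 * mean(item_vals), mean(log(item_vals + 1e-6)),
               degenerate = degenerate)
}

#' Known-optimum oracle objective
#'
#' A synthetic objective with a brute-force-certifiable unique maximizer on
#' the time-constant grid: `score = 100 - sum_channels(|AT - AT*|/w_at +
#' |RT - RT*|/w_rt)`, floored at 0, with `mean_loglik = -distance` so that
#' ties in the floored region still order correctly. Used to test the random
#' search without any audio processing.
#'
#' @param peak_tc the [time_constants()] at which the score is 100.
#' @param w_at,w_rt distance scale (ms of deviation per lost point).
#' @return An object of class `oracle_scorer`.
#' @export
oracle_scorer <- function(peak_tc, w_at = 10, w_rt = 100) {
  stopifnot(inherits(peak_tc, "time_constants"), w_at > 0, w_rt > 0)
  structure(list(peak_tc = peak_tc, w_at = w_at, w_rt = w_rt),
            class = "oracle_scorer")
}

#' Evaluate the oracle objective at a candidate
#'
#' @param scorer an [oracle_scorer()].
#' @param tc candidate [time_constants()] (same channel count as the peak).
#' @return A [score_result()].
#' @export
score_for <- function(scorer, tc) UseMethod("score_for")

#' @export
score_for.oracle_scorer <- function(scorer, tc) {
  stopifnot(inherits(tc, "time_constants"))
  d <- sum(abs(tc$attack_ms - scorer$peak_tc$attack_ms) / scorer$w_at +
             abs(tc$release_ms - scorer$peak_tc$release_ms) / scorer$w_rt)
  score_result(max(0, 100 - d), -d)
}
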