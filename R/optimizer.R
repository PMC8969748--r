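# Contracting random search over per-channel attack/release times: uniform
# candidate sampling on a stepsize grid within per-parameter ranges centered
# on the incumbent, score-then-log-likelihood acceptance, linear range
# shrinkage per iteration, independent restarts ("threads"), best-of
# selection with a default-retention check.

#' Random-search specification
#'
#' @param at_bounds_ms global attack-time range (ms), default 10-500.
#' @param rt_bounds_ms global release-time range (ms), default 300-2000.
#' @param stepsize_ms grid step (ms), default 10; both range widths must be
#'   divisible by it.
#' @param n_iterations per-thread iteration budget, default 1000.
#' @param n_threads independent restarts, default 4.
#' @param seeds one RNG seed per thread (default `1:n_threads`).
#' @param n_channels number of compression channels (default 5).
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(at_bounds_ms = c(10, 500), rt_bounds_ms = c(300, 2000),
                        stepsize_ms = 10, n_iterations = 1000, n_threads = 4,
                        seeds = seq_len(n_threads), n_channels = 5) {
  for (b in list(at_bounds_ms, rt_bounds_ms)) {
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2]) {
      stop("bounds must be positive with lower < upper")
    }
    if (abs((b[2] - b[1]) %% stepsize_ms) > 1e-9) {
      stop("(upper - lower) must be divisible by stepsize")
    }
  }
  # search ranges may not escape the global slow-compression limits
  if (at_bounds_ms[1] < .AT_BOUNDS[1] || at_bounds_ms[2] > .AT_BOUNDS[2]) {
    stop("at_bounds_ms outside the global attack range ",
         .AT_BOUNDS[1], "-", .AT_BOUNDS[2], " ms")
  }
  if (rt_bounds_ms[1] < .RT_BOUNDS[1] || rt_bounds_ms[2] > .RT_BOUNDS[2]) {
    stop("rt_bounds_ms outside the global release range ",
         .RT_BOUNDS[1], "-", .RT_BOUNDS[2], " ms")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (n_threads < 1) stop("n_threads must be >= 1")
  if (length(seeds) != n_threads) stop("one seed per thread required")
  structure(
    list(at_bounds_ms = as.numeric(at_bounds_ms),
         rt_bounds_ms = as.numeric(rt_bounds_ms),
         stepsize_ms = as.numeric(stepsize_ms),
         n_iterations = as.integer(n_iterations),
         n_threads = as.integer(n_threads),
         seeds = as.integer(seeds),
         n_channels = as.integer(n_channels)),
    class = "search_spec"
  )
}

#' One step of the search-range contraction
#'
#' The range width shrinks linearly: `width - (initial_width -
#' 2*stepsize)/N` per iteration, so that after exactly `N` applications the
#' initial width has contracted to `2*stepsize` (the grid then holds the
#' baseline and its two neighbours).
#'
#' @param width_ms current range width (ms).
#' @param initial_width_ms width at iteration 1 (ms).
#' @param stepsize_ms grid step (ms).
#' @param n_iterations total iteration budget `N`.
#' @return The contracted width (ms).
#' @export
shrink_range <- function(width_ms, initial_width_ms, stepsize_ms, n_iterations) {
  width_ms - (initial_width_ms - 2 * stepsize_ms) / n_iterations
}

# grid values (multiples of stepsize anchored at the lower bound) inside
# [center - width/2, center + width/2] clipped to the global bounds
.grid_in_range <- function(center, width, bounds, step) {
  g <- seq(bounds[1], bounds[2], by = step)
  g[g >= center - width / 2 - 1e-9 & g <= center + width / 2 + 1e-9]
}

#' Sample a candidate configuration
#'
#' For every channel and both parameters, draws uniformly from the stepsize
#' grid within the current range centered on the baseline value, intersected
#' with the global bounds. All parameters are resampled each iteration.
#'
#' @param baseline_tc incumbent [time_constants()] (range centers).
#' @param width_at_ms,width_rt_ms current range widths (ms).
#' @param spec a [search_spec()].
#' @return A candidate [time_constants()].
#' @export
sample_candidate <- function(baseline_tc, width_at_ms, width_rt_ms, spec) {
  draw <- function(center, width, bounds) {
    g <- .grid_in_range(center, width, bounds, spec$stepsize_ms)
    g[sample.int(length(g), 1)]
  }
  time_constants(
    vapply(baseline_tc$attack_ms, draw, numeric(1),
           width = width_at_ms, bounds = spec$at_bounds_ms),
    vapply(baseline_tc$release_ms, draw, numeric(1),
           width = width_rt_ms, bounds = spec$rt_bounds_ms)
  )
}

#' Acceptance rule: higher score, ties broken by log-likelihood
#'
#' `TRUE` iff the candidate's score is strictly higher than the incumbent's,
#' or equal with a strictly higher mean log-likelihood. An exact tie on both
#' keeps the incumbent.
#'
#' @param candidate,incumbent [score_result()]s.
#' @return Logical.
#' @export
accept <- function(candidate, incumbent) {
  candidate$score_pct > incumbent$score_pct ||
    (candidate$score_pct == incumbent$score_pct &&
       candidate$mean_loglik > incumbent$mean_loglik)
}

#' Run one random-search thread
#'
#' Iteration 1 draws the first candidate uniformly from the full grids and
#' makes it the incumbent. Every following iteration samples around the
#' incumbent within the current (contracting) ranges, evaluates, accepts or
#' keeps, then shrinks both range widths. Bit-reproducible for a fixed seed.
#'
#' @param spec a [search_spec()].
#' @param objective function `time_constants -> score_result`; build one with
#'   [oracle_objective()] or [pipeline_objective()].
#' @param seed integer RNG seed for this thread.
#' @return A list with `best_tc`, `best_result` and a per-iteration `trace`
#'   data frame (candidate parameters, score, log-likelihood, acceptance,
#'   range widths, running best score).
#' @export
run_thread <- function(spec, objective, seed) {
  stopifnot(inherits(spec, "search_spec"))
  n_ch <- spec$n_channels
  width_at0 <- spec$at_bounds_ms[2] - spec$at_bounds_ms[1]
  width_rt0 <- spec$rt_bounds_ms[2] - spec$rt_bounds_ms[1]

  .with_seed(seed, {
    width_at <- width_at0
    width_rt <- width_rt0
    rows <- vector("list", spec$n_iterations)
    best_tc <- NULL
    best <- NULL
    for (i in seq_len(spec$n_iterations)) {
      if (i == 1) {
        # initialization: uniform over the full ranges (centering on the
        # midpoint with full width makes every grid point reachable)
        mid <- time_constants(rep(mean(spec$at_bounds_ms), n_ch),
                              rep(mean(spec$rt_bounds_ms), n_ch))
        cand <- sample_candidate(mid, width_at0, width_rt0, spec)
      } else {
        cand <- sample_candidate(best_tc, width_at, width_rt, spec)
      }
      res <- objective(cand)
      if (!inherits(res, "score_result")) {
        stop("objective must return a score_result")
      }
      accepted <- is.null(best) || accept(res, best)
      if (accepted) {
        best <- res
        best_tc <- cand
      }
      rows[[i]] <- data.frame(
        iteration = i,
        t(stats::setNames(cand$attack_ms, paste0("at", seq_len(n_ch)))),
        t(stats::setNames(cand$release_ms, paste0("rt", seq_len(n_ch)))),
        score_pct = res$score_pct, mean_loglik = res$mean_loglik,
        accepted = accepted,
        width_at_ms = width_at, width_rt_ms = width_rt,
        best_score_pct = best$score_pct
      )
      width_at <- shrink_range(width_at, width_at0, spec$stepsize_ms,
                               spec$n_iterations)
      width_rt <- shrink_range(width_rt, width_rt0, spec$stepsize_ms,
                               spec$n_iterations)
    }
    list(best_tc = best_tc, best_result = best,
         trace = do.call(rbind, rows))
  })
}

#' Run the full multi-thread random search
#'
#' Runs `n_threads` independent [run_thread()] restarts (sequentially, so the
#' result cannot depend on scheduling) and selects the thread with the
#' highest score, ties broken by higher mean log-likelihood, then by lowest
#' thread index. If `default_tc` is supplied it is evaluated too, and
#' retained as the final answer unless some thread strictly beats it under
#' the same acceptance rule — mirroring the observation that a search can
#' fail to improve on the default compression speeds.
#'
#' @inheritParams run_thread
#' @param default_tc optional default [time_constants()] to compare against.
#' @return A list with `best_tc`, `best_result`, `thread_results`,
#'   `default_retained` and (when applicable) `default_result`.
#' @export
run_search <- function(spec, objective, default_tc = NULL) {
  stopifnot(inherits(spec, "search_spec"))
  threads <- lapply(seq_len(spec$n_threads), function(k) {
    run_thread(spec, objective, spec$seeds[k])
  })
  best_k <- 1
  for (k in seq_len(spec$n_threads)[-1]) {
    if (accept(threads[[k]]$best_result, threads[[best_k]]$best_result)) {
      best_k <- k
    }
  }
  out <- list(best_tc = threads[[best_k]]$best_tc,
              best_result = threads[[best_k]]$best_result,
              best_thread = best_k,
              thread_results = threads,
              default_retained = FALSE)
  if (!is.null(default_tc)) {
    def_res <- objective(default_tc)
    out$default_result <- def_res
    if (!accept(out$best_result, def_res)) {
      out$best_tc <- default_tc
      out$best_result <- def_res
      out$default_retained <- TRUE
    }
  }
  out
}

#' Oracle objective for optimizer testing
#'
#' Wraps an [oracle_scorer()] as an objective function for [run_thread()].
#'
#' @param scorer an [oracle_scorer()].
#' @return Function `time_constants -> score_result`.
#' @export
oracle_objective <- function(scorer) {
  stopifnot(inherits(scorer, "oracle_scorer"))
  function(tc) score_for(scorer, tc)
}

#' Full-chain audio objective
#'
#' The evaluation pipeline of the optimization chain: candidate time constants
#' are written into the hearing-aid configuration, the stimuli are amplified
#' ([amplify()]), degraded by the hearing-loss simulator ([simulate_hl()]),
#' and scored ([score()]).
#'
#' @param cfg_template an [ha_config()] whose time constants are replaced per
#'   candidate.
#' @param ag the listener's [audiogram()].
#' @param stimuli list of calibrated [waveform()] stimuli.
#' @param scorer a scorer with a [score()] method (e.g. [proxy_scorer()]).
#' @param hl_cfg an [hl_sim_config()].
#' @return Function `time_constants -> score_result`.
#' @export
pipeline_objective <- function(cfg_template, ag, stimuli, scorer,
                               hl_cfg = hl_sim_config()) {
  stopifnot(inherits(cfg_template, "ha_config"))
  if (anyNA(.ag_match(ag, .HL_DESIGN_FREQS))) {
    ag <- complete_audiogram(ag, .HL_DESIGN_FREQS)
  }
  function(tc) {
    cfg <- cfg_template
    cfg$tc <- tc
    degraded <- lapply(stimuli, function(w) simulate_hl(amplify(w, cfg), ag,
                                                        hl_cfg))
    score(scorer, degraded)
  }
}
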