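test_that("shrink_range follows the linear contraction law", {
  # attack range 500-10 = 490, step 10, N = 1000: decrement 0.47
  expect_equal(shrink_range(490, 490, 10, 1000), 489.53)
  # fixed point at width 2*stepsize
  expect_equal(shrink_range(20, 20, 10, 1000), 20)
  # telescoping-sum oracle: N applications land exactly on 2*stepsize
  w <- 490
  for (i in seq_len(1000)) w <- shrink_range(w, 490, 10, 1000)
  expect_equal(w, 20, tolerance = 1e-9)
  # closed form at every iteration
  w <- 1700
  for (i in seq_len(250)) {
    w <- shrink_range(w, 1700, 10, 1000)
    expect_equal(w, 1700 - i * (1700 - 20) / 1000, tolerance = 1e-9)
  }
})

test_that("search_spec validates bounds and seeds", {
  expect_s3_class(search_spec(), "search_spec")
  expect_error(search_spec(at_bounds_ms = c(500, 10)), "lower < upper")
  expect_error(search_spec(at_bounds_ms = c(10, 505)), "divisible")
  expect_error(search_spec(n_threads = 2, seeds = 1), "one seed per thread")
  expect_error(search_spec(n_iterations = 0), "n_iterations")
})

test_that("sampled candidates live on the grid inside the current window", {
  spec <- search_spec()
  base <- time_constants(rep(250, 5), rep(1000, 5))
  set.seed(1)
  for (i in 1:200) {
    cand <- sample_candidate(base, 490, 1700, spec)
    expect_true(all(cand$attack_ms %% 10 == 0))
    expect_true(all(cand$release_ms %% 10 == 0))
    expect_true(all(cand$attack_ms >= 10 & cand$attack_ms <= 500))
    expect_true(all(cand$release_ms >= 300 & cand$release_ms <= 2000))
  }
  # fully contracted window: only the baseline and its grid neighbours
  set.seed(2)
  vals <- replicate(300, sample_candidate(base, 20, 20, spec)$attack_ms[1])
  expect_setequal(unique(vals), c(240, 250, 260))
  # window clipped at a global bound never escapes it
  edge <- time_constants(rep(10, 5), rep(300, 5))
  vals <- replicate(200, sample_candidate(edge, 20, 20, spec)$attack_ms[1])
  expect_setequal(unique(vals), c(10, 20))
})

test_that("full-range sampling is uniform over the grid (chi-square)", {
  spec <- search_spec(n_channels = 1)
  base <- time_constants(255, 1150)
  set.seed(42)
  draws <- replicate(10000, sample_candidate(base, 490, 1700, spec)$attack_ms)
  tab <- table(factor(draws, levels = seq(10, 500, by = 10)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("acceptance rule: higher score wins, ties broken by log-likelihood", {
  expect_true(accept(score_result(92, -5), score_result(88, -4)))
  expect_true(accept(score_result(88, -3), score_result(88, -4)))
  expect_false(accept(score_result(88, -4), score_result(88, -4)))
  expect_false(accept(score_result(86, -1), score_result(88, -4)))
})

test_that("run_thread traces are monotone, legal and reproducible", {
  spec <- search_spec(n_iterations = 300, n_threads = 1, n_channels = 2)
  orc <- oracle_scorer(time_constants(c(130, 200), c(1190, 800)))
  th <- run_thread(spec, oracle_objective(orc), seed = 5)
  expect_identical(nrow(th$trace), 300L)
  expect_false(is.unsorted(th$trace$best_score_pct))
  expect_gte(th$best_result$score_pct, th$trace$score_pct[1])
  for (col in c("at1", "at2")) {
    expect_true(all(th$trace[[col]] %% 10 == 0 &
                      th$trace[[col]] >= 10 & th$trace[[col]] <= 500))
  }
  for (col in c("rt1", "rt2")) {
    expect_true(all(th$trace[[col]] %% 10 == 0 &
                      th$trace[[col]] >= 300 & th$trace[[col]] <= 2000))
  }
  # closed-form width columns
  expect_equal(th$trace$width_at_ms,
               490 - (seq_len(300) - 1) * (490 - 20) / 300, tolerance = 1e-9)
  # bit-identical repetition
  th2 <- run_thread(spec, oracle_objective(orc), seed = 5)
  expect_identical(th$trace, th2$trace)
  expect_false(identical(th$trace,
                         run_thread(spec, oracle_objective(orc), seed = 6)$trace))
})

test_that("random search recovers the oracle optimum at small scale", {
  spec <- search_spec(n_iterations = 200, n_threads = 1, n_channels = 1)
  orc <- oracle_scorer(time_constants(130, 1190))
  hits <- vapply(1:20, function(s) {
    th <- run_thread(spec, oracle_objective(orc), seed = s)
    abs(th$best_tc$attack_ms - 130) <= 20 && abs(th$best_tc$release_ms - 1190) <= 50
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("run_search picks the best thread with deterministic tie-breaks", {
  # synthetic objective keyed on the thread's first draw is hard to control;
  # instead check selection logic through the oracle with varying seeds
  spec <- search_spec(n_iterations = 50, n_threads = 4, seeds = c(11, 12, 13, 14),
                      n_channels = 1)
  orc <- oracle_scorer(time_constants(130, 1190))
  res <- run_search(spec, oracle_objective(orc))
  scores <- vapply(res$thread_results, function(t) t$best_result$score_pct,
                   numeric(1))
  expect_equal(res$best_result$score_pct, max(scores))
  expect_equal(res$best_thread, which(scores == max(scores))[1])
  # n_threads = 1 degenerates to run_thread
  spec1 <- search_spec(n_iterations = 50, n_threads = 1, seeds = 11,
                       n_channels = 1)
  one <- run_search(spec1, oracle_objective(orc))
  expect_identical(one$best_tc, res$thread_results[[1]]$best_tc)
})

test_that("defaults are retained when no thread beats them", {
  spec <- search_spec(n_iterations = 5, n_threads = 2, seeds = c(1, 2),
                      n_channels = 1)
  peak <- time_constants(130, 1190)
  orc <- oracle_scorer(peak, w_at = 0.01, w_rt = 0.01) # near-impossible target
  res <- run_search(spec, oracle_objective(orc), default_tc = peak)
  expect_true(res$default_retained)
  expect_identical(res$best_tc, peak)
  expect_equal(res$best_result$score_pct, 100)
  # and not retained when a thread can win
  orc2 <- oracle_scorer(peak)
  res2 <- run_search(search_spec(n_iterations = 400, n_threads = 1, seeds = 3,
                                 n_channels = 1),
                     oracle_objective(orc2),
                     default_tc = time_constants(500, 2000))
  expect_false(res2$default_retained)
})
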