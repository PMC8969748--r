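test_that("static curve follows the two-anchor construction", {
  crv <- derive_static_curve(20, 10, 50)
  expect_equal(attr(crv, "cr"), 2)
  expect_equal(crv(65), 20)
  expect_equal(crv(85), 10)
  expect_equal(crv(75), 15)
  # flat below threshold, continuous at it
  expect_equal(crv(50), crv(40))
  expect_equal(crv(50), crv(50 - 1e-9), tolerance = 1e-6)
  # equal anchors: linear, constant gain everywhere
  lin <- derive_static_curve(12, 12, 45)
  expect_equal(attr(lin, "cr"), 1)
  expect_equal(lin(c(30, 65, 85, 100)), rep(12, 4))
  expect_error(derive_static_curve(25, 5, 50), "compression ratio")
})

test_that("envelope follower converges to a stationary tone's level", {
  tn <- make_tone(1000, 72, 1)
  lev <- envelope_follower(tn, 50, 500)
  n <- length(lev)
  expect_equal(lev[round(0.9 * n)], 72, tolerance = 0.1)
  expect_error(envelope_follower(tn, -5, 500), "positive")
})

test_that("attack and release settling match nominal times on 55<->90 steps", {
  fs <- 22050
  up <- make_level_step(1000, 55, 90, 0.5, 2)
  lev <- envelope_follower(up, 100, 1000)
  t_att <- measure_settling_time(lev, fs, 0.5, 90, 3)
  expect_lt(abs(t_att - 0.1), 0.2 * 0.1)

  down <- make_level_step(1000, 90, 55, 0.5, 4)
  lev2 <- envelope_follower(down, 100, 1000)
  t_rel <- measure_settling_time(lev2, fs, 0.5, 55, 4)
  expect_lt(abs(t_rel - 1), 0.2 * 1)
})

test_that("compress_channel reproduces the static law at steady state", {
  crv <- derive_static_curve(20, 10, 50)
  for (case in list(c(65, 85), c(85, 95), c(40, 70))) {
    out <- compress_channel(make_tone(1000, case[1], 1), crv, 50, 500)
    expect_equal(steady_level(out), case[2], tolerance = 0.2)
  }
})

test_that("limiter is transparent below threshold and ratio-limits above", {
  below <- limit_channel(make_tone(1000, 80, 0.8), threshold_db_spl = 85,
                         ratio = 10)
  expect_equal(steady_level(below), 80, tolerance = 0.1)
  above <- limit_channel(make_tone(1000, 95, 0.8), threshold_db_spl = 85,
                         ratio = 10)
  expect_equal(steady_level(above), 86, tolerance = 0.2)
  # disabled limiter is a near-exact passthrough
  tn <- make_tone(1000, 90, 0.3)
  off <- limit_channel(tn, threshold_db_spl = Inf)
  expect_equal(off$samples, tn$samples, tolerance = 1e-9)
})

test_that("amplify reproduces the gain anchors in every channel", {
  cfg <- test_ha_config(limiter_threshold_db_spl = Inf)
  for (ch in 1:5) {
    f <- band_centers_hz()[ch]
    o65 <- amplify(make_tone(f, 65, 0.6), cfg)
    o85 <- amplify(make_tone(f, 85, 0.6), cfg)
    expect_equal(steady_level(o65), 65 + cfg$ig65_db[ch], tolerance = 0.2)
    expect_equal(steady_level(o85), 85 + cfg$ig85_db[ch], tolerance = 0.2)
  }
})

test_that("identity configuration passes signals through within 0.5 dB", {
  cfg0 <- ha_config(rep(0, 5), rep(0, 5), rep(45, 5),
                    limiter_threshold_db_spl = Inf)
  # in-band probes (>= 150 Hz, <= 7 kHz: away from the outer band limits)
  for (f in c(150, 300, 700, 1000, 1400, 2800, 4000, 5600, 7000)) {
    tn <- make_tone(f, 70, 0.4)
    out <- amplify(tn, cfg0)
    expect_equal(steady_level(out, skip_s = 0.1), 70, tolerance = 0.5)
  }
})

test_that("a 1-kHz tone engages only channel 2", {
  cfg <- test_ha_config()
  tn <- make_tone(1000, 70, 0.4)
  e <- cfg$channel_edges_khz * 1000
  energies <- vapply(1:5, function(ch) {
    b <- hafit:::.analytic_band(tn$samples, tn$sample_rate_hz, e[ch], e[ch + 1],
                                cfg$filter_order)
    10 * log10(mean(Re(b)^2))
  }, numeric(1))
  expect_true(all(energies[-2] <= energies[2] - 30))
})

test_that("steady-state output level is monotone in input level", {
  cfg <- test_ha_config()
  levels <- seq(40, 90, by = 10)
  out <- vapply(levels, function(L) {
    steady_level(amplify(make_tone(990, L, 0.5), cfg))
  }, numeric(1))
  expect_true(all(diff(out) > -1e-6))
})

test_that("amplify is deterministic and accepts the default time constants", {
  tc <- default_time_constants()
  expect_equal(tc$attack_ms, c(200, 100, 100, 100, 100))
  expect_equal(tc$release_ms, c(2000, 1500, 1200, 1000, 1000))
  cfg <- test_ha_config(tc = tc)
  w <- make_speech_surrogate(1, 9, duration_s = 0.3)[[1]]
  a <- amplify(w, cfg)
  b <- amplify(w, cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(length(a$samples), length(w$samples))
})

test_that("configuration invariants are enforced", {
  expect_error(test_ha_config(channel_edges_khz = c(0.1, 0.7, 1.4, 2.8, 8)),
               "5 channels")
  expect_error(ha_config(rep(10, 5), rep(20, 5), rep(45, 5)), "ig65")
  expect_error(ha_config(rep(25, 5), rep(4, 5), rep(45, 5)), "-20")
  expect_error(ha_config(rep(20, 5), rep(10, 5), rep(70, 5)), "below 65")
  expect_error(test_ha_config(limiter_ratio = 2), ">= 10")
  expect_error(time_constants(c(5, rep(100, 4)), rep(1000, 5)), "10")
  expect_error(time_constants(rep(100, 5), rep(2500, 5)), "2000")
  expect_error(amplify(make_speech_surrogate(1, 1, duration_s = 0.1)[[1]],
                       structure(list(), class = "ha_config")))
})
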