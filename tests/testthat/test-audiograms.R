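test_that("audiogram construction enforces invariants", {
  expect_s3_class(audiogram(c(0.5, 1, 2), c(20, 30, 40)), "audiogram")
  expect_error(audiogram(c(1, 0.5), c(10, 20)), "increasing")
  expect_error(audiogram(c(0.05, 1), c(10, 20)), "0.125")
  expect_error(audiogram(c(0.5, 1), c(10, 130)), "120")
  expect_error(audiogram(c(0.5, 1), c(10, 20, 30)), "equal length")
  expect_error(audiogram(0.5, 10), "at least 2")
})

test_that("completion recovers data lying exactly on a cubic in log2 f", {
  freqs <- c(0.25, 0.5, 1, 2, 4, 8)
  poly <- function(f) 10 + 5 * log2(f / 0.125)
  ag <- audiogram(freqs, poly(freqs))
  done <- complete_audiogram(ag, c(0.75, 1.5, 3))
  for (f in c(0.75, 1.5, 3)) {
    i <- which(abs(done$frequencies_khz - f) < 1e-9)
    expect_equal(done$thresholds_dbhl[i], poly(f), tolerance = 1e-6)
  }
  # and a genuinely cubic surface, not just a line
  poly3 <- function(f) 30 + 4 * log2(f) - 1.5 * log2(f)^2 + 0.4 * log2(f)^3
  ag3 <- audiogram(freqs, poly3(freqs))
  done3 <- complete_audiogram(ag3, c(0.75, 3))
  for (f in c(0.75, 3)) {
    i <- which(abs(done3$frequencies_khz - f) < 1e-9)
    expect_equal(done3$thresholds_dbhl[i], poly3(f), tolerance = 1e-6)
  }
})

test_that("completion of a flat audiogram is flat", {
  ag <- audiogram(c(0.25, 0.5, 1, 2, 4, 8), rep(40, 6))
  done <- complete_audiogram(ag, 0.75)
  i <- which(abs(done$frequencies_khz - 0.75) < 1e-9)
  expect_equal(done$thresholds_dbhl[i], 40, tolerance = 1e-8)
})

test_that("completion matches a brute-force normal-equations cubic fit", {
  freqs <- c(0.25, 0.5, 1, 2, 3, 4, 6)
  thr <- c(20, 25, 35, 45, 55, 65, 70)
  ag <- audiogram(freqs, thr)
  # independent oracle: direct solve of the 4x4 normal equations
  x <- log2(freqs)
  V <- outer(x, 0:3, `^`)
  beta <- solve(t(V) %*% V, t(V) %*% thr)
  oracle <- function(f) drop(outer(log2(f), 0:3, `^`) %*% beta)
  done <- complete_audiogram(ag, c(0.75, 1.5))
  for (f in c(0.75, 1.5)) {
    i <- which(abs(done$frequencies_khz - f) < 1e-9)
    expect_equal(done$thresholds_dbhl[i], oracle(f), tolerance = 1e-8)
  }
})

test_that("completion retains original thresholds verbatim and is idempotent", {
  ag <- audiogram(c(0.25, 0.5, 1, 2, 4, 8), c(15, 20, 30, 50, 70, 85))
  done <- complete_audiogram(ag, STD_FREQS)
  idx <- match(ag$frequencies_khz, done$frequencies_khz)
  expect_identical(done$thresholds_dbhl[idx], ag$thresholds_dbhl)
  expect_identical(complete_audiogram(done, STD_FREQS), done)
  # extrapolation stays clamped to the physical range
  expect_true(all(done$thresholds_dbhl >= -10 & done$thresholds_dbhl <= 120))
})

test_that("completion rejects degenerate requests", {
  expect_error(complete_audiogram(audiogram(c(0.5, 1, 2), c(10, 20, 30))),
               "insufficient points")
  ag <- audiogram(c(0.25, 0.5, 1, 2), c(10, 20, 30, 40))
  expect_error(complete_audiogram(ag, 10), "audiometric band")
})

test_that("pta averages exactly the requested frequencies", {
  ag <- audiogram(PTA_FREQS, c(30, 35, 40, 45, 50, 55, 60))
  expect_equal(pta(ag), 45)
  expect_equal(pta(ag, 2), 50) # single-frequency identity
  expect_equal(pta(flat_audiogram(40)), 40)
  expect_equal(pta(flat_audiogram(40), c(0.5, 4)), 40)
  expect_error(pta(audiogram(c(0.5, 1), c(10, 10)), PTA_FREQS),
               "complete_audiogram")
})

test_that("synthetic audiograms are deterministic, ordered and in range", {
  a1 <- synth_audiogram("moderate", 42)
  a2 <- synth_audiogram("moderate", 42)
  expect_identical(a1[c("frequencies_khz", "thresholds_dbhl")],
                   a2[c("frequencies_khz", "thresholds_dbhl")])
  for (s in seq_len(20)) {
    expect_lt(pta(synth_audiogram("mild", s)), pta(synth_audiogram("severe", s)))
  }
  bands <- list(mild = c(20, 34), moderate = c(35, 49),
                moderately_severe = c(50, 64), severe = c(65, 80))
  for (sev in names(bands)) {
    for (s in seq_len(25)) {
      ag <- synth_audiogram(sev, s)
      expect_true(all(ag$thresholds_dbhl >= -10 & ag$thresholds_dbhl <= 120))
      p <- pta(ag)
      expect_gte(p, bands[[sev]][1] - 1e-9)
      expect_lte(p, bands[[sev]][2] + 1e-9)
    }
  }
})

test_that("audiogram CSV round trip is lossless", {
  ag <- synth_audiogram("mild", 3)
  path <- tempfile(fileext = ".csv")
  write_audiogram(ag, path)
  back <- read_audiogram(path)
  expect_equal(back$frequencies_khz, ag$frequencies_khz)
  expect_equal(back$thresholds_dbhl, ag$thresholds_dbhl)
})
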