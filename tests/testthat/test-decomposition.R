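test_that("sifting isolates the fastest mode and flags unsiftable input", {
  # single-mode input passes through
  x <- tone(10)
  s <- sift(x)
  expect_true(s$siftable)
  expect_gt(cor(s$imf, x), 0.99)
  expect_gt(sum(s$imf^2) / sum(x^2), 0.99)

  # two-tone sum: first sift extracts the fast tone (narrowband oracle)
  x2 <- tone(4) + tone(40)
  s2 <- sift(x2)
  expect_gt(cor(s2$imf[INTERIOR], tone(40)[INTERIOR]), 0.95)
  expect_equal(s2$imf + s2$remainder, x2)

  # monotonic ramp: no IMF, all residue
  s3 <- sift(seq(0, 1, length.out = 200))
  expect_false(s3$siftable)
  expect_null(s3$imf)
})

test_that("every produced IMF satisfies the defining count property", {
  set.seed(5)
  d <- emd(rnorm(1400))
  int <- 71:1330
  for (k in seq_len(ncol(d$imfs))) {
    e <- holospec:::.extrema_c(d$imfs[int, k])
    n_ext <- length(e$maxima) + length(e$minima)
    expect_lte(abs(n_ext - e$zero_crossings), 1)
  }
})

test_that("EMD reconstructs exactly and separates tone from trend", {
  set.seed(6)
  for (x in list(rnorm(1400), tone(10) + tone(3), am_tone())) {
    d <- emd(x)
    expect_lt(max(abs(reconstruct(d) - x)) / max(abs(x)), 1e-8)
  }
  xt <- tone(10) + seq(0, 3, length.out = length(TT))
  d <- emd(xt)
  expect_gt(cor(d$imfs[, 1], tone(10)), 0.999)
  slow <- reconstruct(d) - d$imfs[, 1]
  expect_gt(cor(slow, seq(0, 3, length.out = length(TT))), 0.999)
  expect_error(emd(c(rnorm(100), NA, rnorm(100))), "finite")
})

test_that("EMD acts as a dyadic filter bank on white noise", {
  set.seed(42)
  ratios <- replicate(50, dyadic_ratio(emd(rnorm(1400)), rate = RATE))
  expect_gt(mean(ratios), 1.8)
  expect_lt(mean(ratios), 2.2)
})

test_that("orthogonality index stays low on tonal signals", {
  expect_lt(orthogonality_index(emd(tone(4) + tone(40))), 0.1)
  expect_lt(orthogonality_index(emd(tone(3) + tone(12) + tone(48))), 0.1)
})

test_that("degenerate iCEEMDAN equals plain EMD elementwise", {
  x <- tone(4) + tone(40)
  d1 <- iceemdan(x, ensemble_size = 1, noise_sd = 0)
  d0 <- emd(x)
  expect_identical(d1$imfs, d0$imfs)
  expect_identical(d1$residue, d0$residue)
})

test_that("iCEEMDAN is seed-deterministic with stable mode counts", {
  x <- with_seed(7, am_tone() + rnorm(1400, sd = 0.3))
  a <- iceemdan(x, 20, 0.2, seed = 11)
  b <- iceemdan(x, 20, 0.2, seed = 11)
  expect_identical(a$imfs, b$imfs)
  counts <- vapply(1:4, function(s) ncol(iceemdan(x, 10, 0.2, seed = s)$imfs), 0L)
  expect_lte(diff(range(counts)), 2)     # +/- 1 around the typical count
})

test_that("iCEEMDAN recovers a planted AM tone from 10 dB noise", {
  clean <- am_tone(fc = 40, fam = 4, m = 0.5)
  x <- with_seed(8, clean + rnorm(1400, sd = sd(clean) / sqrt(10)))
  d <- iceemdan(x, ensemble_size = 50, noise_sd = 0.2, seed = 13)
  f <- apply(d$imfs, 2, mean_frequency, rate = RATE)
  k <- which(f >= 32 & f <= 100)[1]
  expect_false(is.na(k))
  expect_gt(cor(d$imfs[INTERIOR, k], clean[INTERIOR]), 0.9)
  expect_lt(max(abs(reconstruct(d) - x)) / max(abs(x)), 1e-7)
})

test_that("iCEEMDAN reconstructs white noise better than plain EEMD", {
  w <- with_seed(9, rnorm(1400))
  e1 <- eemd(w, ensemble_size = 30, noise_sd = 0.2, seed = 7)
  e2 <- iceemdan(w, ensemble_size = 30, noise_sd = 0.2, seed = 7)
  err <- function(d) max(abs(reconstruct(d) - w))
  expect_lt(err(e2), err(e1))
})

test_that("spline envelope interpolates the maxima and tracks known envelopes", {
  # constant-amplitude tone: within 2% over the interior 80%
  x <- tone(10)
  e <- envelope(x)
  int80 <- round(0.1 * 1400):round(0.9 * 1400)
  expect_lt(max(abs(e[int80] - 1)), 0.02)

  # AM tone at a denser carrier sampling: envelope correlates > 0.98
  rate <- 1000
  t <- seq_len(7 * rate) / rate
  xa <- (1 + 0.5 * cos(2 * pi * 4 * t)) * cos(2 * pi * 40 * t)
  ea <- envelope(xa)
  int <- round(0.1 * length(t)):round(0.9 * length(t))
  expect_gt(cor(ea[int], (1 + 0.5 * cos(2 * pi * 4 * t))[int]), 0.98)

  # exact interpolation at the detected maxima of |x|
  mx <- holospec:::.extrema_c(abs(xa))$maxima
  expect_equal(ea[mx], abs(xa)[mx], tolerance = 1e-10)

  # degenerate: fewer than 2 maxima -> constant max|x| with warning
  expect_warning(ec <- envelope(seq(-1, 2, length.out = 50)), "maxima")
  expect_equal(ec, rep(2, 50))
  expect_true(all(envelope(xa) >= 0))
})
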