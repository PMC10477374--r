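test_that("direct quadrature recovers constant, ramping and AM-masked frequency", {
  # constant-frequency tone
  d <- direct_quadrature(tone(10), RATE)
  expect_lt(abs(median(d$inst_freq[d$valid]) - 10), 0.1)

  # linear chirp 5 -> 15 Hz over 7 s, smoothed track RMSE < 0.5 Hz interior
  chirp <- sin(2 * pi * (5 * TT + (10 / 7) * TT^2 / 2))
  dc <- direct_quadrature(chirp, RATE, smooth_secs = 0.75)
  truef <- 5 + (10 / 7) * TT
  ix <- which(dc$valid)
  expect_lt(sqrt(mean((dc$inst_freq[ix] - truef[ix])^2)), 0.5)

  # FM/AM separation: envelope variation leaves the carrier estimate at 40 Hz
  da <- direct_quadrature(am_tone(), RATE)
  expect_lt(abs(median(da$inst_freq[da$valid]) - 40), 1)
  expect_true(all(abs(da$carrier) <= 1))
  expect_true(all(da$envelope >= 0))
})

test_that("HHT marginal accounts energy into the right carrier bands", {
  g <- band_grid(RATE)
  # 10 Hz tone of amplitude A: alpha band holds nearly all power, total ~ A^2
  A <- 3
  m <- hht_marginal(emd(tone(10, amp = A)), g, RATE)
  expect_gt(m[["alpha"]] / sum(m), 0.95)
  expect_equal(unname(m[["alpha"]]), A^2, tolerance = 0.1 * A^2)

  # silence
  m0 <- hht_marginal(emd(c(numeric(1399), 1e-30)), g, RATE)
  expect_true(all(m0 < 1e-20))

  # equal-amplitude 3 and 20 Hz tones land symmetrically in delta2 and beta
  m2 <- hht_marginal(emd(tone(3) + tone(20)), g, RATE)
  expect_lt(abs(m2[["delta2"]] - m2[["beta"]]) / m2[["beta"]], 0.1)
})

test_that("the Holo-Hilbert spectrum localizes planted AM at one channel", {
  g <- band_grid(RATE)
  clean <- am_tone(fc = 40, fam = 4, m = 0.5)
  x <- with_seed(3, clean + rnorm(1400, sd = sd(clean) / sqrt(10)))
  data <- rbind(O1 = x, O2 = with_seed(4, rnorm(1400, sd = 0.05)))
  hs <- holo_spectrum(data, grid = g, config = holo_config(ensemble = 16, seed = 7),
                      rate = RATE)
  v1 <- hs$values[1, , ]; v1[hs$mask[1, , ]] <- NA
  # planted cell is the arg-max and dominates the planted channel's AM power
  w <- which(v1 == max(v1, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(unname(w), c(4, 7))        # (theta AM, gamma carrier)
  expect_gt(v1[4, 7] / sum(v1, na.rm = TRUE), 0.5)
  # other channel near zero
  expect_lt(sum(hs$values[2, , ]), 0.01 * sum(hs$values[1, , ], na.rm = TRUE))
})

test_that("an unmodulated tone concentrates its power in the Lf AM band", {
  g <- band_grid(RATE)
  hs <- holo_spectrum(matrix(tone(10), 1), grid = g,
                      config = holo_config(ensemble = 1, noise_sd = 0, seed = 1),
                      rate = RATE)
  v <- hs$values[1, , ]
  expect_gt(v[1, 5] / sum(v), 0.95)       # (Lf, alpha)
  expect_equal(hs$diagnostics$lf_fallback, 1)
})

test_that("spectrum values are finite, non-negative, masked off-triangle", {
  x <- with_seed(5, rnorm(1400))
  hs <- holo_spectrum(matrix(x, 1), config = holo_config(ensemble = 4, seed = 2),
                      rate = RATE)
  expect_true(all(is.finite(hs$values)))
  expect_true(all(hs$values >= 0))
  am <- slice.index(hs$mask, 2); ca <- slice.index(hs$mask, 3)
  expect_true(all(hs$mask[am > ca]))
  expect_true(all(hs$bedrosian[am == ca & ca >= 2]))
})

test_that("subject averaging is an element-wise mean with k^2 power scaling", {
  g <- band_grid(RATE)
  mkep <- function(data) structure(list(data = data, rate = RATE,
                                        channels = "O1", epoch_index = 1,
                                        subject_id = "S"), class = "epoch")
  x <- with_seed(6, am_tone() + rnorm(1400, sd = 0.2))
  e1 <- mkep(matrix(x, 1))
  cfg <- holo_config(ensemble = 4, seed = 3)
  # identical epochs: average equals any single epoch
  s1 <- holo_spectrum(e1, grid = g, config = cfg)
  savg <- subject_spectrum(list(e1, e1), grid = g, config = cfg)
  expect_equal(savg$values, s1$values)
  expect_equal(savg$n_epochs, 2L)
  # doubling the amplitude multiplies every cell by 4
  s2 <- holo_spectrum(mkep(matrix(2 * x, 1)), grid = g, config = cfg)
  nz <- s1$values > 1e-12
  expect_equal(s2$values[nz] / s1$values[nz], rep(4, sum(nz)), tolerance = 1e-6)
  # arithmetic mean of cell values {2, 4} is 3
  sa <- s1; sa$values[] <- 2
  sb <- s1; sb$values[] <- 4
  mixed <- sa
  mixed$values <- (sa$values + sb$values) / 2
  expect_true(all(mixed$values == 3))
})

test_that("windowed FFT band power uses the clinical bins and obeys Parseval", {
  bp <- fft_band_power(matrix(tone(10), 1), rate = RATE)
  expect_gt(bp[1, "alpha"] / sum(bp), 0.95)
  edges <- attr(bp, "edges")
  expect_equal(edges$delta, c(0.5, 4))
  expect_equal(edges$theta, c(4.5, 8))
  expect_equal(edges$alpha, c(8.5, 12))
  expect_equal(edges$beta, c(12.5, 30))
  expect_equal(edges$gamma, c(30.5, 80))
  # Parseval: all energy inside 0.5-80 Hz -> band sum matches variance to 5%
  x <- tone(3, amp = 2) + tone(10) + tone(25, amp = 1.5)
  bx <- fft_band_power(matrix(x, 1), rate = RATE)
  expect_lt(abs(sum(bx) - var(x)) / var(x), 0.05)
  expect_lte(sum(bx), var(x) * 1.05)
})
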