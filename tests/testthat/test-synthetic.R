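test_that("AM signal matches the closed-form sideband identity", {
  # FFT oracle: [1 + m cos(2pi fam t)] cos(2pi fc t) has sidebands at
  # fc +/- fam with amplitude m/2 of the carrier line
  n <- 8 * RATE
  x <- generate_am_signal(40, 4, 0.5, 8, RATE)
  sp <- Mod(fft(x))[1:(n / 2)] / n * 2
  f <- (0:(n / 2 - 1)) * RATE / n
  carrier <- sp[which(f == 40)]
  lo <- sp[which(f == 36)]; hi <- sp[which(f == 44)]
  expect_equal(carrier, 1, tolerance = 1e-6)
  expect_equal(lo / carrier, 0.25, tolerance = 1e-6)
  expect_equal(hi / carrier, 0.25, tolerance = 1e-6)

  # zero modulation: constant unit envelope, single spectral line
  x0 <- generate_am_signal(40, 4, 0, 8, RATE)
  sp0 <- Mod(fft(x0))[1:(n / 2)] / n * 2
  expect_equal(sp0[which(f == 40)], 1, tolerance = 1e-6)
  expect_lt(max(sp0[f != 40]), 1e-6)
  expect_equal(diff(range((1 + 0 * x0))), 0)

  # duration x rate arithmetic: 7 s at 200 Hz -> 1400 samples
  expect_length(generate_am_signal(30, 3, 0.4, 7, 200), 1400)
})

test_that("aliasing rates are rejected with a Nyquist diagnostic", {
  expect_error(generate_am_signal(120, 4, 0.5, 1, 200), "Nyquist")
  expect_error(generate_am_signal(100, 4, 0.5, 1, 200), "Nyquist")
})

test_that("aperiodic background matches its spectral exponent within 0.3", {
  for (target in c(0.5, 1.0, 1.5)) {
    x <- with_seed(11, aperiodic_noise(40 * RATE, RATE, target))
    sp <- spec.pgram(ts(x, frequency = RATE), plot = FALSE, spans = 11)
    sel <- sp$freq >= 2 & sp$freq <= 80
    slope <- coef(lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel])))[2]
    expect_lt(abs(-slope - target), 0.3)
  }
})

test_that("cohort generation is bitwise deterministic given the spec", {
  spec <- small_cohort_spec(n_per_group = 2, seed = 9)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$recordings[["S001"]]$data, c2$recordings[["S001"]]$data)
  expect_identical(c1$manifest, c2$manifest)
})

test_that("unknown effect group labels are rejected", {
  expect_error(
    cohort_spec(group_sizes = c(A = 2, B = 2),
                group_effects = list(C = mci_like_effects())),
    "unknown group")
})

test_that("a planted AM-power multiplier is recovered by a direct t-test", {
  # group B doubles AM power of the posterior-dominant alpha component
  # (Lf AM, alpha carrier); oracle: two-sample t on that spectrum cell
  eff <- list(B = list(group_effect(c("O1", "O2", "P3", "P4"),
                                    "Lf", "alpha", 2.0)))
  spec <- small_cohort_spec(n_per_group = 10, effects = eff, seed = 21)
  coh <- generate_cohort(spec)
  spectra <- cohort_spectra(coh$recordings, holo = fast_holo(3))
  cellval <- vapply(spectra, function(s) s$values["O1", 1, 5], 0.0)
  grp <- coh$manifest$group
  tt <- t.test(cellval[grp == "B"], cellval[grp == "A"], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("increasing a planted multiplier strictly increases the cell mean", {
  means <- vapply(c(1, 2, 4), function(mult) {
    eff <- if (mult == 1) list() else
      list(B = list(group_effect(c("O1", "O2", "P3", "P4"), "Lf", "alpha", mult)))
    spec <- small_cohort_spec(n_per_group = 3, effects = eff, seed = 33)
    coh <- generate_cohort(spec)
    bsub <- coh$manifest$subject_id[coh$manifest$group == "B"]
    sp <- cohort_spectra(coh$recordings[bsub], holo = fast_holo(5))
    mean(vapply(sp, function(s) s$values["O1", 1, 5], 0.0))
  }, 0.0)
  expect_true(all(diff(means) > 0))
})
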