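test_that("dyadic grid has the published edges with a Nyquist-capped top", {
  g <- band_grid(200)
  expect_equal(g$edges, c(0.5, 1, 2, 4, 8, 16, 32, 100))
  expect_identical(g$names,
                   c("Lf", "delta1", "delta2", "theta", "alpha", "beta", "gamma"))
  expect_equal(g$edges[8], 100)          # min(100, 200/2)
  g160 <- band_grid(160)
  expect_equal(g160$edges[8], 80)        # Nyquist rule caps the gamma band
})

test_that("valid triangle holds 27 cells with 6 Bedrosian-flagged diagonals", {
  g <- band_grid(200)
  expect_equal(nrow(g$cells), 27)
  expect_true(all(g$cells$am <= g$cells$carrier))
  expect_equal(sum(g$cells$bedrosian), 6)
  expect_setequal(unique(g$cells$carrier), 2:7)
})

test_that("band indexing routes edge and out-of-range frequencies correctly", {
  g <- band_grid(200)
  # AM: below the grid floor -> Lf; above the top edge -> NA (leakage)
  expect_equal(holospec:::am_band_index(g, c(0.2, 0.7, 1, 4, 99, 101)),
               c(1L, 1L, 2L, 4L, 7L, NA))
  # carrier: Lf and out-of-range frequencies don't qualify
  expect_equal(holospec:::carrier_band_index(g, c(0.7, 1.5, 4, 40, 101)),
               c(NA, 2L, 4L, 7L, NA))
})
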