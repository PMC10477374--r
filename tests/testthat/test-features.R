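test_that("signature extraction enumerates channel x valid-cell combinations", {
  g <- band_grid(RATE)
  hs <- spectrum_from_values(abs(rnorm(19 * 49)), SCALP_1020, g)
  sig <- build_signatures(hs)
  expect_equal(nrow(sig), 513)            # 19 x 27
  expect_true(all(match(sig$am_band, g$names) <= match(sig$carrier_band, g$names)))
  one <- build_signatures(spectrum_from_values(abs(rnorm(49)), "O1", g))
  expect_equal(nrow(one), 27)
  expect_error(
    build_signatures(spectrum_from_values(abs(rnorm(49)), "XX", g)),
    "missing from montage")
})

test_that("ordered ratio descriptors satisfy the n(n-1) identity", {
  for (n in c(2, 10, 513)) {
    ids <- sprintf("s%03d", seq_len(n))
    rd <- build_ratio_features(ids, include_singles = FALSE)
    expect_equal(nrow(rd), n * (n - 1))
    expect_false(any(rd$numerator == rd$denominator))
  }
  withs <- build_ratio_features(c("a", "b"), include_singles = TRUE)
  expect_equal(table(withs$kind)[["single"]], 2)
  expect_equal(table(withs$kind)[["ratio"]], 2)
})

test_that("feature evaluation floors ratio denominators at epsilon", {
  g <- band_grid(RATE)
  v <- abs(rnorm(49)) + 0.5
  s1 <- spectrum_from_values(v, "O1", g)
  s2 <- spectrum_from_values(v * 0, "O1", g)   # zero spectrum
  desc <- build_ratio_features(build_signatures(s1), include_singles = TRUE)
  X <- compute_feature_matrix(list(s1, s2), desc, eps = 1e-12)
  expect_true(all(is.finite(X)))
  expect_equal(ncol(X), 27 + 27 * 26)
  expect_true(length(attr(X, "clamped")) > 0)
})

test_that("correlation pruning is greedy, deterministic and idempotent", {
  set.seed(3)
  base <- rnorm(30)
  X <- cbind(f1 = base,
             f2 = base + rnorm(30, sd = 0.01),
             f3 = base + rnorm(30, sd = 0.01),
             f4 = rnorm(30), f5 = rnorm(30))
  dc <- decorrelate(X, 0.95)
  expect_equal(dc$keep, c(1, 4, 5))       # columns 2,3 pruned against 1
  expect_identical(decorrelate(dc$X, 0.95)$X, dc$X)
  # brute-force oracle: every retained pair is below the threshold
  R <- abs(cor(dc$X))
  expect_true(all(R[upper.tri(R)] <= 0.95))

  # exact duplicate: one copy retained
  Xd <- cbind(a = base, b = base, c = rnorm(30))
  expect_equal(decorrelate(Xd, 0.95)$keep, c(1, 3))
  # r_max = 1: only exact duplicates removed
  expect_equal(decorrelate(X, 1.0)$keep, 1:5)
  expect_equal(decorrelate(Xd, 1.0)$keep, c(1, 3))
  expect_error(decorrelate(matrix(1, 5, 3)), "constant")
})

test_that("subset boosting ranks a planted informative feature first", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    n <- 40
    X <- matrix(rnorm(n * 100), n)
    y <- rep(c(0, 1), each = n / 2)
    X[, 63] <- rnorm(n, mean = 2 * y)      # Cohen's d = 2
    sel <- boost_rank_select(X, y, subset_size = 100, max_selected = 5,
                             rounds = 20)
    if (sel[1] == 63) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("small tables and duplicated winners follow the selection contract", {
  set.seed(9)
  n <- 30
  X <- matrix(rnorm(n * 20), n)
  y <- rep(c(0, 1), each = n / 2)
  X[, 7] <- rnorm(n, mean = 2 * y)
  # fewer features than the subset size: single subset = direct ranking
  sel_small <- boost_rank_select(X, y, subset_size = 100, max_selected = 3,
                                 rounds = 20)
  direct <- logitboost_train(X, y, rounds = 20)
  expect_equal(sel_small[1], which.max(direct$importance))
  # two identical planted features: exactly one selected (first column wins)
  X2 <- cbind(X, X[, 7])
  sel2 <- boost_rank_select(X2, y, subset_size = 100, max_selected = 5,
                            rounds = 20)
  expect_true(7 %in% sel2)
  expect_false(21 %in% sel2)
  # max_selected >= features: everything returned with a warning
  expect_warning(all3 <- boost_rank_select(X[, 1:3], y, max_selected = 10,
                                           rounds = 5), "all")
  expect_equal(sort(as.integer(all3)), 1:3)
})
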