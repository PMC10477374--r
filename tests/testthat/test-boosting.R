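test_that("boosting separates linearly separable data within 20 rounds", {
  set.seed(1)
  X <- matrix(c(rnorm(20, -2), rnorm(20, 2)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  for (fit in list(logitboost_train(X, y, rounds = 20),
                   gentleboost_train(X, y, rounds = 20))) {
    expect_equal(mean(predict(fit, X, type = "class") == y), 1.0)
  }
})

test_that("training loss is non-increasing round by round", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60)
  y <- as.integer(X[, 2] + rnorm(60, sd = 0.8) > 0)
  lf <- logitboost_train(X, y, rounds = 40)
  gf <- gentleboost_train(X, y, rounds = 40)
  expect_true(all(diff(lf$loss_trace) <= 1e-10))
  expect_true(all(diff(gf$loss_trace) <= 1e-10))
})

test_that("held-out error approaches the known Bayes rate", {
  # two-feature generating model with axis-aligned Bayes rule [x1 > 0.5] and a
  # nuisance feature; labels flipped with p = 0.1, so the Bayes error is 0.1
  gen <- function(n, seed) with_seed(seed, {
    x <- matrix(runif(2 * n), n)
    y <- as.integer(x[, 1] > 0.5)
    flip <- runif(n) < 0.1
    y[flip] <- 1 - y[flip]
    list(x = x, y = y)
  })
  tr <- gen(400, 31); te <- gen(400, 32)
  for (fit in list(logitboost_train(tr$x, tr$y, rounds = 60),
                   gentleboost_train(tr$x, tr$y, rounds = 60))) {
    err <- mean(predict(fit, te$x, type = "class") != te$y)
    expect_lte(err, 0.15)
  }
})

test_that("an empty ensemble predicts the training prior", {
  set.seed(3)
  X <- matrix(rnorm(30), ncol = 1)
  y <- c(rep(0, 10), rep(1, 20))
  f0 <- logitboost_train(X, y, rounds = 0)
  expect_equal(unique(predict(f0, X, type = "prob")), 2 / 3)
  expect_equal(unique(predict(f0, X, type = "class")), 1L)
  g0 <- gentleboost_train(X, y, rounds = 0)
  expect_equal(unique(predict(g0, X, type = "prob")), 2 / 3)
})

test_that("single-class labels are rejected", {
  X <- matrix(rnorm(20), ncol = 1)
  expect_error(logitboost_train(X, rep(1, 20)), "both classes")
  expect_error(gentleboost_train(X, rep(0, 20)), "both classes")
})
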