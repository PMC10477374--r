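test_that("metric panel reproduces the clinical worked example", {
  m <- metrics(14, 3, 16, 4)
  expect_equal(unname(m$rounded),
               c(0.82, 0.80, 0.78, 0.80, 0.81))
  # self-consistency: metrics recomputable from the stored confusion counts
  cc <- m$confusion
  expect_equal(m$raw[["sensitivity"]], cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]))
  expect_equal(m$raw[["accuracy"]], (cc[["TP"]] + cc[["TN"]]) / sum(cc))
})

test_that("degenerate confusion matrices give NA, 1.0 or 0 as appropriate", {
  perfect <- metrics(10, 0, 10, 0)
  expect_true(all(perfect$raw == 1))
  allneg <- metrics(0, 10, 10, 0)
  expect_equal(unname(allneg$raw[["sensitivity"]]), 0)
  expect_equal(unname(allneg$raw[["specificity"]]), 1)
  expect_true(is.na(allneg$raw[["precision"]]))   # undefined, not 0
})

test_that("cross-validation partitions subjects exactly once", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40)
  y <- rep(c(0, 1), 20)
  rep1 <- crossval_evaluate(X, y, algorithms = "logitboost", k = 10, seed = 2,
                            rounds = 10)
  expect_equal(sort(unique(rep1$folds)), 1:10)
  expect_equal(as.vector(table(rep1$folds)), rep(4, 10))
  # deterministic rerun
  rep2 <- crossval_evaluate(X, y, algorithms = "logitboost", k = 10, seed = 2,
                            rounds = 10)
  expect_identical(rep1$results$logitboost$scores, rep2$results$logitboost$scores)
})

test_that("a separable cohort yields near-perfect AUC for boosting", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 3), 20))
  y <- factor(rep(c("CN", "MCI"), each = 20), levels = c("CN", "MCI"))
  rep7 <- crossval_evaluate(X, y, algorithms = c("logitboost", "gentleboost"),
                            k = 10, seed = 6, rounds = 30)
  expect_gt(rep7$results$logitboost$auc, 0.95)
  expect_gt(rep7$results$gentleboost$auc, 0.95)
})

test_that("permuted labels give chance-level AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 3), 20))
    y <- sample(rep(c(0, 1), each = 20))
    crossval_evaluate(X, y, algorithms = "logitboost", k = 5, seed = s,
                      rounds = 10)$results$logitboost$auc
  }, 0.0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("all seven panel algorithms produce consistent reports", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 2.5), 20))
  y <- rep(c(0, 1), each = 20)
  rep7 <- crossval_evaluate(X, y, k = 5, seed = 8, rounds = 20)
  expect_setequal(names(rep7$results), classifier_panel())
  for (r in rep7$results) {
    ok <- !is.na(r$metrics$raw)
    expect_true(all(r$metrics$raw[ok] >= 0 & r$metrics$raw[ok] <= 1))
    expect_equal(sum(r$confusion), 40)
    m2 <- metrics(r$confusion[["TP"]], r$confusion[["FN"]],
                  r$confusion[["TN"]], r$confusion[["FP"]])
    expect_equal(m2$raw, r$metrics$raw)
  }
})

test_that("cumulative conversion percentages follow the printed arithmetic", {
  ct <- conversion_table(c(rep(1, 6), rep(2, 7), rep(3, 3)), n_total = 36)
  expect_equal(ct$n_converted, c(6, 13, 16))
  expect_equal(ct$percent, c(16.7, 36.1, 44.4))
  expect_error(conversion_table(integer(0), 36) -> x, NA)
  expect_equal(conversion_table(integer(0), 36)$percent, c(0, 0, 0))
})
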