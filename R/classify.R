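#' Performance metrics from a confusion matrix
#'
#' @param tp,fn,tn,fp Confusion counts: true/false positives and negatives,
#'   with the patient group as the positive class.
#' @param digits Rounding for the display panel (default 2, matching clinical
#'   reporting practice); raw values are kept alongside.
#' @return List with `raw` and `rounded` named vectors of sensitivity,
#'   specificity, precision, F1 and accuracy. Undefined ratios (zero
#'   denominators) are `NA`, not 0.
#' @export
metrics <- function(tp, fn, tn, fp, digits = 2) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  acc <- (tp + tn) / (tp + fn + tn + fp)
  raw <- c(sensitivity = sens, specificity = spec, precision = prec,
           f1 = f1, accuracy = acc)
  list(raw = raw, rounded = round(raw, digits),
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' The seven-classifier panel
#' @return Character vector of the algorithm names accepted by
#'   [crossval_evaluate()].
#' @export
classifier_panel <- function() {
  c("logitboost", "bag", "gentleboost", "tree", "svm", "nbayes", "knn")
}

# train on (X, y01) and return positive-class scores for Xt.
# The two boosting variants are this package's own implementations; the
# remaining five go through established libraries behind this interface.
fit_and_score <- function(alg, X, y01, Xt, seed, rounds = 50) {
  yf <- factor(y01, levels = c(0, 1))
  switch(alg,
    logitboost = predict(logitboost_train(X, y01, rounds = rounds), Xt, type = "prob"),
    gentleboost = predict(gentleboost_train(X, y01, rounds = rounds), Xt, type = "prob"),
    tree = {
      d <- data.frame(y = yf, X)
      fit <- rpart::rpart(y ~ ., data = d,
                          method = "class",
                          control = rpart::rpart.control(minsplit = 5, cp = 0.01,
                                                         xval = 0))
      predict(fit, data.frame(Xt), type = "prob")[, "1"]
    },
    bag = {
      d <- data.frame(y = yf, X)
      nd <- data.frame(Xt)
      B <- 50
      i0 <- which(y01 == 0); i1 <- which(y01 == 1)
      probs <- with_seed(seed, {
        # stratified bootstrap so every resample carries both classes
        rowMeans(vapply(seq_len(B), function(b) {
          ix <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
          fit <- rpart::rpart(y ~ ., data = d[ix, ], method = "class",
                              control = rpart::rpart.control(minsplit = 5,
                                                             cp = 0.01, xval = 0))
          predict(fit, nd, type = "prob")[, "1"]
        }, numeric(nrow(nd))))
      })
      probs
    },
    svm = {
      sc <- scale(X)
      ctr <- attr(sc, "scaled:center"); scl <- attr(sc, "scaled:scale")
      scl[scl == 0] <- 1
      fit <- with_seed(seed, e1071::svm(sc, yf, kernel = "radial",
                                        probability = TRUE))
      tt <- scale(Xt, center = ctr, scale = scl)
      attr(predict(fit, tt, probability = TRUE), "probabilities")[, "1"]
    },
    nbayes = {
      fit <- e1071::naiveBayes(X, yf)
      predict(fit, Xt, type = "raw")[, "1"]
    },
    knn = {
      sc <- scale(X)
      ctr <- attr(sc, "scaled:center"); scl <- attr(sc, "scaled:scale")
      scl[scl == 0] <- 1
      tt <- scale(Xt, center = ctr, scale = scl)
      kk <- min(5L, nrow(sc) - 1L)
      pr <- with_seed(seed, class::knn(sc, tt, cl = yf, k = kk, prob = TRUE))
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    stop("unknown algorithm: ", alg))
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(y01, k, seed) {
  fold <- integer(length(y01))
  with_seed(seed, {
    for (cls in unique(y01)) {
      ix <- which(y01 == cls)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

#' Cross-validated evaluation of the classifier panel
#'
#' Stratified k-fold cross-validation; out-of-fold positive-class scores are
#' pooled into one confusion matrix (at probability 0.5) and one ROC curve per
#' algorithm. Deterministic given `seed`.
#'
#' @param X Subjects x features matrix.
#' @param y Binary labels; factor (second level = positive/patient class),
#'   logical, or 0/1.
#' @param algorithms Subset of [classifier_panel()] (default: all seven).
#' @param k Folds (default 10, capped at the smaller class size).
#' @param seed Integer seed for fold assignment and any resampling-based
#'   learner.
#' @param rounds Boosting rounds (default 50).
#' @return A `classifier_report`: per-algorithm list with `confusion`,
#'   `metrics` (see [metrics()]), `auc`, `roc` (data frame FPR/TPR), `scores`;
#'   plus `folds`, `labels` and `seed`.
#' @export
crossval_evaluate <- function(X, y, algorithms = classifier_panel(), k = 10,
                              seed = 1, rounds = 50) {
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  stopifnot(nrow(X) == length(y01))
  if (min(table(y01)) < 2) stop("need at least 2 subjects per class")
  k <- min(k, min(table(y01)))
  algorithms <- match.arg(algorithms, classifier_panel(), several.ok = TRUE)
  fold <- stratified_folds(y01, k, seed)
  results <- list()
  for (alg in algorithms) {
    scores <- numeric(length(y01))
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y01[tr])) < 2)
        stop("a training fold lost one class; reduce k")
      scores[te] <- fit_and_score(alg, X[tr, , drop = FALSE], y01[tr],
                                  X[te, , drop = FALSE], seed = seed + f,
                                  rounds = rounds)
    }
    pred <- as.integer(scores >= 0.5)
    tp <- sum(pred == 1 & y01 == 1); fn <- sum(pred == 0 & y01 == 1)
    tn <- sum(pred == 0 & y01 == 0); fp <- sum(pred == 1 & y01 == 0)
    roc <- pROC::roc(response = y01, predictor = scores, levels = c(0, 1),
                     direction = "<", quiet = TRUE)
    results[[alg]] <- list(
      confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
      metrics = metrics(tp, fn, tn, fp),
      auc = as.numeric(pROC::auc(roc)),
      roc = data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities),
      scores = scores)
  }
  structure(list(results = results, folds = fold, labels = y01, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  tab <- do.call(rbind, lapply(names(x$results), function(a) {
    r <- x$results[[a]]
    data.frame(algorithm = a, t(r$metrics$rounded), auc = round(r$auc, 3))
  }))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Cumulative conversion table for a longitudinal follow-up
#'
#' Yearly cumulative conversion percentages among the converted subgroup,
#' reported to one decimal as `converters so far / total at risk`.
#'
#' @param conversion_year Integer year of conversion (1-based) per converted
#'   subject.
#' @param n_total Total subjects at risk in the converted subgroup.
#' @param horizon Follow-up horizon in years (default 3).
#' @return Data frame: `year`, `n_converted` (cumulative), `percent`
#'   (one decimal).
#' @export
conversion_table <- function(conversion_year, n_total, horizon = 3) {
  stopifnot(all(conversion_year >= 1), n_total >= length(conversion_year))
  data.frame(
    year = seq_len(horizon),
    n_converted = vapply(seq_len(horizon),
                         function(yr) sum(conversion_year <= yr), 0L),
    percent = vapply(seq_len(horizon), function(yr)
      round(100 * sum(conversion_year <= yr) / n_total, 1), 0.0))
}
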