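# Weighted least-squares decision stump: f(x) = left if x[, feature] <= split
# else right, minimizing the weighted squared error to the working response.
# Ties broken by column order, then by lower split index.
fit_stump <- function(X, z, w) {
  n <- nrow(X)
  sw <- sum(w); swz <- sum(w * z)
  best <- list(gain = -Inf)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    o <- order(x)
    xo <- x[o]; wo <- w[o]; zo <- z[o]
    cw <- cumsum(wo); cwz <- cumsum(wo * zo)
    valid <- which(xo[-n] < xo[-1])          # split between distinct values
    if (!length(valid)) next
    wl <- cw[valid]; wr <- sw - wl
    zl <- cwz[valid]; zr <- swz - zl
    gain <- zl^2 / wl + zr^2 / wr
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      s <- (xo[valid[b]] + xo[valid[b] + 1]) / 2
      best <- list(gain = gain[b], feature = j, split = s,
                   left = zl[b] / wl[b], right = zr[b] / wr[b])
    }
  }
  if (!is.finite(best$gain)) {               # all features constant
    best <- list(gain = 0, feature = 1L, split = Inf,
                 left = swz / sw, right = swz / sw)
  }
  best
}

stump_predict <- function(stump, X) {
  ifelse(X[, stump$feature] <= stump$split, stump$left, stump$right)
}

#' LogitBoost with decision stumps
#'
#' Stagewise Newton fitting of the binomial log-likelihood: at each round the
#' working response `z = (y - p) / (p(1-p))` is fitted by a weighted
#' least-squares stump with weights `p(1-p)`, the additive score grows by half
#' the stump output, and probabilities come from the logistic link
#' `p = 1 / (1 + exp(-2F))`. Deterministic. Per-feature importance is the
#' training log-loss reduction summed over the rounds in which the feature's
#' stump was chosen.
#'
#' @param X Subjects x features numeric matrix.
#' @param y Binary labels: logical, 0/1, or a two-level factor (second level
#'   is the positive class).
#' @param rounds Boosting rounds (default 50). Zero rounds gives a
#'   prior-probability model.
#' @param z_max Working-response clip (default 4, the customary guard).
#' @return A `boost_model` (type `"logitboost"`).
#' @export
logitboost_train <- function(X, y, rounds = 50, z_max = 4) {
  X <- as.matrix(X)
  y <- as_binary01(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  Fv <- numeric(n); p <- rep(0.5, n)
  stumps <- vector("list", rounds)
  importance <- numeric(ncol(X))
  loglo <- function(p) -mean(y * log(pmax(p, 1e-12)) +
                             (1 - y) * log(pmax(1 - p, 1e-12)))
  loss <- loglo(p)
  trace <- loss
  for (m in seq_len(rounds)) {
    w <- pmax(p * (1 - p), 1e-10)
    z <- pmin(pmax((y - p) / w, -z_max), z_max)
    st <- fit_stump(X, z, w)
    f <- stump_predict(st, X)
    # safeguarded Newton step: halve the contribution until the training
    # log-loss does not increase (clipping of z can overshoot otherwise)
    scale <- 1
    repeat {
      p_new <- 1 / (1 + exp(-2 * (Fv + 0.5 * scale * f)))
      new_loss <- loglo(p_new)
      if (new_loss <= loss + 1e-12 || scale < 1e-3) break
      scale <- scale / 2
    }
    if (new_loss > loss + 1e-12) { scale <- 0; p_new <- p; new_loss <- loss }
    st$left <- st$left * scale; st$right <- st$right * scale
    stumps[[m]] <- st
    Fv <- Fv + 0.5 * scale * f
    p <- p_new
    importance[st$feature] <- importance[st$feature] + max(loss - new_loss, 0)
    loss <- new_loss
    trace <- c(trace, loss)
  }
  new_boost_model("logitboost", stumps[seq_len(rounds)], importance,
                  prior = mean(y), loss_trace = trace)
}

#' GentleBoost with decision stumps
#'
#' Gentle adaptive boosting: each round fits a weighted least-squares stump to
#' labels in `{-1, +1}` under exponential-loss weights, adds the stump output
#' to the score, and reweights by `exp(-y * f)`. Deterministic. Importance is
#' the training exponential-loss reduction attributed to the chosen feature.
#'
#' @inheritParams logitboost_train
#' @return A `boost_model` (type `"gentleboost"`).
#' @export
gentleboost_train <- function(X, y, rounds = 50) {
  X <- as.matrix(X)
  y01 <- as_binary01(y)
  ys <- 2 * y01 - 1
  if (length(unique(ys)) < 2) stop("both classes must be present")
  n <- nrow(X)
  w <- rep(1 / n, n)
  Fv <- numeric(n)
  stumps <- vector("list", rounds)
  importance <- numeric(ncol(X))
  loss <- mean(exp(-ys * Fv))
  trace <- loss
  for (m in seq_len(rounds)) {
    st <- fit_stump(X, ys, w)
    f <- stump_predict(st, X)
    # safeguarded step, as in LogitBoost: the finite-sample least-squares
    # stump can overshoot the exponential loss
    scale <- 1
    repeat {
      new_loss <- mean(exp(-ys * (Fv + scale * f)))
      if (new_loss <= loss + 1e-12 || scale < 1e-3) break
      scale <- scale / 2
    }
    if (new_loss > loss + 1e-12) { scale <- 0; new_loss <- loss }
    st$left <- st$left * scale; st$right <- st$right * scale
    stumps[[m]] <- st
    Fv <- Fv + scale * f
    w <- exp(-ys * Fv)
    w <- w / sum(w)
    importance[st$feature] <- importance[st$feature] + max(loss - new_loss, 0)
    loss <- new_loss
    trace <- c(trace, loss)
  }
  new_boost_model("gentleboost", stumps[seq_len(rounds)], importance,
                  prior = mean(y01), loss_trace = trace)
}

new_boost_model <- function(type, stumps, importance, prior, loss_trace) {
  structure(list(type = type, stumps = stumps, importance = importance,
                 prior = prior, loss_trace = loss_trace),
            class = "boost_model")
}

as_binary01 <- function(y) {
  if (is.factor(y)) as.integer(y == levels(y)[2])
  else if (is.logical(y)) as.integer(y)
  else { stopifnot(all(y %in% c(0, 1))); as.integer(y) }
}

#' Predict from a boosted stump model
#'
#' @param object A `boost_model`.
#' @param newdata Subjects x features matrix (same columns as training).
#' @param type `"prob"` (positive-class probability), `"score"` (additive
#'   score F) or `"class"` (0/1 at probability 0.5).
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.boost_model <- function(object, newdata, type = c("prob", "score", "class"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  Fv <- numeric(nrow(newdata))
  half <- if (object$type == "logitboost") 0.5 else 1
  for (st in object$stumps) Fv <- Fv + half * stump_predict(st, newdata)
  if (length(object$stumps) == 0)          # empty ensemble: prior model
    return(switch(type,
                  score = Fv,
                  prob = rep(object$prior, nrow(newdata)),
                  class = rep(as.integer(object$prior >= 0.5), nrow(newdata))))
  p <- 1 / (1 + exp(-2 * Fv))
  switch(type, score = Fv, prob = p, class = as.integer(p >= 0.5))
}

#' @export
print.boost_model <- function(x, ...) {
  cat(x$type, "model:", length(x$stumps), "stumps;",
      sum(x$importance > 0), "features used\n")
  invisible(x)
}
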