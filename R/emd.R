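#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the mean of the upper and lower cubic-spline envelopes
#' (fitted through local maxima and minima, with mirror extension of the
#' extrema at both ends) until the candidate satisfies the two IMF defining
#' properties: extrema and zero-crossing counts differ by at most one, and the
#' local envelope mean is approximately zero. Stopping follows the S-number
#' rule: counts unchanged for `s_number` consecutive sifts, with a hard cap of
#' `max_sift` iterations.
#'
#' @param x Numeric signal.
#' @param s_number Consecutive-sift stability requirement (default 4).
#' @param max_sift Hard iteration cap (default 50).
#' @return A list with `imf` (the extracted mode, or `NULL` when the signal
#'   has fewer than 4 extrema and is treated as a residue/trend), `remainder`
#'   (`x - imf`) and `siftable` (logical).
#' @export
sift <- function(x, s_number = 4, max_sift = 50) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  res <- .sift_c(as.double(x), as.integer(s_number), as.integer(max_sift))
  if (!res$siftable)
    return(list(imf = NULL, remainder = x, siftable = FALSE))
  list(imf = res$imf, remainder = x - res$imf, siftable = TRUE)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterated
#' sifting; each extracted IMF is subtracted and sifting continues on the
#' remainder until it has fewer than 4 extrema or the maximum mode count
#' (dyadic filter-bank depth, `floor(log2(n)) - 1`) is reached. The IMFs plus
#' residue reconstruct the input exactly up to floating-point round-off.
#'
#' @param x Numeric signal, length at least 32, all finite.
#' @param max_imf Maximum number of modes; default `floor(log2(length(x))) - 1`.
#' @param s_number,max_sift Sifting stop parameters, see [sift()].
#' @return An `imf_set`: list with `imfs` (samples x modes matrix, mode 1 the
#'   fastest), `residue` and `source_length`.
#' @export
emd <- function(x, max_imf = NULL, s_number = 4, max_sift = 50) {
  stopifnot(is.numeric(x), length(x) >= 32)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  max_imf <- max_imf %||% max(1L, floor(log2(length(x))) - 1L)
  res <- .emd_c(as.double(x), as.integer(max_imf),
                as.integer(s_number), as.integer(max_sift))
  new_imf_set(res$imfs, res$residue, length(x))
}

new_imf_set <- function(imfs, residue, n) {
  structure(list(imfs = imfs, residue = residue, source_length = n),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("imf_set:", ncol(x$imfs), "modes over", x$source_length, "samples\n")
  invisible(x)
}

#' Reconstruct the original signal from an `imf_set`
#' @param x An `imf_set`.
#' @return Numeric vector: row sums of the IMFs plus the residue.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  if (ncol(x$imfs) == 0) return(x$residue)
  rowSums(x$imfs) + x$residue
}

#' Improved complete ensemble EMD with adaptive noise (iCEEMDAN)
#'
#' Noise-assisted EMD with reduced mode mixing and residual noise: at each
#' stage the k-th EMD mode of every white-noise realization, scaled to a
#' fraction `noise_sd` of the current residual's standard deviation, is added
#' before estimating the local mean, and the stage IMF is the difference of
#' successive ensemble-averaged local means. With `ensemble_size = 1` and
#' `noise_sd = 0` the result equals plain [emd()] elementwise.
#'
#' The decomposed noise ensemble depends only on (length, ensemble size, seed,
#' sift settings) and is cached across calls, so decomposing many epochs of
#' equal length reuses it.
#'
#' @param x Numeric signal.
#' @param ensemble_size Number of noise realizations (default 100).
#' @param noise_sd Noise amplitude as a fraction of the residual's standard
#'   deviation (default 0.2).
#' @param seed Integer seed for the noise ensemble; the decomposition is fully
#'   deterministic given the seed.
#' @param max_imf,s_number,max_sift As in [emd()].
#' @return An `imf_set`.
#' @export
iceemdan <- function(x, ensemble_size = 100, noise_sd = 0.2, seed = 1,
                     max_imf = NULL, s_number = 4, max_sift = 50) {
  stopifnot(is.numeric(x), length(x) >= 32, ensemble_size >= 1, noise_sd >= 0)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  max_imf <- max_imf %||% max(1L, floor(log2(n)) - 1L)
  if (noise_sd == 0 || sd(x) == 0)
    return(emd(x, max_imf = max_imf, s_number = s_number, max_sift = max_sift))

  W <- noise_mode_ensemble(n, ensemble_size, seed, max_imf, s_number, max_sift)

  local_mean <- function(y) {
    s <- .sift_c(y, as.integer(s_number), as.integer(max_sift))
    if (!s$siftable) y else y - s$imf
  }
  nsift <- function(y) {  # number of extrema, for the residue stop rule
    e <- .extrema_c(y)
    length(e$maxima) + length(e$minima)
  }

  imfs <- matrix(0.0, n, 0)
  # stage 1: noise scaled relative to its own first mode, per the method
  acc <- numeric(n)
  for (i in seq_len(ensemble_size)) {
    w1 <- W$modes[[i]][, 1]
    acc <- acc + local_mean(x + noise_sd * sd(x) / sd(w1) * w1)
  }
  r <- acc / ensemble_size
  imfs <- cbind(imfs, x - r)
  k <- 2L
  while (k <= max_imf && nsift(r) >= 4 && sd(r) > 0) {
    beta <- noise_sd * sd(r)
    acc <- numeric(n)
    for (i in seq_len(ensemble_size)) {
      Wi <- W$modes[[i]]
      y <- if (ncol(Wi) >= k) r + beta * Wi[, k] / sd(Wi[, k]) else r
      acc <- acc + local_mean(y)
    }
    rn <- acc / ensemble_size
    d <- r - rn
    if (sd(d) == 0) break
    imfs <- cbind(imfs, d)
    r <- rn
    k <- k + 1L
  }
  new_imf_set(imfs, r, n)
}

# Decompose `ensemble_size` unit-variance white-noise realizations once and
# cache the mode matrices (keyed on everything that determines them).
noise_mode_ensemble <- function(n, ensemble_size, seed, max_imf, s_number, max_sift) {
  key <- paste(n, ensemble_size, seed, max_imf, s_number, max_sift, sep = "|")
  hit <- .holospec_cache[[key]]
  if (!is.null(hit)) return(hit)
  noise <- with_seed(seed, matrix(rnorm(n * ensemble_size), n, ensemble_size))
  modes <- lapply(seq_len(ensemble_size), function(i) {
    m <- .emd_c(noise[, i], as.integer(max_imf),
                as.integer(s_number), as.integer(max_sift))$imfs
    if (ncol(m) == 0) m <- matrix(noise[, i], n, 1)
    m
  })
  out <- list(modes = modes)
  .holospec_cache[[key]] <- out
  out
}

#' Ensemble EMD (EEMD) baseline
#'
#' Classic ensemble averaging: EMD of `x` plus independent white noise, modes
#' averaged by index. Unlike [iceemdan()], the averaged modes do not sum back
#' to the input, so its reconstruction error is a useful comparison baseline.
#'
#' @inheritParams iceemdan
#' @return An `imf_set` (approximate reconstruction).
#' @export
eemd <- function(x, ensemble_size = 100, noise_sd = 0.2, seed = 1,
                 max_imf = NULL, s_number = 4, max_sift = 50) {
  stopifnot(is.numeric(x), length(x) >= 32, ensemble_size >= 1)
  n <- length(x)
  max_imf <- max_imf %||% max(1L, floor(log2(n)) - 1L)
  noise <- with_seed(seed, matrix(rnorm(n * ensemble_size), n, ensemble_size))
  amp <- noise_sd * sd(x)
  acc <- matrix(0.0, n, max_imf)
  res <- numeric(n)
  kmax <- 0L
  for (i in seq_len(ensemble_size)) {
    d <- .emd_c(x + amp * noise[, i], as.integer(max_imf),
                as.integer(s_number), as.integer(max_sift))
    K <- ncol(d$imfs)
    if (K > 0) acc[, seq_len(K)] <- acc[, seq_len(K)] + d$imfs
    # modes beyond K stay in the residue for this member
    res <- res + d$residue
    kmax <- max(kmax, K)
  }
  new_imf_set(acc[, seq_len(kmax), drop = FALSE] / ensemble_size,
              res / ensemble_size, n)
}

#' Amplitude envelope of an IMF
#'
#' Cubic spline fitted through the local maxima of the absolute-valued signal,
#' with mirror extension at the ends; the envelope interpolates `|x|` exactly
#' at the maxima used. With fewer than 2 maxima of `|x|` a constant envelope
#' equal to `max(|x|)` is returned with a warning.
#'
#' @param x Numeric signal (typically one IMF).
#' @return Non-negative numeric vector of the same length.
#' @export
envelope <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  env <- .envelope_c(as.double(x))
  if (is.null(env)) {
    warning("fewer than 2 maxima of |x|; returning constant envelope")
    return(rep(max(abs(x)), length(x)))
  }
  pmax(env, 0)
}

# Amplitude envelope with parabolic sub-sample peak refinement: each sampled
# maximum of |x| is replaced by the vertex of the parabola through its three
# neighbouring samples, correcting the systematic undershoot when the carrier
# is sampled coarsely. Used by the spectral power-accounting paths; the
# exported envelope() keeps the exact-interpolation contract instead.
envelope_refined <- function(x) {
  n <- length(x)
  ax <- abs(x)
  mx <- .extrema_c(ax)$maxima
  if (length(mx) < 2) return(rep(max(ax), n))
  t <- as.numeric(mx - 1)
  y <- ax[mx]
  inner <- mx > 1 & mx < n
  i <- mx[inner]
  y0 <- ax[i - 1]; y1 <- ax[i]; y2 <- ax[i + 1]
  den <- y0 - 2 * y1 + y2
  ok <- den < 0
  dt <- ifelse(ok, 0.5 * (y0 - y2) / den, 0)
  dt <- pmin(pmax(dt, -0.5), 0.5)
  t[inner] <- t[inner] + dt
  y[inner] <- pmax(y1 - 0.25 * (y0 - y2) * dt, y1)
  # mirror two refined peaks about each end
  k <- min(2, length(t))
  tl <- -rev(t[seq_len(k)]); yl <- rev(y[seq_len(k)])
  tr <- 2 * (n - 1) - rev(rev(t)[seq_len(k)]); yr <- rev(rev(y)[seq_len(k)])
  tt <- c(tl, t, tr); yy <- c(yl, y, yr)
  keep <- !duplicated(tt)
  ord <- order(tt[keep])
  ttk <- tt[keep][ord]; yyk <- yy[keep][ord]
  env <- stats::spline(ttk, yyk, xout = 0:(n - 1), method = "natural")$y
  pmax(env, 0)
}

#' Mean frequency of an oscillation by zero-crossing count
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @return Frequency in Hz (`zero crossings / (2 * duration)`).
#' @export
mean_frequency <- function(x, rate) {
  zc <- .extrema_c(as.double(x))$zero_crossings
  zc / (2 * (length(x) / rate))
}

#' Dyadic filter-bank decay factor of a decomposition
#'
#' Mean ratio of successive IMF mean frequencies, the classic diagnostic of
#' EMD's dyadic filter-bank behaviour on broadband input (expected near 2).
#' Only modes carrying at least `min_cycles` oscillation cycles within the
#' record are used: slower modes have too few zero crossings for a stable
#' frequency estimate and are dominated by boundary effects.
#'
#' @param x An `imf_set`.
#' @param rate Sampling rate in Hz.
#' @param min_cycles Minimum number of cycles a mode must contain (default 14).
#' @return Mean of successive mean-frequency ratios, or `NA` when fewer than
#'   two modes qualify.
#' @export
dyadic_ratio <- function(x, rate, min_cycles = 14) {
  stopifnot(inherits(x, "imf_set"))
  f <- apply(x$imfs, 2, mean_frequency, rate = rate)
  dur <- x$source_length / rate
  f <- f[f * dur >= min_cycles]
  if (length(f) < 2) return(NA_real_)
  mean(f[-length(f)] / f[-1])
}

#' Orthogonality index of a decomposition
#'
#' Total cross-mode energy relative to the energy of the reconstructed signal;
#' near-orthogonal decompositions give values close to 0.
#' @param x An `imf_set`.
#' @return A non-negative scalar.
#' @export
orthogonality_index <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  comps <- cbind(x$imfs, x$residue)
  total <- sum(reconstruct(x)^2)
  G <- crossprod(comps)
  sum(abs(G[upper.tri(G)])) * 2 / total
}
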