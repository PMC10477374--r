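#' Configuration for Holo-Hilbert spectral decomposition
#'
#' Collects the tunable parameters of the two-layer decomposition. The
#' ensemble settings apply to both layers; the iCEEMDAN noise amplitude is a
#' fraction of the residual standard deviation. `boundary_frac` of samples at
#' each epoch end is excluded from accumulation (spline end effects).
#'
#' @param ensemble iCEEMDAN ensemble size for both layers (default 16; the
#'   standalone [iceemdan()] default is 100 — spectra average over epochs and
#'   channels, so a lighter ensemble is sufficient and much faster).
#' @param noise_sd iCEEMDAN relative noise amplitude (default 0.2).
#' @param seed Base seed for the noise ensembles.
#' @param boundary_frac Excluded boundary fraction per end (default 0.05).
#' @param s_number,max_sift Sifting stop parameters.
#' @param if_smooth_secs Running-median window (seconds) for
#'   instantaneous-frequency tracks before band assignment (default 0.75:
#'   several cycles of the fastest carriers, below half the slowest AM period
#'   of the grid).
#' @return A list of class `holo_config`.
#' @export
holo_config <- function(ensemble = 16, noise_sd = 0.2, seed = 1,
                        boundary_frac = 0.05, s_number = 4, max_sift = 50,
                        if_smooth_secs = 0.75) {
  stopifnot(ensemble >= 1, noise_sd >= 0, boundary_frac >= 0, boundary_frac < 0.5)
  structure(list(ensemble = ensemble, noise_sd = noise_sd, seed = seed,
                 boundary_frac = boundary_frac, s_number = s_number,
                 max_sift = max_sift, if_smooth_secs = if_smooth_secs),
            class = "holo_config")
}

# Two-layer decomposition of one channel: returns a 7 x 7 (am x carrier)
# power matrix plus leakage diagnostics. Cells above the diagonal
# (am band > carrier band) are accumulated but flagged by the caller's mask.
holo_channel <- function(x, rate, grid, config) {
  nb7 <- grid$n_bands
  acc <- matrix(0.0, nb7, nb7)             # am x carrier
  leak <- 0L; lf_fallback <- 0L; n_acc <- 0L
  n <- length(x)
  nbound <- max(1L, round(config$boundary_frac * n))
  interior <- (nbound + 1):(n - nbound)

  if (sd(x) == 0)
    return(list(power = acc, leakage = 0L, lf_fallback = 0L,
                n_interior = length(interior)))

  l1 <- iceemdan(x, ensemble_size = config$ensemble, noise_sd = config$noise_sd,
                 seed = config$seed, s_number = config$s_number,
                 max_sift = config$max_sift)
  for (i in seq_len(ncol(l1$imfs))) {
    imf <- l1$imfs[, i]
    if (sd(imf) == 0) next
    n_max <- length(.extrema_c(abs(imf))$maxima)
    if (n_max < 2) next                    # no resolvable envelope
    a <- envelope_refined(imf)
    dq1 <- direct_quadrature(imf, rate, env = a,
                             boundary_frac = config$boundary_frac,
                             smooth_secs = config$if_smooth_secs)
    fc_band <- carrier_band_index(grid, dq1$inst_freq)
    ok1 <- dq1$valid & !is.na(fc_band)
    leak <- leak + sum(dq1$valid & is.na(fc_band))

    ext_a <- .extrema_c(a)
    if (length(ext_a$maxima) + length(ext_a$minima) < 4) {
      # constant-envelope limit: no second layer possible; the envelope power
      # is attributed to the lowest AM band
      lf_fallback <- lf_fallback + 1L
      idx <- which(ok1)
      idx <- idx[idx %in% interior]
      if (length(idx)) {
        tab <- tapply(a[idx]^2, fc_band[idx], sum)
        ci <- as.integer(names(tab))
        acc[1L, ci] <- acc[1L, ci] + as.numeric(tab)
      }
      next
    }
    l2 <- iceemdan(a, ensemble_size = config$ensemble, noise_sd = config$noise_sd,
                   seed = config$seed + 1L, s_number = config$s_number,
                   max_sift = config$max_sift)
    # the layer-2 residue (the envelope's non-oscillatory level) is carrier
    # strength, not amplitude modulation; it is not accumulated
    for (j in seq_len(ncol(l2$imfs))) {
      d <- l2$imfs[, j]
      if (sd(d) == 0) next
      if (length(.extrema_c(abs(d))$maxima) < 2) next
      b <- envelope_refined(d)
      dq2 <- direct_quadrature(d, rate, env = b,
                               boundary_frac = config$boundary_frac,
                               smooth_secs = config$if_smooth_secs)
      am_band <- am_band_index(grid, dq2$inst_freq)
      ok <- ok1 & dq2$valid & !is.na(am_band)
      leak <- leak + sum(ok1 & dq2$valid & is.na(am_band))
      idx <- which(ok)
      idx <- idx[idx %in% interior]
      if (length(idx)) {
        cell <- am_band[idx] + nb7 * (fc_band[idx] - 1L)
        tab <- tapply(b[idx]^2, cell, sum)
        ci <- as.integer(names(tab))
        acc[ci] <- acc[ci] + as.numeric(tab)
      }
    }
  }
  list(power = acc, leakage = leak, lf_fallback = lf_fallback,
       n_interior = length(interior))
}

#' Holo-Hilbert spectrum of one epoch
#'
#' Two-layer empirical mode decomposition per channel: layer-1 iCEEMDAN yields
#' carrier IMFs with amplitude envelopes and instantaneous carrier frequencies
#' (direct quadrature); layer-2 iCEEMDAN of each envelope yields
#' amplitude-modulation components whose own squared amplitudes are
#' accumulated, sample by sample, into the (AM band, carrier band) cell of the
#' dyadic grid, then time-marginalized (divided by the interior sample count).
#' Cells with AM band above the carrier band are accumulated but masked;
#' diagonal cells carry the Bedrosian reliability flag.
#'
#' @param epoch An `epoch` object (see [epoch_signal()]), or a channels x
#'   samples matrix.
#' @param grid A [band_grid()].
#' @param config A [holo_config()].
#' @param rate Sampling rate in Hz; required when `epoch` is a bare matrix.
#' @param channels Channel labels; defaults to the epoch's labels or rownames.
#' @return A `holo_spectrum`: list with `values` (channel x AM band x carrier
#'   band array, µV²), `mask` (logical array, TRUE = outside the valid
#'   triangle), `bedrosian` (logical array, TRUE on the AM = carrier
#'   diagonal), `grid`, `n_epochs`, and `diagnostics` (leakage counts and
#'   constant-envelope fallbacks).
#' @export
holo_spectrum <- function(epoch, grid = band_grid(rate), config = holo_config(),
                          rate = NULL, channels = NULL) {
  if (inherits(epoch, "epoch")) {
    data <- epoch$data; rate <- epoch$rate
    channels <- channels %||% epoch$channels
  } else {
    data <- as.matrix(epoch)
    if (is.null(rate)) stop("`rate` is required when `epoch` is a matrix")
    channels <- channels %||% rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  nb7 <- grid$n_bands
  nch <- nrow(data)
  vals <- array(0.0, c(nch, nb7, nb7),
                dimnames = list(channels, grid$names, grid$names))
  leak <- 0L; lf_fb <- 0L
  for (ch in seq_len(nch)) {
    res <- holo_channel(data[ch, ], rate, grid,
                        within_channel_config(config, ch))
    vals[ch, , ] <- res$power / res$n_interior
    leak <- leak + res$leakage
    lf_fb <- lf_fb + res$lf_fallback
  }
  am_idx <- matrix(seq_len(nb7), nb7, nb7)
  ca_idx <- matrix(seq_len(nb7), nb7, nb7, byrow = TRUE)
  mask2d <- am_idx > ca_idx | ca_idx < 2   # outside the valid triangle
  bed2d <- am_idx == ca_idx & ca_idx >= 2
  new_holo_spectrum(
    values = vals,
    mask = aperm(array(mask2d, c(nb7, nb7, nch)), c(3, 1, 2)),
    bedrosian = aperm(array(bed2d, c(nb7, nb7, nch)), c(3, 1, 2)),
    grid = grid, n_epochs = 1L,
    diagnostics = list(leakage = leak, lf_fallback = lf_fb))
}

# channel-specific decomposition seed so channels get independent noise
within_channel_config <- function(config, ch) {
  config$seed <- config$seed + 1000L * ch
  config
}

new_holo_spectrum <- function(values, mask, bedrosian, grid, n_epochs,
                              diagnostics, subject_id = NULL) {
  structure(list(values = values, mask = mask, bedrosian = bedrosian,
                 grid = grid, n_epochs = n_epochs, diagnostics = diagnostics,
                 subject_id = subject_id),
            class = "holo_spectrum")
}

#' @export
print.holo_spectrum <- function(x, ...) {
  d <- dim(x$values)
  cat("holo_spectrum:", d[1], "channels x", d[2], "AM bands x", d[3],
      "carrier bands; averaged over", x$n_epochs, "epoch(s)\n")
  invisible(x)
}

#' Subject-level Holo-Hilbert spectrum
#'
#' Element-wise mean of single-epoch spectra.
#'
#' @param epochs List of `epoch` objects for one subject.
#' @param grid A [band_grid()].
#' @param config A [holo_config()].
#' @param subject_id Optional identifier stored in the result.
#' @return A `holo_spectrum` with `n_epochs` set to `length(epochs)`.
#' @export
subject_spectrum <- function(epochs, grid = NULL, config = holo_config(),
                             subject_id = NULL) {
  stopifnot(length(epochs) >= 1)
  grid <- grid %||% band_grid(epochs[[1]]$rate)
  specs <- lapply(epochs, holo_spectrum, grid = grid, config = config)
  out <- specs[[1]]
  if (length(specs) > 1) {
    for (s in specs[-1]) out$values <- out$values + s$values
    out$values <- out$values / length(specs)
    out$diagnostics <- list(
      leakage = sum(vapply(specs, function(s) s$diagnostics$leakage, 0L)),
      lf_fallback = sum(vapply(specs, function(s) s$diagnostics$lf_fallback, 0L)))
  }
  out$n_epochs <- length(epochs)
  out$subject_id <- subject_id
  out
}

#' Hilbert-Huang marginal band power
#'
#' Per-IMF squared instantaneous amplitude accumulated into the dyadic carrier
#' band of the instantaneous frequency, summed over time and modes and
#' normalized by the accumulated sample count.
#'
#' @param imfset An `imf_set` from [emd()] or [iceemdan()].
#' @param grid A [band_grid()].
#' @param rate Sampling rate in Hz.
#' @param boundary_frac Boundary fraction excluded per end.
#' @param smooth_secs Instantaneous-frequency median-smoothing window
#'   (seconds), as in [holo_config()].
#' @return Named numeric vector of band powers (one per grid band; the Lf band
#'   collects sub-1 Hz carrier estimates).
#' @export
hht_marginal <- function(imfset, grid, rate, boundary_frac = 0.05,
                         smooth_secs = 0.75) {
  stopifnot(inherits(imfset, "imf_set"))
  n <- imfset$source_length
  out <- stats::setNames(numeric(grid$n_bands), grid$names)
  nbound <- max(1L, round(boundary_frac * n))
  interior <- (nbound + 1):(n - nbound)
  for (i in seq_len(ncol(imfset$imfs))) {
    imf <- imfset$imfs[, i]
    if (sd(imf) == 0) next
    if (length(.extrema_c(abs(imf))$maxima) < 2) next
    a <- envelope_refined(imf)
    dq <- direct_quadrature(imf, rate, env = a, boundary_frac = boundary_frac,
                            smooth_secs = smooth_secs)
    # for the marginal, sub-grid carrier estimates fall into the lowest band
    band <- am_band_index(grid, dq$inst_freq)
    ok <- which(dq$valid & !is.na(band))
    ok <- ok[ok %in% interior]
    if (length(ok)) {
      tab <- tapply(a[ok]^2, band[ok], sum)
      out[as.integer(names(tab))] <- out[as.integer(names(tab))] + tab
    }
  }
  out / length(interior)
}

#' Conventional windowed-FFT band power
#'
#' Hann-windowed periodogram on non-overlapping 2-s segments, averaged within
#' the epoch, integrated over the conventional clinical bands delta (0.5--4),
#' theta (4.5--8), alpha (8.5--12), beta (12.5--30) and gamma (30.5--80 Hz).
#'
#' @param epoch An `epoch` object or channels x samples matrix.
#' @param rate Sampling rate in Hz (required for a bare matrix).
#' @return Matrix channels x 5 of band powers (µV², variance units), with an
#'   attribute `"edges"` listing the band limits.
#' @export
fft_band_power <- function(epoch, rate = NULL) {
  if (inherits(epoch, "epoch")) { data <- epoch$data; rate <- epoch$rate }
  else {
    data <- as.matrix(epoch)
    if (is.null(rate)) stop("`rate` is required when `epoch` is a matrix")
  }
  n <- ncol(data)
  if (n < 2 * rate) stop("epoch shorter than 2 s")
  bands <- list(delta = c(0.5, 4), theta = c(4.5, 8), alpha = c(8.5, 12),
                beta = c(12.5, 30), gamma = c(30.5, 80))
  seg <- floor(2 * rate)
  nseg <- n %/% seg
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))   # Hann
  scale <- 1 / (sum(w^2) * rate)
  freqs <- (seq_len(seg %/% 2)) * rate / seg                 # skip DC
  df <- rate / seg
  out <- matrix(0.0, nrow(data), length(bands),
                dimnames = list(rownames(data), names(bands)))
  for (ch in seq_len(nrow(data))) {
    psd <- numeric(length(freqs))
    for (s in seq_len(nseg)) {
      x <- data[ch, ((s - 1) * seg + 1):(s * seg)]
      X <- fft((x - mean(x)) * w)
      p <- Mod(X[2:(seg %/% 2 + 1)])^2 * scale
      # one-sided: double everything except Nyquist
      p[-length(p)] <- 2 * p[-length(p)]
      psd <- psd + p
    }
    psd <- psd / nseg
    for (b in seq_along(bands)) {
      sel <- freqs >= bands[[b]][1] & freqs <= bands[[b]][2]
      out[ch, b] <- sum(psd[sel]) * df
    }
  }
  attr(out, "edges") <- bands
  out
}
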