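#' Direct quadrature demodulation of an IMF
#'
#' Splits an IMF into its amplitude envelope and a unit-amplitude carrier,
#' then recovers instantaneous phase and frequency from the quadrature pair
#' without a Hilbert transform: the normalized carrier `q = x / a(t)` is
#' clipped to `[-1, 1]`, its quadrature `sqrt(1 - q^2)` is signed for branch
#' continuity (the sign of `-dq/dt`, so phase increases), and the phase is
#' unwrapped and differentiated centrally to give frequency in Hz.
#'
#' @param x Numeric vector, one IMF.
#' @param rate Sampling rate in Hz.
#' @param env Optional precomputed amplitude envelope (defaults to
#'   [envelope()] of `x`).
#' @param boundary_frac Fraction of samples at each end flagged invalid
#'   (spline end effects); default 0.05.
#' @param smooth_secs Length (seconds) of a running-median filter applied to
#'   the instantaneous-frequency track; 0 (default) disables it. Median
#'   smoothing suppresses sample-level wobble in the frequency estimate while
#'   preserving monotone frequency ramps.
#' @return List of class `analytic_imf`: `envelope`, `carrier` (normalized),
#'   `phase` (unwrapped, radians), `inst_freq` (Hz), and `valid` (logical;
#'   `FALSE` at boundaries, envelope zeros, and isolated negative-frequency
#'   samples).
#' @export
direct_quadrature <- function(x, rate, env = NULL, boundary_frac = 0.05,
                              smooth_secs = 0) {
  stopifnot(is.numeric(x), rate > 0)
  n <- length(x)
  a <- env %||% envelope(x)
  stopifnot(length(a) == n)
  valid <- a > .Machine$double.eps * max(a, 1)
  q <- ifelse(valid, x / pmax(a, .Machine$double.xmin), 0)
  q <- pmin(pmax(q, -1), 1)

  # quadrature sign: phase advances, so sin(phi) carries the sign of -dq/dt
  dq <- c(q[2] - q[1], (q[-(1:2)] - q[1:(n - 2)]) / 2, q[n] - q[n - 1])
  s <- -sign(dq)
  s[s == 0] <- 1
  y <- s * sqrt(pmax(1 - q^2, 0))
  phi <- atan2(y, q)
  # unwrap
  d <- diff(phi)
  d <- (d + pi) %% (2 * pi) - pi
  phi <- phi[1] + c(0, cumsum(d))

  f <- c(phi[2] - phi[1], (phi[-(1:2)] - phi[1:(n - 2)]) / 2, phi[n] - phi[n - 1])
  f <- f * rate / (2 * pi)
  if (smooth_secs > 0) {
    k <- round(smooth_secs * rate)
    k <- min(k + 1 - k %% 2, n - 1 + n %% 2)     # odd, within signal length
    # endrule "keep": the boundary fraction is flagged invalid below anyway
    if (k >= 3) f <- as.numeric(stats::runmed(f, k, endrule = "keep"))
  }
  nb <- max(1L, round(boundary_frac * n))
  valid[c(seq_len(nb), (n - nb + 1):n)] <- FALSE
  valid[f < 0] <- FALSE                  # isolated negative estimates
  structure(list(envelope = a, carrier = q, phase = phi,
                 inst_freq = f, valid = valid, rate = rate),
            class = "analytic_imf")
}
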