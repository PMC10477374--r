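#' Dyadic frequency band grid
#'
#' Frequency bands on a dyadic scale: Lf (0.5--1 Hz), delta1 (1--2), delta2
#' (2--4), theta (4--8), alpha (8--16), beta (16--32) and gamma (32 Hz up to
#' the Nyquist frequency, capped at 100 Hz). Carrier bands run from delta1 to
#' gamma; admissible amplitude-modulation (AM) bands for a carrier are all
#' bands up to and including the carrier band itself, giving 27 (AM, carrier)
#' cells, of which the 6 diagonal cells (AM band equal to carrier band) are
#' flagged as unreliable under the Bedrosian condition.
#'
#' @param rate Sampling rate in Hz; the top band edge is `min(100, rate/2)`.
#' @return An object of class `band_grid` with elements `edges` (8 band
#'   edges in Hz), `names`, `carrier_idx` (indices of carrier bands) and
#'   `cells` (data frame of valid (am, carrier) index pairs with a
#'   `bedrosian` flag).
#' @export
#' @examples
#' g <- band_grid(200)
#' g$edges
band_grid <- function(rate = 200) {
  stopifnot(rate > 0)
  top <- min(100, rate / 2)
  edges <- c(0.5, 1, 2, 4, 8, 16, 32, top)
  if (any(diff(edges) <= 0))
    stop("sampling rate too low for the dyadic grid (top edge must exceed 32 Hz)")
  nm <- c("Lf", "delta1", "delta2", "theta", "alpha", "beta", "gamma")
  carrier_idx <- 2:7
  cells <- do.call(rbind, lapply(carrier_idx, function(ci)
    data.frame(am = seq_len(ci), carrier = ci)))
  cells$bedrosian <- cells$am == cells$carrier
  structure(list(edges = edges, names = nm, n_bands = 7L,
                 carrier_idx = carrier_idx, cells = cells, rate = rate),
            class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat("Dyadic band grid:", paste(x$names, collapse = " "), "\n")
  cat("Edges (Hz):", paste(x$edges, collapse = ", "), "\n")
  cat(nrow(x$cells), "valid (AM, carrier) cells;",
      sum(x$cells$bedrosian), "Bedrosian-flagged diagonal cells\n")
  invisible(x)
}

# Band index for an AM frequency: frequencies below the lowest edge fall into
# Lf (band 1); above the top edge -> NA (counted as leakage by callers).
am_band_index <- function(grid, f) {
  idx <- findInterval(f, grid$edges, rightmost.closed = TRUE)
  idx[idx == 0] <- 1L
  idx[f > grid$edges[8] | is.na(f)] <- NA_integer_
  idx
}

# Band index for a carrier frequency: only bands delta1..gamma qualify;
# anything below 1 Hz or above the top edge -> NA (leakage).
carrier_band_index <- function(grid, f) {
  idx <- findInterval(f, grid$edges, rightmost.closed = TRUE)
  idx[idx < 2 | f > grid$edges[8] | is.na(f)] <- NA_integer_
  idx
}
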