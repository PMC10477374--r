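#' Topographic grid of contrast t-statistics
#'
#' One panel per (AM band, carrier band) cell of the valid triangle, each
#' showing the scalp layout from above (nose up) with channels coloured by the
#' t statistic (blue negative, red positive) and significant channels marked
#' by a heavier open circle — the conventional rendering for AM-by-carrier
#' contrast maps.
#'
#' @param x A `contrast_result`.
#' @param positions Electrode coordinate table (default the packaged montage).
#' @param t_range Symmetric colour range for t (default `c(-2, 2)`).
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.contrast_result <- function(x, positions = load_montage(),
                                 t_range = c(-2, 2), ...) {
  cells <- x$cells
  combos <- unique(cells[, c("am", "carrier")])
  combos <- combos[order(combos$carrier, combos$am), ]
  g <- band_grid()
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  old <- graphics::par(mfrow = c(max(combos$am), 6), mar = c(0.4, 0.4, 1.1, 0.4))
  on.exit(graphics::par(old))
  for (ai in seq_len(max(combos$am))) {
    for (ci in 2:7) {
      sel <- cells$am == ai & cells$carrier == ci
      if (!any(sel)) {
        graphics::plot.new()
        next
      }
      sub <- cells[sel, ]
      tv <- x$t_map[sel]
      sig <- x$sig_mask[sel]
      xy <- positions[match(sub$channel, positions$label), c("x_mm", "y_mm")]
      graphics::plot(xy$x_mm, xy$y_mm, asp = 1, axes = FALSE, xlab = "",
                     ylab = "", pch = 21, cex = 1.6,
                     bg = pal[pmin(101, pmax(1, round(
                       50 * (tv - t_range[1]) / diff(t_range)) + 1))],
                     col = "grey40",
                     main = paste0(g$names[ai], " AM / ", g$names[ci], " fc"),
                     cex.main = 0.7)
      if (any(sig))
        graphics::points(xy$x_mm[sig], xy$y_mm[sig], pch = 1, cex = 2.4, lwd = 2)
    }
  }
  invisible(x)
}
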