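#' Sensor neighbourhood graph from electrode positions
#'
#' Two sensors are neighbours when their Euclidean distance does not exceed
#' `max_distance` (70 mm by default).
#'
#' @param positions Numeric matrix (labelled rows) or data frame with columns
#'   `label`, `x_mm`, `y_mm`, `z_mm` of 3-D electrode coordinates in mm.
#' @param max_distance Neighbouring distance in mm (default 70).
#' @return An `adjacency` object: logical symmetric matrix with zero diagonal
#'   plus the `max_distance` used.
#' @export
sensor_adjacency <- function(positions, max_distance = 70) {
  if (is.data.frame(positions)) {
    m <- as.matrix(positions[, c("x_mm", "y_mm", "z_mm")])
    rownames(m) <- positions$label
    positions <- m
  }
  stopifnot(is.matrix(positions), ncol(positions) == 3, nrow(positions) >= 2)
  if (any(!is.finite(positions))) stop("missing coordinates for an analyzed channel")
  d <- as.matrix(stats::dist(positions))
  adj <- d <= max_distance
  diag(adj) <- FALSE
  structure(list(matrix = adj, labels = rownames(positions),
                 max_distance = max_distance),
            class = "adjacency")
}

#' Cell neighbourhood over (channel, AM band, carrier band)
#'
#' Two cells are adjacent iff they share the channel and differ by exactly one
#' step along exactly one band axis (AM or carrier) within the valid triangle,
#' or they sit at the same (AM, carrier) coordinates on sensor-neighbouring
#' channels. Diagonal (Bedrosian-flagged) cells are excluded by default.
#'
#' @param grid A [band_grid()].
#' @param sensors An [sensor_adjacency()] over the analyzed channels.
#' @param include_bedrosian Keep the AM = carrier diagonal cells (default
#'   FALSE).
#' @return A `cell_adjacency` object: `cells` (data frame `channel`, `am`,
#'   `carrier`), CSR neighbour lists (`ptr`, `idx`, 0-based) and the inputs.
#' @export
cell_adjacency <- function(grid, sensors, include_bedrosian = FALSE) {
  stopifnot(inherits(sensors, "adjacency"))
  ch_labels <- sensors$labels
  cel <- grid$cells
  if (!include_bedrosian) cel <- cel[!cel$bedrosian, ]
  cells <- do.call(rbind, lapply(seq_along(ch_labels), function(ci)
    data.frame(channel = ch_labels[ci], ch_idx = ci,
               am = cel$am, carrier = cel$carrier)))
  rownames(cells) <- NULL
  n <- nrow(cells)
  key <- function(ch, am, ca) paste(ch, am, ca)
  lookup <- stats::setNames(seq_len(n), key(cells$ch_idx, cells$am, cells$carrier))
  nbr <- vector("list", n)
  A <- sensors$matrix
  for (i in seq_len(n)) {
    ch <- cells$ch_idx[i]; am <- cells$am[i]; ca <- cells$carrier[i]
    cand <- c(key(ch, am - 1, ca), key(ch, am + 1, ca),
              key(ch, am, ca - 1), key(ch, am, ca + 1),
              key(which(A[ch, ]), am, ca))
    hit <- lookup[cand]
    nbr[[i]] <- sort(unname(hit[!is.na(hit)]))
  }
  deg <- lengths(nbr)
  structure(list(cells = cells[, c("channel", "am", "carrier")],
                 ptr = c(0L, cumsum(deg)),
                 idx = as.integer(unlist(nbr) - 1L),
                 grid = grid, sensors = sensors,
                 include_bedrosian = include_bedrosian),
            class = "cell_adjacency")
}

# subjects x cells matrix from a list of holo_spectrum objects, in the cell
# order of a cell_adjacency
holo_cell_matrix <- function(spectra, adjacency) {
  cells <- adjacency$cells
  labels <- adjacency$sensors$labels
  X <- matrix(NA_real_, length(spectra), nrow(cells))
  for (s in seq_along(spectra)) {
    v <- spectra[[s]]$values
    ch <- match(cells$channel, dimnames(v)[[1]])
    if (anyNA(ch)) stop("spectra lack channels required by the adjacency: ",
                        paste(unique(cells$channel[is.na(ch)]), collapse = ", "))
    X[s, ] <- v[cbind(ch, cells$am, cells$carrier)]
  }
  X
}

# pooled-variance two-sample t for all permutations at once.
# X: subjects x cells; PA: subjects x n_perm 0/1 indicator of group-A
# membership. Returns cells x n_perm matrix of t statistics.
perm_t_matrix <- function(X, PA, nA, nB) {
  n <- nA + nB
  X2 <- X^2
  SA <- crossprod(X, PA)            # cells x perms: group-A sums
  QA <- crossprod(X2, PA)
  ST <- colSums(X); QT <- colSums(X2)
  SB <- ST - SA; QB <- QT - QA
  mA <- SA / nA; mB <- SB / nB
  ssA <- QA - SA^2 / nA
  ssB <- QB - SB^2 / nB
  sp2 <- (ssA + ssB) / (n - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tmat <- (mA - mB) / se
  tmat[!is.finite(tmat)] <- 0        # degenerate variance cells
  tmat
}

#' Two-tailed cluster-based nonparametric permutation contrast
#'
#' Per-cell pooled-variance Student t between two groups of Holo-Hilbert
#' spectra; cells exceeding the two-tailed cluster-forming threshold are
#' clustered by sign under the cell adjacency; cluster mass is the summed t;
#' the null distribution is the maximum absolute cluster mass over random
#' relabelings of subjects (subjects, not epochs, are the exchange units).
#' Monte-Carlo p-values use the add-one convention
#' `(1 + #\{null >= |mass|\}) / (n_perm + 1)`.
#'
#' @param groupA,groupB Lists of `holo_spectrum` objects (>= 2 subjects each,
#'   identical grids).
#' @param adjacency A [cell_adjacency()]; its `include_bedrosian` flag governs
#'   whether diagonal cells enter the test.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Cluster significance level (default 0.05).
#' @param cluster_alpha Two-tailed cluster-forming level on the per-cell t
#'   (default 0.05); `1` sets the forming threshold to zero so every non-zero
#'   cell can enter a cluster (useful to reduce the test to a permutation
#'   t-test on a single cell).
#' @param seed Integer seed; the relabelings are deterministic given it.
#' @param covariate Optional numeric per-subject covariate (ordered as
#'   `c(groupA, groupB)`) regressed out of every cell before testing.
#' @return A `contrast_result`: `cells`, `t_map`, `cluster_labels`, `clusters`
#'   (data frame with `id`, `sign`, `n_cells`, `mass`, `p_perm`), `sig_mask`,
#'   `threshold`, `n_perm`, `alpha`, `seed`, `n_degenerate`.
#' @export
cluster_permutation_test <- function(groupA, groupB, adjacency,
                                     n_perm = 5000, alpha = 0.05,
                                     cluster_alpha = 0.05, seed = 1,
                                     covariate = NULL) {
  stopifnot(inherits(adjacency, "cell_adjacency"),
            length(groupA) >= 2, length(groupB) >= 2)
  if (n_perm < 100)
    warning("with n_perm = ", n_perm, " the permutation p-value cannot fall ",
            "below 1/", n_perm + 1, " = ", signif(1 / (n_perm + 1), 3))
  nA <- length(groupA); nB <- length(groupB); n <- nA + nB
  X <- holo_cell_matrix(c(groupA, groupB), adjacency)
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    cc <- covariate - mean(covariate)
    beta <- crossprod(cc, X) / sum(cc^2)
    X <- X - outer(cc, as.numeric(beta))
  }
  df <- n - 2
  thr <- if (cluster_alpha >= 1) 0 else qt(1 - cluster_alpha / 2, df)

  obsA <- matrix(0, n, 1); obsA[seq_len(nA), 1] <- 1
  t_obs <- as.numeric(perm_t_matrix(X, obsA, nA, nB))
  n_degenerate <- sum(t_obs == 0 & apply(X, 2, function(v) var(v) == 0))

  lab <- .cluster_label_c(t_obs, thr, adjacency$ptr, adjacency$idx)
  masses <- lab$mass

  PA <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      z <- numeric(n); z[sample.int(n, nA)] <- 1; z
    }, numeric(n))
  })
  t_null <- perm_t_matrix(X, PA, nA, nB)
  null_max <- .perm_max_mass_c(t_null, thr, adjacency$ptr, adjacency$idx)

  # relative tolerance so tie relabelings (e.g. the identity split) are
  # counted as in exhaustive enumeration despite floating-point noise
  p_perm <- vapply(masses, function(m)
    (1 + sum(null_max >= abs(m) * (1 - 1e-9))) / (n_perm + 1), 0.0)
  clusters <- data.frame(id = seq_along(masses),
                         sign = ifelse(masses >= 0, "positive", "negative"),
                         n_cells = as.integer(table(factor(lab$labels[lab$labels > 0],
                                                           levels = seq_along(masses)))),
                         mass = masses, p_perm = p_perm)
  sig_ids <- clusters$id[clusters$p_perm < alpha]
  structure(list(cells = adjacency$cells, t_map = t_obs,
                 cluster_labels = lab$labels, clusters = clusters,
                 sig_mask = lab$labels %in% sig_ids,
                 threshold = thr, n_perm = n_perm, alpha = alpha,
                 cluster_alpha = cluster_alpha, seed = seed,
                 n_degenerate = n_degenerate),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast_result over", length(x$t_map), "cells;",
      nrow(x$clusters), "cluster(s),",
      sum(x$clusters$p_perm < x$alpha), "significant at alpha =", x$alpha, "\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Summarize a contrast as per-cell significance table
#'
#' @param object A `contrast_result`.
#' @param ... Unused.
#' @return Data frame: cell coordinates, t, cluster id, significance flag.
#' @export
summary.contrast_result <- function(object, ...) {
  out <- object$cells
  out$t <- object$t_map
  out$cluster <- object$cluster_labels
  out$significant <- object$sig_mask
  out
}
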