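test_that("sensor adjacency applies the distance rule symmetrically", {
  pos <- rbind(a = c(0, 0, 0), b = c(69, 0, 0), c = c(140.5, 0, 0))
  adj <- sensor_adjacency(pos, 70)
  expect_true(adj$matrix["a", "b"])       # 69 mm: neighbours
  expect_false(adj$matrix["b", "c"])      # 71.5 mm: not
  expect_identical(adj$matrix, t(adj$matrix))
  expect_true(all(!diag(adj$matrix)))
  expect_error(sensor_adjacency(rbind(a = c(0, 0, NA), b = c(1, 1, 1))), "missing")
})

test_that("cell adjacency allows one-step moves on exactly one axis", {
  ca <- adjacency_1020()
  cells <- ca$cells
  find <- function(ch, am, carr)
    which(cells$channel == ch & cells$am == am & cells$carrier == carr)
  nbrs <- function(i) ca$idx[(ca$ptr[i] + 1):(ca$ptr[i + 1])] + 1
  i <- find("O1", 4, 6)                    # (O1, theta, beta)
  expect_true(find("O1", 5, 6) %in% nbrs(i))   # one step on the AM axis
  expect_true(find("O2", 4, 6) %in% nbrs(i))   # O1-O2 under 70 mm
  expect_false(find("O2", 5, 7) %in% nbrs(i))  # two-axis move excluded
  expect_false(find("Fp1", 4, 6) %in% nbrs(i)) # distant channel excluded
  # Bedrosian diagonal excluded by default: 19 x 21 cells
  expect_equal(nrow(cells), 19 * 21)
  expect_equal(nrow(cell_adjacency(band_grid(RATE),
                                   sensor_adjacency(scalp_positions(), 70),
                                   include_bedrosian = TRUE)$cells), 19 * 27)
})

test_that("isolated sensors degrade gracefully to per-channel clusters", {
  pos <- rbind(a = c(0, 0, 0), b = c(300, 0, 0))
  ca <- cell_adjacency(band_grid(RATE), sensor_adjacency(pos, 70))
  # per-cell permutation oracle: plant a difference at one cell of channel a
  set.seed(2)
  M <- matrix(rnorm(12 * nrow(ca$cells), sd = 0.1), 12)
  M[7:12, 5] <- M[7:12, 5] + 3
  sp <- spectra_from_matrix(M, ca)
  res <- cluster_permutation_test(sp[7:12], sp[1:6], ca, n_perm = 500, seed = 4)
  sig_cells <- which(res$sig_mask)
  expect_true(5 %in% sig_cells)
  # the cluster containing the planted cell stays on channel a
  cl <- res$cluster_labels[5]
  expect_true(all(ca$cells$channel[res$cluster_labels == cl] == "a"))
})

test_that("the exact null yields no clusters and degenerate cells t = 0", {
  ca <- adjacency_1020()
  M <- matrix(rep(runif(nrow(ca$cells)), each = 8), 8, byrow = FALSE)
  sp <- spectra_from_matrix(M, ca)
  res <- cluster_permutation_test(sp[1:4], sp[5:8], ca, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$t_map == 0))
  expect_false(any(res$sig_mask))
})

test_that("Monte-Carlo p matches exhaustive enumeration on 4 vs 4", {
  mon <- load_montage()
  ca <- cell_adjacency(band_grid(RATE),
                       sensor_adjacency(mon[mon$label %in% c("O1", "Fp2"), ], 70))
  set.seed(10)
  vals <- rnorm(8); vals[1:4] <- vals[1:4] + 1.5
  M <- matrix(0, 8, nrow(ca$cells))
  cell <- which(ca$cells$channel == "O1" & ca$cells$am == 4 & ca$cells$carrier == 6)
  M[, cell] <- vals
  sp <- spectra_from_matrix(M, ca)
  res <- cluster_permutation_test(sp[1:4], sp[5:8], ca, n_perm = 4000,
                                  cluster_alpha = 1, seed = 3)
  tstat <- function(ix) {
    a <- vals[ix]; b <- vals[-ix]
    sp2 <- (3 * var(a) + 3 * var(b)) / 6
    (mean(a) - mean(b)) / sqrt(sp2 / 2)
  }
  tall <- apply(combn(8, 4), 2, tstat)
  p_exact <- mean(abs(tall) >= abs(tstat(1:4)))
  p_mc <- res$clusters$p_perm[which.max(abs(res$clusters$mass))]
  expect_lt(abs(p_exact - p_mc), 0.02)
})

test_that("permuting subject order within groups leaves the contrast unchanged", {
  ca <- adjacency_1020()
  set.seed(12)
  M <- matrix(rnorm(16 * nrow(ca$cells)), 16)
  M[9:16, 40:47] <- M[9:16, 40:47] + 1.2
  sp <- spectra_from_matrix(M, ca)
  r1 <- cluster_permutation_test(sp[9:16], sp[1:8], ca, n_perm = 400, seed = 5)
  r2 <- cluster_permutation_test(sp[c(12:16, 9:11)], sp[c(5:8, 1:4)], ca,
                                 n_perm = 400, seed = 5)
  expect_equal(r1$t_map, r2$t_map)
  expect_equal(r1$clusters$mass, r2$clusters$mass)
  expect_equal(r1$clusters$p_perm, r2$clusters$p_perm, tolerance = 0.05)
})

test_that("cluster mass grows monotonically with planted effect size", {
  ca <- adjacency_1020()
  patch <- which(ca$cells$channel %in% c("O1", "O2") & ca$cells$carrier == 5)
  masses <- vapply(c(0.8, 1.6, 3.2), function(delta) {
    set.seed(21)
    M <- matrix(rnorm(20 * nrow(ca$cells)), 20)
    M[11:20, patch] <- M[11:20, patch] + delta
    sp <- spectra_from_matrix(M, ca)
    res <- cluster_permutation_test(sp[11:20], sp[1:10], ca, n_perm = 200, seed = 2)
    if (nrow(res$clusters) == 0) 0 else max(res$clusters$mass)
  }, 0.0)
  expect_true(all(diff(masses) > 0))
})

test_that("a planted multi-cell patch is localized with few false cells", {
  ca <- adjacency_1020()
  patch <- which(ca$cells$channel %in% c("O1", "O2", "P3", "P4") &
                 ca$cells$am == 1 & ca$cells$carrier %in% 4:5)
  expect_equal(length(patch), 8)
  hits <- 0; false_cells <- 0
  for (s in 1:10) {
    set.seed(s + 100)
    M <- matrix(rnorm(24 * nrow(ca$cells)), 24)
    M[13:24, patch] <- M[13:24, patch] + 2
    sp <- spectra_from_matrix(M, ca)
    res <- cluster_permutation_test(sp[13:24], sp[1:12], ca, n_perm = 300, seed = s)
    sig <- which(res$sig_mask)
    hits <- hits + length(intersect(sig, patch))
    false_cells <- false_cells + length(setdiff(sig, patch))
  }
  expect_gt(hits / (10 * length(patch)), 0.5)          # >= 50% of planted cells
  expect_lt(false_cells / (10 * (nrow(ca$cells) - 8)), 0.01)  # < 1% elsewhere
})

test_that("low permutation counts trigger the resolution warning", {
  ca <- adjacency_1020()
  M <- matrix(rnorm(8 * nrow(ca$cells)), 8)
  sp <- spectra_from_matrix(M, ca)
  expect_warning(cluster_permutation_test(sp[1:4], sp[5:8], ca, n_perm = 10,
                                          seed = 1), "1/11")
})
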