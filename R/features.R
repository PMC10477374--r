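#' EEG signatures from a Holo-Hilbert spectrum
#'
#' One signature per (channel, valid AM x carrier cell): the AM power of that
#' cell. On the default 19-channel montage and dyadic grid this yields
#' 19 x 27 = 513 signatures (diagonal Bedrosian-flagged cells included, with
#' the flag carried along).
#'
#' @param spectrum A `holo_spectrum`.
#' @param check_montage Reject channels absent from the packaged 10--20
#'   montage (default TRUE; disable for synthetic ad-hoc channel sets).
#' @return Data frame: `id`, `channel`, `am_band`, `carrier_band`, `bedrosian`,
#'   `value`.
#' @export
build_signatures <- function(spectrum, check_montage = TRUE) {
  stopifnot(inherits(spectrum, "holo_spectrum"))
  g <- spectrum$grid
  channels <- dimnames(spectrum$values)[[1]]
  if (check_montage) {
    bad <- setdiff(channels, load_montage()$label)
    if (length(bad))
      stop("channels missing from montage: ", paste(bad, collapse = ", "))
  }
  cel <- g$cells
  out <- do.call(rbind, lapply(seq_along(channels), function(ci)
    data.frame(channel = channels[ci],
               am_band = g$names[cel$am], carrier_band = g$names[cel$carrier],
               bedrosian = cel$bedrosian,
               value = spectrum$values[cbind(ci, cel$am, cel$carrier)])))
  out$id <- sprintf("%s.%s.%s", out$channel, out$am_band, out$carrier_band)
  rownames(out) <- NULL
  out[, c("id", "channel", "am_band", "carrier_band", "bedrosian", "value")]
}

#' Feature descriptors: signatures and their ordered ratios
#'
#' All ordered pairs of distinct signatures become ratio descriptors
#' (`n * (n-1)` of them; 513 signatures give 262,656 ratios), optionally
#' preceded by the single-signature features, which are tagged separately.
#'
#' @param signatures A signature data frame from [build_signatures()] (only
#'   the `id` column is used) or a character vector of signature ids.
#' @param include_singles Prepend single-signature descriptors (default TRUE).
#' @return Data frame: `name`, `kind` (`"single"`/`"ratio"`), `numerator`,
#'   `denominator` (NA for singles).
#' @export
build_ratio_features <- function(signatures, include_singles = TRUE) {
  ids <- if (is.data.frame(signatures)) signatures$id else as.character(signatures)
  n <- length(ids)
  if (n < 2) stop("need at least 2 signatures")
  pair <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), times = n))
  pair <- pair[pair[, 1] != pair[, 2], , drop = FALSE]   # no identity ratios
  ratios <- data.frame(name = paste0(ids[pair[, 1]], "/", ids[pair[, 2]]),
                       kind = "ratio",
                       numerator = ids[pair[, 1]], denominator = ids[pair[, 2]])
  if (!include_singles) return(ratios)
  singles <- data.frame(name = ids, kind = "single",
                        numerator = ids, denominator = NA_character_)
  rbind(singles, ratios)
}

#' Evaluate feature descriptors over a cohort of spectra
#'
#' @param spectra List of `holo_spectrum` objects (one per subject).
#' @param descriptors Descriptor data frame from [build_ratio_features()].
#' @param eps Denominator floor for ratio features (default 1e-12); values
#'   below it are clamped and the affected columns flagged in the
#'   `"clamped"` attribute.
#' @param check_montage Passed to [build_signatures()].
#' @return Subjects x features numeric matrix (column names = descriptor
#'   names).
#' @export
compute_feature_matrix <- function(spectra, descriptors, eps = 1e-12,
                                   check_montage = TRUE) {
  sigs <- lapply(spectra, build_signatures, check_montage = check_montage)
  ids <- sigs[[1]]$id
  V <- t(vapply(sigs, function(s) s$value[match(ids, s$id)],
                numeric(length(ids))))
  colnames(V) <- ids
  ni <- match(descriptors$numerator, ids)
  di <- match(descriptors$denominator, ids)
  if (anyNA(ni)) stop("descriptor numerator not found among signatures")
  out <- matrix(NA_real_, nrow(V), nrow(descriptors),
                dimnames = list(rownames(V), descriptors$name))
  single <- is.na(di)
  out[, single] <- V[, ni[single], drop = FALSE]
  if (any(!single)) {
    den <- V[, di[!single], drop = FALSE]
    clamped <- den < eps
    den[clamped] <- eps
    out[, !single] <- V[, ni[!single], drop = FALSE] / den
    attr(out, "clamped") <- colnames(out)[!single][colSums(clamped) > 0]
  }
  out
}

#' Greedy correlation pruning of a feature matrix
#'
#' Columns are scanned in order; a column is dropped iff its absolute Pearson
#' correlation with an already-retained column exceeds `r_max`. Constant
#' columns are dropped first (their correlation is undefined). Deterministic;
#' idempotent.
#'
#' @param X Subjects x features matrix.
#' @param r_max Correlation threshold (default 0.95). At `r_max = 1` only
#'   exact linear duplicates are removed.
#' @return List: `X` (pruned matrix), `keep` (retained column indices into the
#'   input).
#' @export
decorrelate <- function(X, r_max = 0.95) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  sds <- apply(X, 2, sd)
  nonconst <- which(sds > 0)
  if (!length(nonconst)) stop("all feature columns are constant")
  n <- nrow(X)
  Z <- scale(X[, nonconst, drop = FALSE])
  keep <- integer(0)
  Zk <- matrix(0.0, n, length(nonconst))
  for (j in seq_along(nonconst)) {
    if (length(keep)) {
      r <- crossprod(Zk[, seq_along(keep), drop = FALSE], Z[, j]) / (n - 1)
      # tolerance so exact duplicates prune at r_max = 1 despite roundoff
      if (max(abs(r)) > r_max - 1e-10) next
    }
    keep <- c(keep, j)
    Zk[, length(keep)] <- Z[, j]
  }
  keep <- unname(nonconst[keep])
  list(X = X[, keep, drop = FALSE], keep = keep)
}

#' Subset-wise boosting rank-and-select
#'
#' Features are partitioned into consecutive subsets of at most `subset_size`
#' columns; a LogitBoost fit per subset records each feature's importance
#' (training-loss reduction over the rounds its stump was chosen); the subset
#' winners are pooled and re-ranked by a final LogitBoost fit, and the top
#' `max_selected` features with positive final importance are returned.
#' Deterministic given `seed` (used only when `shuffle = TRUE`).
#'
#' @param X Subjects x features matrix (pruned).
#' @param y Binary labels (see [logitboost_train()]).
#' @param subset_size Columns per subset (default 100).
#' @param max_selected Maximum number of features returned (default 9, below
#'   the customary overfitting guard of 10).
#' @param rounds Boosting rounds per fit (default 30).
#' @param seed Seed for the optional subset shuffle.
#' @param shuffle Randomize column-to-subset assignment (default FALSE:
#'   consecutive subsets).
#' @return Integer vector of selected column indices (ranked), with the final
#'   importances as the `"importance"` attribute.
#' @export
boost_rank_select <- function(X, y, subset_size = 100, max_selected = 9,
                              rounds = 30, seed = 1, shuffle = FALSE) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (max_selected >= p) {
    warning("max_selected >= number of features; returning all")
    return(structure(seq_len(p), importance = rep(NA_real_, p)))
  }
  cols <- seq_len(p)
  if (shuffle) cols <- with_seed(seed, sample(cols))
  groups <- split(cols, ceiling(seq_along(cols) / subset_size))
  candidates <- integer(0)
  for (grp in groups) {
    fit <- logitboost_train(X[, grp, drop = FALSE], y, rounds = rounds)
    win <- grp[fit$importance > 0]
    # keep each subset's strongest contributors
    win <- win[order(-fit$importance[fit$importance > 0],
                     match(win, grp))][seq_len(min(length(win), max_selected))]
    candidates <- c(candidates, win)
  }
  candidates <- sort(unique(candidates))
  if (!length(candidates)) stop("no informative features found in any subset")
  final <- logitboost_train(X[, candidates, drop = FALSE], y, rounds = rounds)
  ord <- order(-final$importance, seq_along(candidates))
  ord <- ord[final$importance[ord] > 0]
  sel <- candidates[ord][seq_len(min(max_selected, length(ord)))]
  structure(sel, importance = final$importance[ord][seq_along(sel)])
}
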