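# Plain-text serialization of the pipeline's containers: CSV payloads with a
# JSON metadata sidecar, so results survive without R-specific binary formats.

#' Write / read an `imf_set` as a columnar on-disk layout
#'
#' One CSV per layer-1 decomposition (columns imf1..imfK plus residue) and a
#' JSON sidecar with the source length and mode count.
#'
#' @param x An `imf_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`write_imfset`); an `imf_set` (`read_imfset`).
#' @export
write_imfset <- function(x, dir) {
  stopifnot(inherits(x, "imf_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- ncol(x$imfs)
  m <- cbind(x$imfs, x$residue)
  colnames(m) <- c(if (k) paste0("imf", seq_len(k)), "residue")
  utils::write.csv(m, file.path(dir, "imfset.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_imfs = k, source_length = x$source_length),
                       file.path(dir, "imfset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_imfset
#' @export
read_imfset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "imfset.json"))
  m <- as.matrix(utils::read.csv(file.path(dir, "imfset.csv")))
  k <- meta$n_imfs
  new_imf_set(m[, seq_len(k), drop = FALSE], as.numeric(m[, k + 1]),
              meta$source_length)
}

#' Write / read a `holo_spectrum` as a labelled long table plus JSON sidecar
#'
#' The CSV holds one row per (channel, AM band, carrier band) with the power
#' value and mask flags; the sidecar records the grid edges, epoch count and
#' diagnostics.
#'
#' @param x A `holo_spectrum`.
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly (`write_holo_spectrum`); a `holo_spectrum`
#'   (`read_holo_spectrum`).
#' @export
write_holo_spectrum <- function(x, path) {
  stopifnot(inherits(x, "holo_spectrum"))
  dn <- dimnames(x$values)
  idx <- expand.grid(channel = dn[[1]], am_band = dn[[2]],
                     carrier_band = dn[[3]], stringsAsFactors = FALSE)
  idx$value <- as.numeric(x$values)
  idx$masked <- as.logical(x$mask)
  idx$bedrosian <- as.logical(x$bedrosian)
  utils::write.csv(idx, path, row.names = FALSE)
  jsonlite::write_json(
    list(grid_edges = x$grid$edges, band_names = x$grid$names,
         n_epochs = x$n_epochs, subject_id = x$subject_id,
         diagnostics = x$diagnostics),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_holo_spectrum
#' @export
read_holo_spectrum <- function(path) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ch <- unique(df$channel)
  nm <- meta$band_names
  a <- array(0.0, c(length(ch), length(nm), length(nm)),
             dimnames = list(ch, nm, nm))
  ix <- cbind(match(df$channel, ch), match(df$am_band, nm),
              match(df$carrier_band, nm))
  a[ix] <- df$value
  msk <- array(FALSE, dim(a), dimnames(a)); msk[ix] <- df$masked
  bed <- array(FALSE, dim(a), dimnames(a)); bed[ix] <- df$bedrosian
  g <- band_grid(2 * max(meta$grid_edges))
  new_holo_spectrum(a, msk, bed, g, meta$n_epochs,
                    as.list(meta$diagnostics),
                    subject_id = meta$subject_id)
}

#' Write a contrast result as a cell table plus JSON cluster summary
#'
#' @param x A `contrast_result`.
#' @param path CSV output path for the per-cell table (t, cluster id,
#'   significance); the cluster table and test settings go to a `.json`
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_contrast_result <- function(x, path) {
  stopifnot(inherits(x, "contrast_result"))
  utils::write.csv(summary(x), path, row.names = FALSE)
  jsonlite::write_json(
    list(clusters = x$clusters, n_perm = x$n_perm, alpha = x$alpha,
         cluster_alpha = x$cluster_alpha, threshold = x$threshold,
         seed = x$seed, n_degenerate = x$n_degenerate),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
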