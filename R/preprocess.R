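NON_SCALP <- c("A1", "A2", "VEOU", "VEOL", "HEOR", "HEOL")

#' Construct a multichannel EEG recording
#'
#' @param data Channels x samples numeric matrix (µV).
#' @param channels Channel labels (unique), length `nrow(data)`.
#' @param rate Sampling rate in Hz.
#' @param positions Optional matrix of 3-D positions in mm with labelled rows.
#' @param reference_state `"as-recorded"` or `"linked-ear"`.
#' @param subject_id Optional identifier.
#' @param condition Recording condition; analyses default to eyes-closed
#'   (`"EC"`); eyes-open recordings are accepted but tagged.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channels, rate, positions = NULL,
                          reference_state = "as-recorded",
                          subject_id = NULL, condition = "EC") {
  data <- as.matrix(data)
  stopifnot(length(channels) == nrow(data), rate > 0)
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (!all(is.finite(data))) stop("non-finite samples in recording")
  reference_state <- match.arg(reference_state, c("as-recorded", "linked-ear"))
  rownames(data) <- channels
  structure(list(data = data, channels = channels, rate = rate,
                 positions = positions, reference_state = reference_state,
                 is_scalp = !(channels %in% NON_SCALP),
                 subject_id = subject_id, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("eeg_recording:", nrow(x$data), "channels x", ncol(x$data), "samples @",
      x$rate, "Hz;", x$reference_state, "reference;",
      sum(x$is_scalp), "scalp channels\n")
  invisible(x)
}

#' Re-reference to linked ears
#'
#' Subtracts the mean of the A1 and A2 ear electrodes from every scalp
#' channel. Refuses to run twice (the operation is not idempotent once the
#' reference channels have been consumed).
#'
#' @param rec An `eeg_recording` with A1 and A2 present, in the `as-recorded`
#'   state.
#' @return The re-referenced `eeg_recording` (`reference_state = "linked-ear"`).
#' @export
rereference_linked_ears <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference_state == "linked-ear")
    stop("recording is already linked-ear referenced; refusing to re-apply")
  miss <- setdiff(c("A1", "A2"), rec$channels)
  if (length(miss)) stop("missing reference channel(s): ", paste(miss, collapse = ", "))
  ref <- (rec$data["A1", ] + rec$data["A2", ]) / 2
  out <- rec
  out$data[rec$is_scalp, ] <- sweep(rec$data[rec$is_scalp, , drop = FALSE], 2, ref)
  out$reference_state <- "linked-ear"
  out
}

#' Segment a recording into consecutive epochs
#'
#' Non-overlapping, complete epochs only; a trailing partial epoch is dropped.
#' A recording shorter than one epoch yields an empty list.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_ms Epoch duration in milliseconds (default 7000); must give a
#'   whole number of samples.
#' @param scalp_only Drop non-scalp channels (default TRUE).
#' @return List of `epoch` objects (`data`, `rate`, `channels`,
#'   `epoch_index`, `subject_id`).
#' @export
epoch_signal <- function(rec, epoch_ms = 7000, scalp_only = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_per <- epoch_ms * rec$rate / 1000
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("epoch_ms * rate / 1000 = ", n_per, " is not a whole sample count")
  n_per <- as.integer(round(n_per))
  sel <- if (scalp_only) rec$is_scalp else rep(TRUE, nrow(rec$data))
  k <- ncol(rec$data) %/% n_per
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    structure(list(
      data = rec$data[sel, ((i - 1) * n_per + 1):(i * n_per), drop = FALSE],
      rate = rec$rate, channels = rec$channels[sel],
      epoch_index = i, subject_id = rec$subject_id),
      class = "epoch")
  })
}

#' Reject artifact-contaminated epochs
#'
#' Two policies: `"threshold"` (deterministic peak-to-peak amplitude and
#' flatline limits, the default used throughout the test surface) and
#' `"external-mask"` (a precomputed keep/drop vector, e.g. from an ICA-based
#' procedure run outside this package).
#'
#' @param epochs List of `epoch` objects.
#' @param policy `"threshold"` or `"external-mask"`.
#' @param ptp_uv Peak-to-peak rejection limit in µV (any channel exceeding it
#'   rejects the epoch); default 200.
#' @param flat_uv Flatline limit: an epoch is rejected when any channel's
#'   peak-to-peak range falls below this (default 1e-6 µV).
#' @param mask For `"external-mask"`: integer indices of epochs to drop, or a
#'   logical keep vector of the same length as `epochs`.
#' @return List with `epochs` (retained, original order) and `log` (data frame
#'   with `epoch_index`, `retained`, `reason`).
#' @export
reject_artifacts <- function(epochs, policy = c("threshold", "external-mask"),
                             ptp_uv = 200, flat_uv = 1e-6, mask = NULL) {
  policy <- match.arg(policy)
  n <- length(epochs)
  reason <- rep("", n)
  if (policy == "threshold") {
    for (i in seq_len(n)) {
      ptp <- apply(epochs[[i]]$data, 1, function(v) diff(range(v)))
      if (any(ptp > ptp_uv)) reason[i] <- "amplitude"
      else if (any(ptp < flat_uv)) reason[i] <- "flatline"
    }
  } else {
    if (is.null(mask)) stop("external-mask policy requires `mask`")
    drop <- if (is.logical(mask)) {
      stopifnot(length(mask) == n)
      which(!mask)
    } else as.integer(mask)
    reason[drop] <- "external-mask"
  }
  keep <- reason == ""
  if (!any(keep))
    stop("all ", n, " epochs rejected; review the rejection thresholds")
  list(epochs = epochs[keep],
       log = data.frame(epoch_index = vapply(epochs, function(e) e$epoch_index, 0L),
                        retained = keep, reason = reason))
}

#' Optional offline mains notch filter
#'
#' Zero-phase Butterworth band-stop around the mains frequency. Off by default
#' in the pipeline: recordings from the target amplifier class carry an online
#' 60 Hz notch, and synthetic data contains no mains interference.
#'
#' @param rec An `eeg_recording`.
#' @param freq Mains frequency in Hz (default 60).
#' @param width Stop-band half-width in Hz (default 2).
#' @param order Filter order (default 4).
#' @return The filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq = 60, width = 2, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  ny <- rec$rate / 2
  if (freq + width >= ny) stop("notch band exceeds the Nyquist frequency ", ny, " Hz")
  bf <- signal::butter(order, c(freq - width, freq + width) / ny, type = "stop")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  out
}
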