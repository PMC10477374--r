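# shared fixtures: tones, tiny cohorts and hand-built spectra

RATE <- 200
TT <- seq_len(7 * RATE) / RATE          # 7 s worth of sample times
INTERIOR <- 150:1250

tone <- function(freq, amp = 1, t = TT) amp * sin(2 * pi * freq * t)

am_tone <- function(fc = 40, fam = 4, m = 0.5, t = TT)
  (1 + m * cos(2 * pi * fam * t)) * cos(2 * pi * fc * t)

# holo_spectrum object with prescribed cell values (channels x 7 x 7)
spectrum_from_values <- function(values, channels, grid = band_grid(RATE)) {
  a <- array(0.0, c(length(channels), 7, 7),
             dimnames = list(channels, grid$names, grid$names))
  a[] <- values
  holospec:::new_holo_spectrum(
    a, array(FALSE, dim(a)), array(FALSE, dim(a)), grid, 1L, list())
}

# subjects x cells matrix -> list of spectra matching a cell_adjacency
spectra_from_matrix <- function(M, adjacency, grid = band_grid(RATE)) {
  labels <- adjacency$sensors$labels
  cells <- adjacency$cells
  lapply(seq_len(nrow(M)), function(s) {
    a <- array(0.0, c(length(labels), 7, 7),
               dimnames = list(labels, grid$names, grid$names))
    a[cbind(match(cells$channel, labels), cells$am, cells$carrier)] <- M[s, ]
    holospec:::new_holo_spectrum(
      a, array(FALSE, dim(a)), array(FALSE, dim(a)), grid, 1L, list())
  })
}

scalp_positions <- function(labels = SCALP_1020) {
  mon <- load_montage()
  mon[mon$label %in% labels, ]
}

adjacency_1020 <- function(max_distance = 70) {
  cell_adjacency(band_grid(RATE), sensor_adjacency(scalp_positions(), max_distance))
}

# single-posterior-channel cohort for fast planted-effect checks
small_cohort_spec <- function(n_per_group = 6, effects = list(), seed = 1,
                              channels = c("O1", "O2", "P3", "P4"),
                              n_epochs = 1) {
  cohort_spec(group_sizes = c(A = n_per_group, B = n_per_group),
              group_effects = effects, channels = channels,
              n_epochs_per_subject = n_epochs, seed = seed)
}

fast_holo <- function(seed = 1) holo_config(ensemble = 8, seed = seed)
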