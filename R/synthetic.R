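#' Standard 10--20 montage with ear references
#'
#' 3-D electrode coordinates (mm) for the 19-channel international 10--20
#' placement plus A1/A2, from a published standard electrode coordinate set,
#' shipped as a packaged fixture. Used for the sensor-distance adjacency rule.
#'
#' @return Data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @export
load_montage <- function() {
  hit <- .holospec_cache[["montage"]]
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", "montage_1020_19.csv", package = "holospec")
  mon <- utils::read.csv(path, stringsAsFactors = FALSE)
  .holospec_cache[["montage"]] <- mon
  mon
}

#' The 19 scalp labels of the 10--20 montage, grouped by region
#' @export
SCALP_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
                "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' @rdname SCALP_1020
#' @export
REGIONS_1020 <- list(
  frontal   = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
  central   = c("C3", "Cz", "C4"),
  temporal  = c("T3", "T4", "T5", "T6"),
  parietal  = c("P3", "Pz", "P4"),
  occipital = c("O1", "O2"))

#' An oscillatory component with amplitude modulation
#'
#' The canonical AM test waveform
#' `x(t) = amplitude * [1 + am_depth * cos(2*pi*am_freq*t)] * cos(2*pi*carrier_freq*t)`
#' projected onto channels with per-channel gains.
#'
#' @param carrier_freq Carrier frequency in Hz.
#' @param am_freq Amplitude-modulation frequency in Hz; must be below
#'   `carrier_freq` (Bedrosian-admissible by construction).
#' @param am_depth Modulation depth in `[0, 1]`.
#' @param amplitude Carrier amplitude in µV.
#' @param channel_weights Named per-channel gain vector (finite); channels
#'   absent from the names get weight 0.
#' @param phase_jitter Standard deviation (radians) of the per-subject random
#'   phase perturbation.
#' @param name Optional component name.
#' @return A list of class `osc_component`.
#' @export
osc_component <- function(carrier_freq, am_freq, am_depth, amplitude,
                          channel_weights, phase_jitter = 0.2, name = NULL) {
  stopifnot(am_freq < carrier_freq, am_depth >= 0, am_depth <= 1,
            amplitude >= 0, all(is.finite(channel_weights)),
            !is.null(names(channel_weights)))
  structure(list(carrier_freq = carrier_freq, am_freq = am_freq,
                 am_depth = am_depth, amplitude = amplitude,
                 channel_weights = channel_weights,
                 phase_jitter = phase_jitter,
                 name = name %||% sprintf("fc%g_fam%g", carrier_freq, am_freq)),
            class = "osc_component")
}

# named weight vector: `value` on `on`, `base` elsewhere
region_weights <- function(channels, on, value = 1, base = 0) {
  w <- stats::setNames(rep(base, length(channels)), channels)
  w[intersect(on, channels)] <- value
  w
}

#' Default resting-state component set
#'
#' Five oscillations emulating eyes-closed resting EEG: posterior-dominant
#' alpha, frontal-midline theta, widespread delta, central beta and a weak
#' widespread gamma, each with a slow amplitude modulation below its own band.
#' Amplitudes (µV) are typical adult scalp values.
#'
#' @param channels Channel label vector (default the 19-channel montage).
#' @return List of [osc_component()] objects.
#' @export
default_components <- function(channels = SCALP_1020) {
  post <- c(REGIONS_1020$parietal, REGIONS_1020$occipital, "T5", "T6")
  list(
    osc_component(10, 0.8, 0.5, 8,
                  region_weights(channels, post, 1, 0.3), name = "alpha"),
    osc_component(6, 1.5, 0.4, 4,
                  region_weights(channels, c(REGIONS_1020$frontal, "Cz"), 1, 0.3),
                  name = "theta"),
    osc_component(3, 0.7, 0.5, 5,
                  region_weights(channels, channels, 1), name = "delta"),
    osc_component(20, 4, 0.4, 3,
                  region_weights(channels, c(REGIONS_1020$central,
                                             REGIONS_1020$parietal), 1, 0.4),
                  name = "beta"),
    osc_component(40, 6, 0.3, 1.5,
                  region_weights(channels, channels, 1), name = "gamma"))
}

#' A planted group effect on AM power
#'
#' Multiplies the AM power a group expresses at one (channel set, AM band,
#' carrier band) cell. Components whose carrier and AM frequencies fall into
#' the cell have their amplitude scaled by `sqrt(multiplier)` on the listed
#' channels, which scales the squared-amplitude (power) spectrum by
#' `multiplier`.
#'
#' @param channels Channel labels the effect applies to.
#' @param am_band,carrier_band Band names from [band_grid()] (e.g. `"theta"`,
#'   `"gamma"`); the AM band must not exceed the carrier band.
#' @param multiplier AM power multiplier, > 0.
#' @return A list of class `group_effect`.
#' @export
group_effect <- function(channels, am_band, carrier_band, multiplier) {
  g <- band_grid()
  ai <- match(am_band, g$names); ci <- match(carrier_band, g$names)
  if (is.na(ai) || is.na(ci)) stop("unknown band name")
  if (ai > ci) stop("AM band above carrier band: outside the valid triangle")
  if (multiplier <= 0) stop("multiplier must be positive")
  structure(list(channels = channels, am_band = am_band,
                 carrier_band = carrier_band, multiplier = multiplier),
            class = "group_effect")
}

#' Group effects emulating the cognitive-decline contrast pattern
#'
#' Augmented AM power of lower-frequency oscillations (delta/theta carriers)
#' over posterior regions, attenuated AM power of higher-frequency
#' oscillations (beta/gamma carriers) globally, and the dual alpha pattern:
#' increased posteriorly, decreased anteriorly. Magnitudes are
#' implementer-chosen (no effect sizes are published for these contrasts);
#' the defaults give moderate, clearly detectable effects at n = 30/group.
#'
#' @param lfo_mult AM power multiplier for delta/theta carriers posteriorly
#'   (default 1.8).
#' @param hfo_mult Multiplier for beta/gamma carriers globally (default 0.55).
#' @param alpha_post,alpha_ant Posterior / anterior alpha multipliers
#'   (default 1.4 and 0.7).
#' @return List of [group_effect()]s.
#' @export
mci_like_effects <- function(lfo_mult = 1.8, hfo_mult = 0.55,
                             alpha_post = 1.4, alpha_ant = 0.7) {
  post <- c(REGIONS_1020$parietal, REGIONS_1020$occipital, "T5", "T6")
  ant <- REGIONS_1020$frontal
  all_ch <- SCALP_1020
  list(
    group_effect(post, "Lf", "delta2", lfo_mult),
    group_effect(post, "delta1", "theta", lfo_mult),
    group_effect(all_ch, "theta", "beta", hfo_mult),
    group_effect(all_ch, "theta", "gamma", hfo_mult),
    group_effect(post, "Lf", "alpha", alpha_post),
    group_effect(ant, "Lf", "alpha", alpha_ant))
}

#' Generate a single-channel AM test signal
#'
#' `x(t) = [1 + m cos(2 pi fam t)] cos(2 pi fc t)`, the canonical test input
#' for AM-carrier analysis.
#'
#' @param carrier_freq,am_freq Carrier and AM frequencies in Hz.
#' @param am_depth Modulation depth m in `[0, 1]`.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz; must exceed twice the carrier frequency.
#' @param seed Optional seed; when given, the carrier and AM phases are drawn
#'   uniformly, otherwise both are 0.
#' @return Numeric vector of `duration * rate` samples.
#' @export
generate_am_signal <- function(carrier_freq, am_freq, am_depth, duration, rate,
                               seed = NULL) {
  if (rate <= 2 * carrier_freq)
    stop("sampling rate ", rate, " Hz violates the Nyquist bound: need rate > ",
         2 * carrier_freq, " Hz for a ", carrier_freq, " Hz carrier")
  stopifnot(am_depth >= 0, am_depth <= 1, am_freq < carrier_freq)
  n <- round(duration * rate)
  t <- seq_len(n) / rate
  ph <- c(0, 0)
  if (!is.null(seed)) ph <- with_seed(seed, runif(2, 0, 2 * pi))
  (1 + am_depth * cos(2 * pi * am_freq * t + ph[2])) *
    cos(2 * pi * carrier_freq * t + ph[1])
}

#' 1/f-like aperiodic background noise
#'
#' White noise spectrally shaped so the power spectrum follows
#' `1/f^exponent`, scaled to unit standard deviation. The DC bin is zeroed.
#'
#' @param n Number of samples.
#' @param rate Sampling rate in Hz.
#' @param exponent Aperiodic exponent (power-spectrum log-log slope magnitude).
#' @return Numeric vector of length `n`, unit variance.
#' @export
aperiodic_noise <- function(n, rate, exponent) {
  w <- rnorm(n)
  X <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * rate / n
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Specification of a synthetic EEG cohort
#'
#' @param group_sizes Named integer vector of subjects per group (each >= 2).
#' @param group_effects Named list (group -> list of [group_effect()]); groups
#'   without an entry get no effect. Every name must appear in `group_sizes`.
#' @param components List of [osc_component()]s (default
#'   [default_components()]).
#' @param montage Electrode coordinate table (default [load_montage()]).
#' @param channels Scalp channels to simulate (default all 19).
#' @param sampling_rate Hz (default 200).
#' @param epoch_ms Epoch duration (default 7000).
#' @param n_epochs_per_subject Epochs per subject (default 5).
#' @param aperiodic_exponent 1/f exponent of the background (default 1.0).
#' @param aperiodic_offset log10 of the background variance in µV²
#'   (default `log10(16)`, i.e. 4 µV SD).
#' @param sensor_noise_sd White sensor noise SD in µV (default 1).
#' @param subject_sigma SD of the per-subject log-normal component gain
#'   (default 0.2).
#' @param include_reference Add flat A1/A2 reference channels (default TRUE).
#' @param seed Integer seed; the cohort is fully deterministic given the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes, group_effects = list(),
                        components = NULL, montage = NULL,
                        channels = SCALP_1020, sampling_rate = 200,
                        epoch_ms = 7000, n_epochs_per_subject = 5,
                        aperiodic_exponent = 1.0,
                        aperiodic_offset = log10(16),
                        sensor_noise_sd = 1, subject_sigma = 0.2,
                        include_reference = TRUE, seed = 1) {
  montage <- montage %||% load_montage()
  components <- components %||% default_components(channels)
  stopifnot(all(group_sizes >= 2), !is.null(names(group_sizes)))
  if (anyDuplicated(montage$label)) stop("montage labels not unique")
  bad <- setdiff(names(group_effects), names(group_sizes))
  if (length(bad))
    stop("group_effects refer to unknown group(s): ", paste(bad, collapse = ", "))
  fmax <- max(vapply(components, function(cp) cp$carrier_freq, 0))
  if (sampling_rate <= 2 * fmax)
    stop("sampling_rate must exceed twice the fastest carrier (", fmax, " Hz)")
  miss <- setdiff(channels, montage$label)
  if (length(miss)) stop("channels missing from montage: ", paste(miss, collapse = ", "))
  structure(list(group_sizes = group_sizes, group_effects = group_effects,
                 components = components, montage = montage,
                 channels = channels, sampling_rate = sampling_rate,
                 epoch_ms = epoch_ms,
                 n_epochs_per_subject = n_epochs_per_subject,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_offset = aperiodic_offset,
                 sensor_noise_sd = sensor_noise_sd,
                 subject_sigma = subject_sigma,
                 include_reference = include_reference, seed = seed),
            class = "cohort_spec")
}

# per-channel amplitude multipliers for one component under a group's effects
effect_gain <- function(component, effects, channels, grid) {
  gain <- stats::setNames(rep(1, length(channels)), channels)
  ci <- carrier_band_index(grid, component$carrier_freq)
  ai <- am_band_index(grid, component$am_freq)
  for (e in effects) {
    if (!is.na(ci) && grid$names[ci] == e$carrier_band &&
        !is.na(ai) && grid$names[ai] == e$am_band) {
      sel <- intersect(e$channels, channels)
      gain[sel] <- gain[sel] * sqrt(e$multiplier)
    }
  }
  gain
}

#' Generate a labelled synthetic EEG cohort
#'
#' Each subject's recording is the sum of the spec's oscillatory components
#' (scaled by the subject's group multipliers and a per-subject log-normal
#' gain), an independent 1/f background per channel, and white sensor noise.
#' Deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of `eeg_recording`) and `manifest`
#'   (data frame: `subject_id`, `group`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- band_grid(spec$sampling_rate)
  rate <- spec$sampling_rate
  n <- as.integer(round(spec$epoch_ms / 1000 * rate)) * spec$n_epochs_per_subject
  t <- seq_len(n) / rate
  channels <- spec$channels
  ap_sd <- sqrt(10^spec$aperiodic_offset)
  recordings <- list()
  manifest <- data.frame(subject_id = character(), group = character())
  sidx <- 0L
  with_seed(spec$seed, {
    for (g in names(spec$group_sizes)) {
      effects <- spec$group_effects[[g]] %||% list()
      for (s in seq_len(spec$group_sizes[[g]])) {
        sidx <- sidx + 1L
        sid <- sprintf("S%03d", sidx)
        data <- matrix(0.0, length(channels), n, dimnames = list(channels, NULL))
        for (cp in spec$components) {
          gains <- effect_gain(cp, effects, channels, grid)
          subj_gain <- exp(rnorm(1, 0, spec$subject_sigma))
          ph <- runif(2, 0, 2 * pi) + rnorm(2, 0, cp$phase_jitter)
          wave <- cp$amplitude * subj_gain *
            (1 + cp$am_depth * cos(2 * pi * cp$am_freq * t + ph[2])) *
            cos(2 * pi * cp$carrier_freq * t + ph[1])
          w <- cp$channel_weights[channels]
          w[is.na(w)] <- 0
          data <- data + outer(as.numeric(w * gains), wave)
        }
        for (ch in seq_along(channels))
          data[ch, ] <- data[ch, ] +
            ap_sd * aperiodic_noise(n, rate, spec$aperiodic_exponent)
        data <- data + matrix(rnorm(length(data), 0, spec$sensor_noise_sd),
                              nrow(data), ncol(data))
        if (spec$include_reference)
          data <- rbind(data, A1 = numeric(n), A2 = numeric(n))
        pos <- as.matrix(spec$montage[match(rownames(data), spec$montage$label),
                                      c("x_mm", "y_mm", "z_mm")])
        rownames(pos) <- rownames(data)
        recordings[[sid]] <- eeg_recording(
          data, channels = rownames(data), rate = rate, positions = pos,
          subject_id = sid)
        manifest <- rbind(manifest, data.frame(subject_id = sid, group = g))
      }
    }
  })
  list(recordings = recordings, manifest = manifest)
}

#' Write a cohort to EDF files plus a manifest
#'
#' One EDF per subject and a `manifest.csv` (`subject_id`, `group`, `file`,
#' `seed`); the cohort spec is serialized alongside as YAML for provenance.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec Optional [cohort_spec()] to serialize next to the data.
#' @return The manifest data frame (with file paths), invisibly.
#' @export
write_cohort_edf <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- file.path(dir, paste0(man$subject_id, ".edf"))
  man$seed <- if (!is.null(spec)) spec$seed else NA
  for (i in seq_len(nrow(man)))
    write_edf(cohort$recordings[[man$subject_id[i]]], man$file[i])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(spec)) {
    ser <- spec
    ser$components <- lapply(ser$components, unclass)
    ser$group_effects <- lapply(ser$group_effects, function(le) lapply(le, unclass))
    ser$montage <- NULL
    yaml::write_yaml(lapply(unclass(ser), unclass), file.path(dir, "cohort_spec.yaml"))
  }
  invisible(man)
}
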