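#' Configuration for synthetic EEG-EMG recordings
#'
#' Describes a two-channel (temple EEG, jaw EMG) recording in which
#' band-limited Gaussian background activity is punctuated by movement
#' "spike" epochs: gamma-band power rises, the EMG bursts, and the
#' alpha-gamma envelope co-modulation present at rest breaks down. Band
#' components are synthesized as Butterworth-filtered white noise (not
#' sinusoids) so that covariance/correlation features are non-degenerate.
#'
#' @param sampling_rate Hz; default 4000 (the native per-channel rate;
#'   4096 is equally valid). A 500 Hz low-rate profile is used throughout
#'   the test suite for speed.
#' @param duration Record length in seconds.
#' @param event_times Onsets (s) of movement events; must be non-overlapping
#'   and fit inside the record. Default: five repetitions.
#' @param event_duration Event length in seconds (default 3).
#' @param band_powers_pre,band_powers_spike Named variance (power) per band
#'   outside/inside events. Defaults give a 4x gamma surge during spikes.
#' @param emg_burst_gain Multiplicative EMG amplitude gain during events.
#' @param noise_sd SD of additive broadband measurement noise.
#' @param comodulation_depth Depth of the slow common amplitude modulation
#'   shared by the EEG bands at rest (gamma decouples from it during
#'   events, producing the correlation decline). Set 0 for a strictly
#'   Gaussian record.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A `synth_config` list.
#' @export
synth_config <- function(sampling_rate = 4000,
                         duration = 35,
                         event_times = c(5, 10.5, 16, 21.5, 27),
                         event_duration = 3,
                         band_powers_pre = c(alpha = 1, beta = 0.6,
                                             gamma = 0.25,
                                             emg_low = 0.3, emg_high = 0.3),
                         band_powers_spike = c(alpha = 1, beta = 0.8,
                                               gamma = 1,
                                               emg_low = 0.3,
                                               emg_high = 0.3),
                         emg_burst_gain = 3,
                         noise_sd = 0.1,
                         comodulation_depth = 0.35,
                         seed = 1) {
  check_number(sampling_rate, "sampling_rate", min = 0, strict = TRUE)
  check_number(duration, "duration", min = 0, strict = TRUE)
  check_number(event_duration, "event_duration", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(emg_burst_gain, "emg_burst_gain", min = 0)
  check_number(comodulation_depth, "comodulation_depth", min = 0)
  if (any(band_powers_pre < 0) || any(band_powers_spike < 0)) {
    abort("Band powers (variances) must be >= 0.")
  }
  # Nyquist check against the configured EEG/EMG band edges.
  if (sampling_rate <= 2 * 100) {
    abort(sprintf(
      "sampling_rate (%g Hz) must exceed twice the highest band edge (100 Hz).",
      sampling_rate))
  }
  event_times <- sort(as.numeric(event_times))
  if (length(event_times)) {
    if (any(event_times < 0) ||
        any(event_times + event_duration > duration + 1e-9)) {
      abort("Event intervals must lie within [0, duration].")
    }
    if (length(event_times) > 1L &&
        any(diff(event_times) < event_duration - 1e-9)) {
      abort("Event intervals overlap; space onsets by at least event_duration.")
    }
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 event_times = event_times, event_duration = event_duration,
                 band_powers_pre = band_powers_pre,
                 band_powers_spike = band_powers_spike,
                 emg_burst_gain = emg_burst_gain, noise_sd = noise_sd,
                 comodulation_depth = comodulation_depth,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Smoothstep event gate: 1 inside events, 0 outside, raised-cosine ramps.
event_gate <- function(n, rate, event_times, event_duration,
                       ramp_s = 0.1) {
  gate <- numeric(n)
  t <- (seq_len(n) - 1) / rate
  for (onset in event_times) {
    off <- onset + event_duration
    ramp_up <- t >= onset - ramp_s & t < onset
    ramp_dn <- t >= off & t < off + ramp_s
    gate[t >= onset & t < off] <- 1
    gate[ramp_up] <- pmax(gate[ramp_up],
                          0.5 * (1 - cos(pi * (t[ramp_up] - onset + ramp_s) / ramp_s)))
    gate[ramp_dn] <- pmax(gate[ramp_dn],
                          0.5 * (1 + cos(pi * (t[ramp_dn] - off) / ramp_s)))
  }
  gate
}

# Unit-variance band-limited Gaussian noise (zero vector if the band
# carries no power so degenerate configs stay exactly zero).
unit_band_noise <- function(n, band, rate) {
  x <- bandpass(rnorm(n), band, rate)
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

# Slow positive amplitude modulator: 1 + depth * lowpassed unit noise,
# floored so gains stay positive.
slow_modulator <- function(n, rate, depth, cutoff_hz = 1.5) {
  if (depth == 0) return(rep(1, n))
  slow <- bandpass(rnorm(n), band_definition("slow", NA, cutoff_hz), rate)
  s <- sd(slow)
  if (s == 0) return(rep(1, n))
  pmax(0.05, 1 + depth * slow / s)
}

#' Simulate a two-channel EEG-EMG recording
#'
#' Generates band-limited Gaussian activity per band with the configured
#' pre/spike powers, a shared slow amplitude co-modulation of the EEG
#' bands at rest (from which gamma decouples during movement events), an
#' EMG burst gain during events, and additive broadband noise. Events are
#' written into the recording's annotations. Identical config and seed
#' give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return An `ssi_recording` with channels `eeg` and `emg`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rate <- config$sampling_rate
  n <- as.integer(round(config$duration * rate))
  with_seed(config$seed, {
    gate <- event_gate(n, rate, config$event_times, config$event_duration)
    eeg_defs <- eeg_bands()
    m_common <- slow_modulator(n, rate, config$comodulation_depth)
    m_gamma_spike <- slow_modulator(n, rate, config$comodulation_depth)

    band_component <- function(name, band) {
      pre <- config$band_powers_pre[[name]] %||% 0
      spike <- config$band_powers_spike[[name]] %||% pre
      if (pre == 0 && spike == 0) return(numeric(n))
      u <- unit_band_noise(n, band, rate)
      amp <- sqrt(pre) * (1 - gate) + sqrt(spike) * gate
      mod <- if (name == "gamma") {
        m_common * (1 - gate) + m_gamma_spike * gate
      } else {
        m_common
      }
      u * amp * mod
    }

    eeg <- band_component("alpha", eeg_defs$alpha) +
      band_component("beta", eeg_defs$beta) +
      band_component("gamma", eeg_defs$gamma)
    if (config$noise_sd > 0) eeg <- eeg + config$noise_sd * rnorm(n)

    emg_defs <- phoneme_bands()
    burst <- 1 + (config$emg_burst_gain - 1) * gate
    emg_part <- function(name, band) {
      pre <- config$band_powers_pre[[name]] %||% 0
      if (pre == 0) return(numeric(n))
      sqrt(pre) * unit_band_noise(n, band, rate)
    }
    emg <- (emg_part("emg_low", emg_defs$emg_low) +
              emg_part("emg_high", emg_defs$emg_high)) * burst
    if (config$noise_sd > 0) emg <- emg + config$noise_sd * rnorm(n)

    ann <- if (length(config$event_times)) {
      tibble::tibble(onset = config$event_times,
                     duration = config$event_duration,
                     label = "movement")
    } else {
      NULL
    }
    new_recording(cbind(eeg = eeg, emg = emg),
                  channel_roles = c("EEG", "EMG"),
                  sampling_rate = rate, annotations = ann)
  })
}

#' Per-class phoneme signal templates
#'
#' Each silently mouthed phoneme is modelled as a class-specific temporal
#' activation envelope (a sum of Gaussian bumps) modulating the low/high
#' EMG components and the EEG gamma component: "M" (bilabial nasal) a
#' single broad mid-record hump, "A" (open vowel) a sustained
#' double-bump activation, "D" (alveolar stop) a sharp early burst.
#' Class identity is carried mainly by envelope shape and timing, with
#' near-equal component gains, so that amplitude jitter produces
#' realistic between-class overlap. Gains are dimensionless multiples of
#' the baseline band amplitude; centers/widths in seconds.
#'
#' @return Named list of per-class template parameter lists.
#' @export
phoneme_templates <- function() {
  list(
    M = list(emg_low_gain = 2.8, emg_high_gain = 1.2, gamma_gain = 1.6,
             centers = 1.00, widths = 0.32),
    A = list(emg_low_gain = 1.6, emg_high_gain = 2.6, gamma_gain = 2.4,
             centers = c(0.72, 1.30), widths = c(0.20, 0.20)),
    D = list(emg_low_gain = 2.4, emg_high_gain = 3.0, gamma_gain = 2.6,
             centers = 0.70, widths = 0.10)
  )
}

#' Configuration for a synthetic phoneme dataset
#'
#' Defaults reproduce the study dataset structure: 3 phonemes (M, A, D) x
#' 2 subjects x 10 samples = 60 recordings, each a short two-channel
#' record containing one silent mouthing event. The default 500 Hz / 2 s
#' profile is the package's computational profile; rate and duration are
#' free parameters.
#'
#' @param n_per_class_per_subject Samples per phoneme per subject
#'   (default 10).
#' @param classes Phoneme labels (default M, A, D).
#' @param n_subjects Number of subjects (default 2).
#' @param sampling_rate Hz (default 500).
#' @param duration Seconds per sample (default 2).
#' @param templates Named per-class template list covering every class;
#'   see [phoneme_templates()].
#' @param subject_offset_scale SD of the per-subject log-gain offsets and
#'   of the per-subject envelope time shift (s).
#' @param sample_jitter SD of the per-sample log-gain jitter and time
#'   jitter (s) that makes classes overlap.
#' @param noise_sd Additive broadband noise SD.
#' @param seed Global seed; fans out to per-sample child seeds so any
#'   subset is reproducible.
#' @return A `phoneme_synth_config`.
#' @export
phoneme_synth_config <- function(n_per_class_per_subject = 10,
                                 classes = c("M", "A", "D"),
                                 n_subjects = 2,
                                 sampling_rate = 500,
                                 duration = 2,
                                 templates = phoneme_templates(),
                                 subject_offset_scale = 0.2,
                                 sample_jitter = 0.4,
                                 noise_sd = 1,
                                 seed = 1) {
  n_per_class_per_subject <- check_count(n_per_class_per_subject,
                                         "n_per_class_per_subject")
  n_subjects <- check_count(n_subjects, "n_subjects")
  classes <- as.character(classes)
  missing_tpl <- setdiff(classes, names(templates))
  if (length(missing_tpl)) {
    abort(sprintf("No template for class(es): %s.",
                  paste(missing_tpl, collapse = ", ")))
  }
  structure(list(n_per_class_per_subject = n_per_class_per_subject,
                 classes = classes, n_subjects = n_subjects,
                 sampling_rate = sampling_rate, duration = duration,
                 templates = templates,
                 subject_offset_scale = subject_offset_scale,
                 sample_jitter = sample_jitter, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phoneme_synth_config")
}

# One phoneme recording from resolved (template x subject x sample) draws.
simulate_phoneme_recording <- function(config, template, subject_fx,
                                       label, subject, sample_seed) {
  rate <- config$sampling_rate
  n <- as.integer(round(config$duration * rate))
  with_seed(sample_seed, {
    jit <- config$sample_jitter
    gain_j <- exp(rnorm(3, 0, jit * 0.6)) # per-component amplitude jitter
    t_shift <- rnorm(1, 0, jit * 0.3)     # timing jitter (s)
    width_j <- exp(rnorm(1, 0, jit * 0.5))
    t <- (seq_len(n) - 1) / rate
    centers <- template$centers + subject_fx$t_shift + t_shift
    widths <- template$widths * width_j
    env <- rowSums(vapply(seq_along(centers), function(b) {
      exp(-((t - centers[b])^2) / (2 * widths[b]^2))
    }, numeric(n)))

    defs <- phoneme_bands()
    gl <- template$emg_low_gain * subject_fx$gain[1] * gain_j[1]
    gh <- template$emg_high_gain * subject_fx$gain[2] * gain_j[2]
    gg <- template$gamma_gain * subject_fx$gain[3] * gain_j[3]

    emg <- (0.3 + gl * env) * unit_band_noise(n, defs$emg_low, rate) +
      (0.3 + gh * env) * unit_band_noise(n, defs$emg_high, rate)
    eeg <- 0.8 * unit_band_noise(n, defs$alpha_beta, rate) +
      (0.3 + gg * env) * unit_band_noise(n, defs$gamma, rate)
    if (config$noise_sd > 0) {
      emg <- emg + config$noise_sd * rnorm(n)
      eeg <- eeg + config$noise_sd * rnorm(n)
    }
    onset <- max(0, min(centers - 2 * widths))
    dur <- min(config$duration - onset, max(centers + 2 * widths) - onset)
    new_recording(cbind(eeg = eeg, emg = emg),
                  channel_roles = c("EEG", "EMG"), sampling_rate = rate,
                  annotations = tibble::tibble(onset = onset, duration = dur,
                                               label = "mouthing"),
                  subject = subject, label = label)
  })
}

#' Simulate a labelled phoneme dataset
#'
#' Generates `n_subjects x length(classes) x n_per_class_per_subject`
#' recordings (60 under the defaults) with class-distinct envelope and
#' band signatures and subject-specific gain/timing offsets. A pure
#' function of (config, seed): the global seed fans out to per-sample
#' child seeds, so any subset is reproducible.
#'
#' @param config A [phoneme_synth_config()].
#' @return An `ssi_dataset`: list with `recordings` (list of
#'   `ssi_recording`) and `index` (tibble `id`, `label`, `subject`).
#' @export
simulate_phoneme_dataset <- function(config) {
  stopifnot(inherits(config, "phoneme_synth_config"))
  subject_fx <- lapply(seq_len(config$n_subjects), function(s) {
    with_seed(child_seed(config$seed, 1000000 + s), {
      list(gain = exp(rnorm(3, 0, config$subject_offset_scale)),
           t_shift = rnorm(1, 0, config$subject_offset_scale))
    })
  })
  grid <- expand.grid(sample = seq_len(config$n_per_class_per_subject),
                      class = config$classes,
                      subject = seq_len(config$n_subjects),
                      stringsAsFactors = FALSE)
  recordings <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cls <- grid$class[i]
    sub <- grid$subject[i]
    recordings[[i]] <- simulate_phoneme_recording(
      config, config$templates[[cls]], subject_fx[[sub]],
      label = cls, subject = paste0("S", sub),
      sample_seed = child_seed(config$seed, i))
  }
  index <- tibble::tibble(id = seq_len(nrow(grid)),
                          label = grid$class,
                          subject = paste0("S", grid$subject))
  structure(list(recordings = recordings, index = index, config = config),
            class = "ssi_dataset")
}

#' @export
print.ssi_dataset <- function(x, ...) {
  counts <- table(x$index$label)
  cat(sprintf("<ssi_dataset> %d recording(s): %s\n", nrow(x$index),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' @export
length.ssi_dataset <- function(x) length(x$recordings)
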