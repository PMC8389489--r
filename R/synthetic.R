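#' Frequency-band table used by the synthetic generator
#'
#' Canonical EEG rhythms: delta, theta, alpha, beta and a band-limited gamma.
#' The generator keeps gamma below 45 Hz so that the planted content survives
#' the default 0.5-40 Hz band-pass of the preprocessing stage.
#' @return data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
synth_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 12, 30), hi = c(4, 8, 12, 30, 45))
}

#' Configuration for the synthetic EEG generator
#'
#' Defines a multi-subject, multi-trial EEG-like dataset with a known ground
#' truth: a pink-noise (1/f^alpha) background, per-band oscillations, 50 Hz
#' line noise, frontal blink transients mirrored into two synthetic EOG
#' channels, and a class-dependent band-power effect confined to
#' `informative_channels` in `informative_bands`. Informative channels share
#' a single oscillation draw (frequency, phase and a slow amplitude
#' envelope) per band and trial, so that their co-activation - not just
#' their marginal power - distinguishes them from the rest of the montage.
#'
#' @param n_subjects,n_trials counts.
#' @param n_channels number of scalp channels (4-32, named from the
#'   32-channel standard montage in layout order).
#' @param fs_raw raw sampling rate in Hz.
#' @param duration trial length in seconds; `duration * fs_raw` must be an
#'   integer sample count.
#' @param informative_channels channel names carrying the planted effect.
#' @param informative_bands subset of delta/theta/alpha/beta/gamma.
#' @param effect_size power ratio (> 0) between the high and low class for
#'   the planted band oscillations; 1 plants no effect.
#' @param line_noise_amp amplitude of the 50 Hz mains component.
#' @param blink_rate blink events per minute.
#' @param blink_amp peak amplitude of the blink transient at the EOG site.
#' @param noise_spectrum_exponent slope alpha of the 1/f^alpha background.
#' @param background_sd standard deviation of the background noise.
#' @param osc_amplitudes named amplitudes of the five band oscillations.
#' @param spatial_mixing neighbour-leakage coefficient emulating volume
#'   conduction (0 disables).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 4, n_trials = 8, n_channels = 32,
                         fs_raw = 512, duration = 60,
                         informative_channels = c("F3", "F4", "T7"),
                         informative_bands = "alpha",
                         effect_size = 3, line_noise_amp = 0.5,
                         blink_rate = 4, blink_amp = 60,
                         noise_spectrum_exponent = 1, background_sd = 1,
                         osc_amplitudes = c(delta = 1.5, theta = 1, alpha = 1,
                                            beta = 0.8, gamma = 0.4),
                         spatial_mixing = 0.2, seed = 1) {
  stop_if(!is_count(n_subjects) || !is_count(n_trials), "counts must be positive integers")
  stop_if(!is_count(n_channels) || n_channels < 4, "n_channels must be >= 4")
  stop_if(!is_number(duration) || duration <= 0, "duration must be positive")
  stop_if(!is_number(fs_raw) || fs_raw <= 0, "fs_raw must be positive")
  stop_if(abs(duration * fs_raw - round(duration * fs_raw)) > 1e-9,
          "duration * fs_raw must be an integer sample count")
  stop_if(!is_number(effect_size) || effect_size <= 0, "effect_size must be > 0")
  stop_if(!is_number(blink_rate) || blink_rate < 0, "blink_rate must be >= 0")
  stop_if(!is_number(line_noise_amp) || line_noise_amp < 0, "line_noise_amp must be >= 0")
  montage <- load_montage("standard_1020_32")
  stop_if(n_channels > length(montage$channel_names),
          "n_channels exceeds the built-in 32-channel montage")
  channels <- montage$channel_names[seq_len(n_channels)]
  stop_if(!all(informative_channels %in% channels),
          "informative_channels must be a subset of the generated channel set")
  bands <- synth_bands()$band
  stop_if(!all(informative_bands %in% bands),
          "informative_bands must be in ", paste(bands, collapse = "/"))
  stop_if(!all(bands %in% names(osc_amplitudes)),
          "osc_amplitudes must name all five bands")
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 n_channels = n_channels, channels = channels,
                 fs_raw = fs_raw, duration = duration,
                 informative_channels = informative_channels,
                 informative_bands = informative_bands,
                 effect_size = effect_size, line_noise_amp = line_noise_amp,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 noise_spectrum_exponent = noise_spectrum_exponent,
                 background_sd = background_sd,
                 osc_amplitudes = osc_amplitudes[bands],
                 spatial_mixing = spatial_mixing, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^alpha noise of length n at rate fs, scaled to standard deviation sd.
pink_noise <- function(n, fs, alpha, sd_target) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  spec[n:(n - nf + 2)] <- Conj(z[seq_len(nf - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s * sd_target
}

# 300 ms biphasic raised-cosine blink pulse sampled at fs.
blink_pulse <- function(fs) {
  nh <- max(2L, round(0.15 * fs))
  lobe <- function(k) 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  c(lobe(nh), -0.5 * lobe(nh))
}

# One band oscillation: amplitude-modulated sinusoid with random frequency,
# phase and a slow sinusoidal envelope.
band_osc <- function(tgrid, lo, hi, amp) {
  f <- stats::runif(1, lo, hi)
  phase <- stats::runif(1, 0, 2 * pi)
  fenv <- stats::runif(1, 0.05, 0.2)
  penv <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.3 * sin(2 * pi * fenv * tgrid + penv)
  amp * env * sin(2 * pi * f * tgrid + phase)
}

#' Generate a synthetic multi-subject EEG dataset
#'
#' Every trial carries a hidden binary state (balanced within each subject).
#' Self-reported valence and arousal ratings on the 1-9 scale are drawn
#' consistently with the state (high state: Uniform(6, 9); low state:
#' Uniform(1, 4)), so both targets are recoverable from the planted band
#' power effect. When `effect_size = 1` the classes are statistically
#' indistinguishable.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_dataset` with elements
#'   `recordings` (nested list: `recordings[[subject]][[trial]]` is an
#'   [eeg_recording()] including two synthetic EOG channels),
#'   `ground_truth` (informative channels/bands, planted power-ratio matrix,
#'   per subject-trial labels and ratings) and `config`.
#' @export
generate_dataset <- function(config) {
  stop_if(!inherits(config, "synth_config"), "config must come from synth_config()")
  cfg <- config
  with_seed(cfg$seed, {
    n <- round(cfg$duration * cfg$fs_raw)
    tgrid <- (seq_len(n) - 1) / cfg$fs_raw
    bands <- synth_bands()
    montage <- load_montage("standard_1020_32")
    pos <- montage$positions[match(cfg$channels, montage$positions$name), ]
    frontal_w <- exp(-sqrt(pos$x^2 + (pos$y - 0.9)^2) / 0.3)
    adj <- montage_subset(montage, cfg$channels)$adjacency
    pulse <- blink_pulse(cfg$fs_raw)
    labels <- NULL
    recordings <- vector("list", cfg$n_subjects)
    names(recordings) <- paste0("s", sprintf("%02d", seq_len(cfg$n_subjects)))

    for (s in seq_len(cfg$n_subjects)) {
      states <- sample(rep(c("low", "high"), length.out = cfg$n_trials))
      trials <- vector("list", cfg$n_trials)
      names(trials) <- paste0("t", sprintf("%02d", seq_len(cfg$n_trials)))
      for (tr in seq_len(cfg$n_trials)) {
        state <- states[tr]
        X <- matrix(0, cfg$n_channels, n, dimnames = list(cfg$channels, NULL))
        # shared oscillation draws for the informative set, one per band;
        # effect_size = 1 plants nothing at all - neither the class power
        # shift nor the co-activation sharing - so it is a true null
        shared <- lapply(seq_len(nrow(bands)), function(b)
          band_osc(tgrid, bands$lo[b], bands$hi[b], cfg$osc_amplitudes[b]))
        for (c in seq_len(cfg$n_channels)) {
          ch <- cfg$channels[c]
          x <- pink_noise(n, cfg$fs_raw, cfg$noise_spectrum_exponent,
                          cfg$background_sd)
          informative <- ch %in% cfg$informative_channels &&
            cfg$effect_size != 1
          for (b in seq_len(nrow(bands))) {
            band <- bands$band[b]
            if (informative) {
              osc <- shared[[b]]
              if (band %in% cfg$informative_bands && state == "high")
                osc <- osc * sqrt(cfg$effect_size)
            } else {
              osc <- band_osc(tgrid, bands$lo[b], bands$hi[b],
                              cfg$osc_amplitudes[b])
            }
            x <- x + osc
          }
          X[c, ] <- x
        }
        if (cfg$spatial_mixing > 0) {
          deg <- pmax(rowSums(adj), 1)
          X <- X + cfg$spatial_mixing * (adj %*% X) / deg
        }
        if (cfg$line_noise_amp > 0) {
          mains <- cfg$line_noise_amp * sin(2 * pi * 50 * tgrid +
                                              stats::runif(1, 0, 2 * pi))
          X <- X + matrix(mains, cfg$n_channels, n, byrow = TRUE)
        }
        blink_train <- rep(0, n)
        n_blinks <- stats::rpois(1, cfg$blink_rate * cfg$duration / 60)
        if (n_blinks > 0) {
          starts <- sort(sample.int(max(1L, n - length(pulse)), n_blinks,
                                    replace = TRUE))
          for (st in starts) {
            idx <- st:(st + length(pulse) - 1L)
            blink_train[idx] <- blink_train[idx] + cfg$blink_amp * pulse
          }
        }
        X <- X + outer(frontal_w, blink_train)
        eog <- rbind(EOG1 = blink_train + 0.3 * stats::rnorm(n),
                     EOG2 = -0.8 * blink_train + 0.3 * stats::rnorm(n))
        rec <- eeg_recording(rbind(X, eog), fs = cfg$fs_raw,
                             channel_names = c(cfg$channels, "EOG1", "EOG2"),
                             eog_channels = c("EOG1", "EOG2"),
                             subject_id = names(recordings)[s],
                             trial_id = names(trials)[tr],
                             provenance = "synthetic")
        trials[[tr]] <- rec
        rate_hi <- function() stats::runif(1, 6, 9)
        rate_lo <- function() stats::runif(1, 1, 4)
        labels <- rbind(labels, data.frame(
          subject = names(recordings)[s], trial = names(trials)[tr],
          state = state,
          valence_class = state, arousal_class = state,
          valence_rating = if (state == "high") rate_hi() else rate_lo(),
          arousal_rating = if (state == "high") rate_hi() else rate_lo(),
          stringsAsFactors = FALSE))
      }
      recordings[[s]] <- trials
    }
    planted <- matrix(1, nrow(bands), cfg$n_channels,
                      dimnames = list(bands$band, cfg$channels))
    planted[cfg$informative_bands, cfg$informative_channels] <- cfg$effect_size
    structure(list(recordings = recordings,
                   ground_truth = list(
                     informative_channels = cfg$informative_channels,
                     informative_bands = cfg$informative_bands,
                     planted_effect = planted, labels = labels),
                   config = cfg),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synth_dataset> %d subjects x %d trials x %d channels, %g s @ %g Hz\n",
              cfg$n_subjects, cfg$n_trials, cfg$n_channels, cfg$duration, cfg$fs_raw))
  cat(sprintf("  planted: %s in %s (power ratio %g)\n",
              paste(cfg$informative_channels, collapse = ","),
              paste(cfg$informative_bands, collapse = ","), cfg$effect_size))
  invisible(x)
}
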