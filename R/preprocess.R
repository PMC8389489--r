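# Apply a zero-phase (forward-backward) IIR filter to every channel.
# The channel mean is removed before filtering and restored afterwards so
# that DC offsets neither leak through filter edge transients nor get
# destroyed by band-stop designs.
filtfilt_rows <- function(X, b, a, keep_mean = TRUE, fs = NULL) {
  t(apply(X, 1, function(x) {
    m <- mean(x)
    y <- signal::filtfilt(b, a, x - m)
    if (keep_mean) y + m else y
  }))
}

#' Notch (band-stop) filter at the mains frequency
#'
#' Removes power-line interference with a zero-phase quality-30 IIR notch
#' (biquad, applied forward and backward). The default 50 Hz matches the
#' European mains standard; pass 60 for recordings made on 60 Hz mains.
#'
#' @param rec an [eeg_recording()].
#' @param freq notch centre frequency in Hz (must be below Nyquist).
#' @param q quality factor of the notch.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  stop_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  nyq <- rec$fs / 2
  stop_if(!is_number(freq) || freq <= 0 || freq >= nyq,
          sprintf("notch frequency %g Hz must lie in (0, Nyquist = %g Hz)", freq, nyq))
  w0 <- 2 * pi * freq / rec$fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  rec$samples <- filtfilt_rows(rec$samples, b, a, keep_mean = TRUE, fs = rec$fs)
  rec$provenance <- c(rec$provenance, sprintf("notch(%gHz,Q=%g)", freq, q))
  rec
}

#' Band-pass filter
#'
#' Zero-phase Butterworth band-pass (order 4, applied forward and backward,
#' so 8th-order magnitude response). The default 0.5-40 Hz band is the
#' conventional EEG analysis band and doubles as the anti-alias filter for
#' the 128 Hz down-sampling stage.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 40) {
  stop_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  nyq <- rec$fs / 2
  stop_if(!is_number(lo) || !is_number(hi) || lo <= 0 || lo >= hi || hi >= nyq,
          sprintf("invalid band [%g, %g] Hz; need 0 < lo < hi < Nyquist = %g Hz",
                  lo, hi, nyq))
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  rec$samples <- filtfilt_rows(rec$samples, bf$b, bf$a, keep_mean = FALSE, fs = rec$fs)
  rec$provenance <- c(rec$provenance, sprintf("bandpass(%g-%gHz)", lo, hi))
  rec
}

#' Remove ocular (blink) components by ICA
#'
#' Decomposes the scalp channels with FastICA and zeroes components whose
#' time course correlates (|Pearson r| >= `threshold`) with the blink
#' reference: the bipolar EOG derivation when EOG channels are present, and
#' otherwise the mean of the prefrontal channels (Fp1/Fp2). At most 30% of
#' the components are removed (the strongest correlates first). If ICA fails
#' to converge the input is returned unchanged with a warning and a
#' provenance flag.
#'
#' @param rec an [eeg_recording()] with at least 8 scalp channels.
#' @param threshold absolute correlation threshold for rejection.
#' @return The reconstructed recording (EOG channels untouched).
#' @export
remove_ocular <- function(rec, threshold = 0.7) {
  stop_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  scalp <- scalp_channels(rec)
  stop_if(length(scalp) < 8, "ocular removal needs at least 8 scalp channels")
  X <- rec$samples[scalp, , drop = FALSE]
  ref <- if (length(rec$eog_channels) >= 2) {
    rec$samples[rec$eog_channels[1], ] - rec$samples[rec$eog_channels[2], ]
  } else if (length(rec$eog_channels) == 1) {
    rec$samples[rec$eog_channels[1], ]
  } else {
    pf <- intersect(c("Fp1", "Fp2"), scalp)
    stop_if(length(pf) == 0,
            "no EOG channels and no prefrontal (Fp1/Fp2) channels to reference")
    colMeans(rec$samples[pf, , drop = FALSE])
  }
  ica <- fastica(X)
  r <- abs(apply(ica$sources, 1, function(s) suppressWarnings(stats::cor(s, ref))))
  r[is.na(r)] <- 0
  cand <- which(r >= threshold)
  if (!ica$converged || !all(ica$comp_converged[cand])) {
    warning("FastICA did not converge; returning recording unchanged")
    rec$provenance <- c(rec$provenance, "ica(non-convergent,skipped)")
    return(rec)
  }
  max_rm <- floor(0.3 * nrow(X))
  if (length(cand) > max_rm) cand <- order(r, decreasing = TRUE)[seq_len(max_rm)]
  if (length(cand) > 0) {
    keep <- setdiff(seq_len(nrow(ica$sources)), cand)
    Xc <- ica$mixing[, keep, drop = FALSE] %*% ica$sources[keep, , drop = FALSE]
    rec$samples[scalp, ] <- Xc + ica$center
  }
  rec$provenance <- c(rec$provenance,
                      sprintf("ica(removed=%d/%d)", length(cand), nrow(X)))
  rec
}

#' Down-sample a recording
#'
#' Polyphase rational-ratio resampling to `fs_out`. The default target of
#' 128 Hz follows common affect-recognition practice; the 0.5-40 Hz
#' band-pass applied beforehand already provides anti-alias protection
#' (40 Hz < 64 Hz Nyquist at the target rate). `fs_out = fs` is the
#' identity.
#'
#' @param rec an [eeg_recording()].
#' @param fs_out target sampling rate in Hz (must not exceed `fs`).
#' @return The resampled recording.
#' @export
downsample <- function(rec, fs_out = 128) {
  stop_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  stop_if(!is_number(fs_out) || fs_out <= 0, "fs_out must be positive")
  stop_if(fs_out > rec$fs, sprintf("fs_out (%g) exceeds input rate (%g)", fs_out, rec$fs))
  if (fs_out == rec$fs) return(rec)
  frac <- rational_fraction(fs_out / rec$fs)
  p <- frac[1]; q <- frac[2]
  Y <- t(apply(rec$samples, 1, function(x) signal::resample(x, p, q)))
  out <- rec
  out$samples <- Y
  rownames(out$samples) <- rec$channel_names
  out$fs <- fs_out
  out$provenance <- c(rec$provenance, sprintf("downsample(%gHz)", fs_out))
  out
}

# Small rational approximation of a ratio in (0, 1].
rational_fraction <- function(ratio, max_den = 10000) {
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio ", ratio, " as a small fraction",
       call. = FALSE)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the scalp channels into consecutive non-overlapping windows of `w`
#' seconds; a trailing partial window is discarded. EOG channels are
#' dropped here: they exist only as the blink reference for
#' [remove_ocular()] and are not feature sources.
#'
#' @param rec an [eeg_recording()].
#' @param w epoch length in seconds; `w * fs` must be an integer and the
#'   recording must be at least `w` seconds long.
#' @return An object of class `eeg_epochs`: list with `epochs`
#'   (array, epochs x channels x samples), `w`, `fs`, `channel_names`,
#'   identifiers and `provenance`.
#' @export
epoch_recording <- function(rec, w) {
  stop_if(!inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  stop_if(!is_number(w) || w <= 0, "w must be positive")
  len <- w * rec$fs
  stop_if(abs(len - round(len)) > 1e-9, "w * fs must be an integer sample count")
  len <- round(len)
  n <- ncol(rec$samples)
  stop_if(n < len, sprintf("recording (%g s) is shorter than one epoch (%g s)",
                           n / rec$fs, w))
  scalp <- scalp_channels(rec)
  n_ep <- floor(n / len)
  ep <- array(NA_real_, dim = c(n_ep, length(scalp), len),
              dimnames = list(NULL, scalp, NULL))
  X <- rec$samples[scalp, , drop = FALSE]
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- X[, ((e - 1) * len + 1):(e * len)]
  }
  structure(list(epochs = ep, w = w, fs = rec$fs, channel_names = scalp,
                 subject_id = rec$subject_id, trial_id = rec$trial_id,
                 provenance = c(rec$provenance, sprintf("epoch(w=%gs)", w))),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (w = %g s @ %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$w, x$fs))
  cat(sprintf("  subject: %s  trial: %s\n", x$subject_id, x$trial_id))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Fixed order: notch, band-pass, ocular-component removal, down-sampling,
#' epoching.
#'
#' @param rec an [eeg_recording()].
#' @param w epoch length in seconds.
#' @param notch_hz mains frequency (NULL skips the notch).
#' @param band length-2 band-pass edges in Hz (NULL skips).
#' @param fs_out target sampling rate (NULL skips down-sampling).
#' @param ica logical: perform ocular-component removal.
#' @return An `eeg_epochs` object.
#' @export
preprocess <- function(rec, w = 2, notch_hz = 50, band = c(0.5, 40),
                       fs_out = 128, ica = TRUE) {
  if (!is.null(notch_hz)) rec <- notch_filter(rec, notch_hz)
  if (!is.null(band)) rec <- bandpass_filter(rec, band[1], band[2])
  if (isTRUE(ica)) rec <- remove_ocular(rec)
  if (!is.null(fs_out)) rec <- downsample(rec, fs_out)
  epoch_recording(rec, w)
}
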