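#' Construct an EEG recording
#'
#' A recording bundles a channel-by-time voltage matrix with its sampling
#' rate and channel metadata. Optional electro-oculogram (EOG) channels are
#' carried alongside the scalp channels and used as the blink reference by
#' [remove_ocular()].
#'
#' @param samples numeric matrix, channels x time points.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector naming the rows of `samples`.
#' @param eog_channels names of rows that are EOG (not scalp) channels.
#' @param subject_id,trial_id identifiers carried through the pipeline.
#' @param provenance character vector of processing steps already applied.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_names = rownames(samples),
                          eog_channels = character(), subject_id = NA,
                          trial_id = NA, provenance = character()) {
  samples <- as.matrix(samples)
  stop_if(!is_number(fs) || fs <= 0, "fs must be a positive number")
  stop_if(is.null(channel_names) || length(channel_names) != nrow(samples),
          "channel_names must name every row of samples")
  stop_if(anyDuplicated(channel_names) > 0, "channel names must be unique")
  stop_if(anyNA(samples), "samples must not contain NaN/NA")
  stop_if(!all(eog_channels %in% channel_names),
          "eog_channels must be a subset of channel_names")
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 eog_channels = eog_channels, subject_id = subject_id,
                 trial_id = trial_id, provenance = provenance),
            class = "eeg_recording")
}

#' Names of scalp (non-EOG) channels of a recording
#' @param rec an `eeg_recording`.
#' @return character vector.
#' @export
scalp_channels <- function(rec) {
  setdiff(rec$channel_names, rec$eog_channels)
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- ncol(x$samples)
  cat(sprintf("<eeg_recording> %d channels (%d EOG) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), length(x$eog_channels), n, x$fs, n / x$fs))
  cat(sprintf("  subject: %s  trial: %s\n", x$subject_id, x$trial_id))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs
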