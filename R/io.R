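#' Write a dataset to a directory tree
#'
#' One sub-directory per subject containing a channels x samples CSV per
#' trial and a `meta.json` sidecar (sampling rate, channel names, EOG
#' channels, ratings); the ground truth is written at the top level.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- dataset$ground_truth$labels
  for (subj in names(dataset$recordings)) {
    sdir <- file.path(dir, subj)
    dir.create(sdir, showWarnings = FALSE)
    trials <- dataset$recordings[[subj]]
    rec1 <- trials[[1]]
    meta <- list(fs = rec1$fs, channel_names = rec1$channel_names,
                 eog_channels = rec1$eog_channels,
                 trials = names(trials),
                 ratings = labels[labels$subject == subj,
                                  c("trial", "valence_rating", "arousal_rating")])
    jsonlite::write_json(meta, file.path(sdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    for (tr in names(trials)) {
      utils::write.csv(t(trials[[tr]]$samples),
                       file.path(sdir, paste0(tr, ".csv")), row.names = FALSE)
    }
  }
  gt <- dataset$ground_truth
  jsonlite::write_json(
    list(informative_channels = gt$informative_channels,
         informative_bands = gt$informative_bands,
         planted_effect = gt$planted_effect, labels = gt$labels),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one recording
#'
#' `format = "synth_dir"` expects the trial CSV written by
#' [write_dataset()] with its `meta.json` sidecar in the same directory;
#' `format = "edf"` reads a 16-bit European Data Format file (annotations
#' ignored; all signals must share one sampling rate).
#'
#' @param path path to the trial CSV (synth_dir) or the EDF file.
#' @param format `"synth_dir"` or `"edf"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("synth_dir", "edf")) {
  format <- match.arg(format)
  stop_if(!file.exists(path), "file not found: ", path)
  if (format == "edf") return(read_edf(path))
  meta_path <- file.path(dirname(path), "meta.json")
  stop_if(!file.exists(meta_path),
          "missing meta.json sidecar next to ", basename(path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  X <- t(as.matrix(utils::read.csv(path, check.names = FALSE)))
  eeg_recording(X, fs = meta$fs, channel_names = meta$channel_names,
                eog_channels = meta$eog_channels %||% character(),
                subject_id = basename(dirname(path)),
                trial_id = sub("\\.csv$", "", basename(path)),
                provenance = "read(synth_dir)")
}

#' Read a full dataset directory
#'
#' @param dir directory written by [write_dataset()].
#' @return A `synth_dataset`-shaped list (`recordings`, `ground_truth`).
#' @export
read_dataset <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.json")
  stop_if(!file.exists(gt_path), "missing ground_truth.json in ", dir)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  gt$informative_channels <- as.character(gt$informative_channels)
  subjects <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  recordings <- lapply(subjects, function(subj) {
    meta <- jsonlite::read_json(file.path(dir, subj, "meta.json"),
                                simplifyVector = TRUE)
    recs <- lapply(meta$trials, function(tr)
      read_recording(file.path(dir, subj, paste0(tr, ".csv")), "synth_dir"))
    stats::setNames(recs, meta$trials)
  })
  names(recordings) <- subjects
  structure(list(recordings = recordings,
                 ground_truth = list(
                   informative_channels = gt$informative_channels,
                   informative_bands = gt$informative_bands,
                   planted_effect = gt$planted_effect,
                   labels = gt$labels)),
            class = "synth_dataset")
}

# ---- minimal 16-bit EDF support -------------------------------------------

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' Minimal European Data Format writer (one data record per second,
#' per-channel physical scaling). Intended for interoperability checks,
#' not archival.
#'
#' @param rec an [eeg_recording()]; `fs` must be an integer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stop_if(abs(rec$fs - round(rec$fs)) > 1e-9, "EDF export needs an integer fs")
  fs <- round(rec$fs)
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  stop_if(n_rec < 1, "recording shorter than one EDF data record (1 s)")
  X <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  # physical limits live in 8-char ASCII header fields; round them first and
  # scale with the rounded values so reader and writer use identical gains
  pmin_ <- floor(apply(X, 1, min) * 1000) / 1000
  pmax_ <- ceiling(apply(X, 1, max) * 1000) / 1000
  flat <- pmax_ - pmin_ < 1e-3
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste("X X X", rec$subject_id), 80),
    pad_field(paste("Startdate X X X X trial", rec$trial_id), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    labels = pad_field(rec$channel_names, 16),
    transducer = rep(pad_field("", 80), ns),
    dim = rep(pad_field("uV", 8), ns),
    pmin = pad_field(sprintf("%.3f", pmin_), 8),
    pmax = pad_field(sprintf("%.3f", pmax_), 8),
    dmin = rep(pad_field(dmin, 8), ns),
    dmax = rep(pad_field(dmax, 8), ns),
    prefilter = rep(pad_field("", 80), ns),
    nsamp = rep(pad_field(fs, 8), ns),
    reserved = rep(pad_field("", 32), ns))
  for (fd in fields) writeChar(paste(fd, collapse = ""), con, eos = NULL)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- X[ch, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmax(dmin, pmin(dmax, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80)); recording_field <- trimws(rd(80))
  rd(8); rd(8)                            # date, time
  rd(8); rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  stop_if(is.na(ns) || ns < 1, "malformed EDF header: bad signal count field")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  vapply(seq_len(ns), function(i) rd(80), "")
  nsamp <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  vapply(seq_len(ns), function(i) rd(32), "")
  stop_if(length(unique(nsamp)) != 1,
          "malformed/unsupported EDF: signals have differing samples-per-record")
  fs <- nsamp[1] / dur
  X <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[ch], size = 2, endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      X[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
    }
  }
  eeg_recording(X, fs = fs, channel_names = make.unique(labels),
                subject_id = patient, trial_id = recording_field,
                provenance = "read(edf)")
}
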