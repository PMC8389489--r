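#' Preprocess a dataset and extract the feature battery
#'
#' Runs the fixed preprocessing chain (notch, band-pass, ocular removal,
#' down-sampling, epoching) and the 54-feature extraction on every
#' subject x trial recording of a dataset, and flattens each trial's
#' feature tensor into an epochs x (channel.feature) matrix for the
#' evaluation stage.
#'
#' @param dataset a `synth_dataset` from [generate_dataset()] (or any list
#'   with the same `recordings` / `ground_truth$labels` layout, e.g. from
#'   [read_dataset()]).
#' @param w epoch length in seconds.
#' @param notch_hz,band,fs_out,ica passed to [preprocess()].
#' @return A `study` list: `features` (nested feature tensors), `flat`
#'   (nested flattened matrices), `labels` (with binary classes),
#'   `channel_names`, `feature_names`, `w`, `fs`.
#' @export
extract_study_features <- function(dataset, w = 2, notch_hz = 50,
                                   band = c(0.5, 40), fs_out = 128,
                                   ica = TRUE) {
  labels <- dataset$ground_truth$labels
  labels$valence_class <- as.character(binarize_ratings(labels$valence_rating))
  labels$arousal_class <- as.character(binarize_ratings(labels$arousal_rating))
  features <- lapply(dataset$recordings, function(trials) {
    lapply(trials, function(rec) {
      ep <- preprocess(rec, w = w, notch_hz = notch_hz, band = band,
                       fs_out = fs_out, ica = ica)
      extract_features(ep)
    })
  })
  flat <- lapply(features, function(trials) lapply(trials, flatten_tensor))
  ft1 <- features[[1]][[1]]
  structure(list(features = features, flat = flat, labels = labels,
                 channel_names = dimnames(ft1)[[2]],
                 feature_names = dimnames(ft1)[[3]],
                 w = w, fs = attr(ft1, "fs")),
            class = "eeg_study")
}

# epochs x (channel.feature) matrix with channel-major column names.
flatten_tensor <- function(ft) {
  d <- dim(ft)
  m <- matrix(ft, d[1], d[2] * d[3])
  colnames(m) <- as.vector(outer(dimnames(ft)[[2]], dimnames(ft)[[3]],
                                 function(ch, f) paste(ch, f, sep = ".")))
  m
}

#' Attach unsupervised per-subject rankings to a study
#'
#' Computes, for every subject, the Laplacian-score feature ranking (over
#' all of the subject's epoch x channel feature vectors) and the
#' affinity-propagation channel ranking (per trial, aggregated by mean
#' rank). Both are unsupervised and use only that subject's own data, so
#' they can be computed once and re-aggregated inside cross-validation
#' folds without leakage.
#'
#' @param study from [extract_study_features()].
#' @param montage an `eeg_montage` covering the study's channels.
#' @param kappa_max hop cap for the spatial discount.
#' @param k,t Laplacian graph parameters ([knn_similarity()]).
#' @param damping,preference AP parameters ([affinity_propagation()]).
#' @param alpha consistency/strength blend ([rank_channels()]).
#' @return The study with `channel_rankings`, `feature_rankings`,
#'   `trial_channel_rankings` and `delta` added.
#' @export
rank_study <- function(study, montage = load_montage("standard_1020_32"),
                       kappa_max = 2, k = 5, t = "mean_sq_dist",
                       damping = 0.9, preference = NULL, alpha = 0.5) {
  sub_m <- montage_subset(montage, study$channel_names)
  delta <- neighboring_matrix(sub_m, kappa_max)
  study$delta <- delta
  study$trial_channel_rankings <- lapply(study$features, function(trials)
    lapply(trials, rank_trial_channels, delta = delta, damping = damping,
           preference = preference, alpha = alpha))
  study$channel_rankings <- lapply(study$trial_channel_rankings,
                                   aggregate_channel_rankings)
  study$feature_rankings <- lapply(study$features, rank_subject_features,
                                   k = k, t = t)
  study
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("<eeg_study> %d subjects x %d trials, %d channels, w = %g s @ %g Hz\n",
              length(x$features), length(x$features[[1]]),
              length(x$channel_names), x$w, x$fs))
  cat(sprintf("  rankings: %s\n",
              if (is.null(x$channel_rankings)) "not computed (rank_study)" else "computed"))
  invisible(x)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Convenience wrapper: generate (or accept) a dataset, extract features,
#' compute unsupervised rankings and evaluate with leave-one-subject-out
#' nested cross-validation.
#'
#' @param config a [synth_config()] or an existing `synth_dataset`.
#' @param w epoch length in seconds.
#' @param fractions channel fractions for the sweep.
#' @param targets affect dimensions to evaluate.
#' @param seed evaluation seed (fold assignment).
#' @param ... further arguments to [nested_cv()].
#' @return list with `dataset`, `study` and `report`.
#' @export
run_study <- function(config, w = 2, fractions = seq(0.1, 1, by = 0.1),
                      targets = c("valence", "arousal"), seed = 1, ...) {
  dataset <- if (inherits(config, "synth_dataset")) config else generate_dataset(config)
  study <- extract_study_features(dataset, w = w)
  study <- rank_study(study)
  report <- nested_cv(study, targets = targets, fractions = fractions,
                      seed = seed, ...)
  list(dataset = dataset, study = study, report = report)
}
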