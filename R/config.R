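#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline with its default:
#' preprocessing (notch frequency, band edges, target rate, epoch length,
#' ICA switch), Laplacian graph (k, kernel-width mode, kept fraction),
#' channel selection (hop cap, AP damping/preference, consistency blend,
#' sweep fractions), MI refinement (bins, kept columns) and evaluation
#' (grid, inner folds, seed).
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    synth = list(n_subjects = 4, n_trials = 8, n_channels = 32, fs_raw = 512,
                 duration = 60, informative_channels = c("F3", "F4", "T7"),
                 informative_bands = "alpha", effect_size = 3,
                 line_noise_amp = 0.5, blink_rate = 4, seed = 1),
    preprocess = list(notch_hz = 50, band = c(0.5, 40), fs_out = 128,
                      w = 2, ica = TRUE),
    laplacian = list(k = 5, t_mode = "mean_sq_dist", top_fraction = 1 / 3),
    channel_select = list(kappa_max = 2, damping = 0.9,
                          preference_mode = "median", alpha = 0.5,
                          fractions = seq(0.1, 1, by = 0.1)),
    mi = list(bins = 8, k_features = 24, threshold_mode = "midpoint"),
    evaluate = list(inner_folds = 3, seed = 1,
                    targets = c("valence", "arousal")),
    montage = "standard_1020_32"
  ), class = "pipeline_config")
}

#' Validate a configuration against the defaults
#'
#' Unknown keys (at either level) are rejected so that typos fail loudly;
#' known keys override the defaults.
#'
#' @param cfg nested list of overrides.
#' @return merged `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  base <- default_config()
  unknown_top <- setdiff(names(cfg), names(base))
  stop_if(length(unknown_top) > 0,
          "unknown config section(s): ", paste(unknown_top, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.list(base[[sec]])) {
      unknown <- setdiff(names(cfg[[sec]]), names(base[[sec]]))
      stop_if(length(unknown) > 0,
              sprintf("unknown key(s) in '%s': %s", sec,
                      paste(unknown, collapse = ", ")))
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else {
      base[[sec]] <- cfg[[sec]]
    }
  }
  base
}

#' Load a YAML configuration file
#'
#' @param path YAML file with any subset of the keys of
#'   [default_config()].
#' @return merged, validated `pipeline_config`.
#' @export
load_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}
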