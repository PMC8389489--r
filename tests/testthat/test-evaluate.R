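# Compact hand-built study: toy feature tensors with a planted class shift,
# bypassing signal preprocessing so the CV machinery can be exercised fast.
make_toy_study <- function(n_subjects = 6, n_trials = 2, n_epochs = 6,
                           effect = 2, seed = 1) {
  set.seed(seed)
  n_ch <- 8
  ch <- paste0("r", seq_len(n_ch))
  ang <- 2 * pi * (seq_len(n_ch) - 1) / n_ch
  montage <- montage_from_positions(
    data.frame(name = ch, x = cos(ang), y = sin(ang)))
  fn <- paste0("f", sprintf("%02d", 1:12))
  subjects <- paste0("s", sprintf("%02d", seq_len(n_subjects)))
  trials <- paste0("t", sprintf("%02d", seq_len(n_trials)))
  features <- list(); labels <- NULL
  for (s in subjects) {
    states <- sample(rep(c("low", "high"), length.out = n_trials))
    features[[s]] <- list()
    for (tr in seq_len(n_trials)) {
      ft <- array(rnorm(n_epochs * n_ch * 12), c(n_epochs, n_ch, 12),
                  dimnames = list(NULL, ch, fn))
      if (states[tr] == "high") ft[, c("r1", "r2"), 1:3] <-
          ft[, c("r1", "r2"), 1:3] + effect
      features[[s]][[trials[tr]]] <- structure(
        ft, fs = 128, w = 2, class = c("feature_tensor", "array"))
      labels <- rbind(labels, data.frame(
        subject = s, trial = trials[tr], state = states[tr],
        valence_class = states[tr], arousal_class = states[tr],
        stringsAsFactors = FALSE))
    }
  }
  study <- structure(list(
    features = features,
    flat = lapply(features, function(tt) lapply(tt, eegsel:::flatten_tensor)),
    labels = labels, channel_names = ch, feature_names = fn,
    w = 2, fs = 128), class = "eeg_study")
  rank_study(study, montage = montage)
}

test_that("F1 follows the precision/recall formula", {
  expect_equal(f1_score(c("high", "low"), c("high", "low")), 1)
  expect_equal(f1_score(c("high", "low"), c("low", "high")), 0)
  # TP = 8, FP = 2, FN = 4 -> 8 / (8 + 0.5 * 6)
  y_true <- c(rep("high", 12), rep("low", 8))
  y_pred <- c(rep("high", 8), rep("low", 4), rep("high", 2), rep("low", 6))
  expect_equal(f1_score(y_true, y_pred), 8 / 11, tolerance = 1e-12)
  # no predicted positives -> 0 by convention
  expect_equal(f1_score(c("high", "low"), c("low", "low")), 0)
})

test_that("the hyperparameter grid enumerates the published configurations", {
  g <- default_svm_grid()
  expect_setequal(unique(g$cost), c(0.025, 0.5, 1, 10, 100))
  expect_setequal(unique(g$kernel), c("linear", "radial"))
  expect_setequal(unique(g$gamma[g$kernel == "radial"]),
                  c(0.001, 2, 10, 50, 100))
  expect_equal(sum(g$kernel == "linear"), 5)
  expect_equal(sum(g$kernel == "radial"), 25)
  expect_true(all(which(g$kernel == "linear") < which(g$kernel == "radial")))
})

test_that("nested CV is deterministic and leaves the held-out subject untouched", {
  study <- make_toy_study(seed = 5)
  grid <- default_svm_grid()[c(3, 8), ]   # small grid: linear C=1, rbf
  r1 <- suppressWarnings(nested_cv(study, targets = "valence", fractions = 0.5,
                                   grid = grid, mi_k = 12, seed = 9))
  r2 <- suppressWarnings(nested_cv(study, targets = "valence", fractions = 0.5,
                                   grid = grid, mi_k = 12, seed = 9))
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  audit <- attr(r1, "audit")
  expect_true(nrow(audit) > 0)
  for (i in seq_len(nrow(audit))) {
    expect_false(grepl(audit$test_subject[i], audit$selection_subjects[i]))
  }
  # every subject appears exactly once as test per stimulus
  tab <- table(r1$stimulus, r1$test_subject)
  expect_true(all(tab == 1))
})

test_that("nested CV recovers a planted effect and collapses under shuffling", {
  study <- make_toy_study(n_subjects = 8, n_trials = 4, effect = 3, seed = 6)
  grid <- default_svm_grid()[c(2, 3), ]
  rep_true <- suppressWarnings(
    nested_cv(study, targets = "valence", fractions = 0.5, grid = grid,
              mi_k = 12, seed = 2))
  s_true <- summary(rep_true)
  expect_gt(s_true$pooled_f1, 0.7)

  rep_shuf <- suppressWarnings(
    nested_cv(study, targets = "valence", fractions = 0.5, grid = grid,
              mi_k = 12, seed = 2, shuffle_labels = TRUE))
  s_shuf <- summary(rep_shuf)
  expect_lt(abs(s_shuf$pooled_f1 - 0.5), 0.18)
  expect_gt(s_true$pooled_f1, s_shuf$pooled_f1 + 0.2)
})

test_that("the sweep report produces one row of box statistics per fraction", {
  set.seed(3)
  fake <- expand.grid(target = c("valence", "arousal"),
                      stimulus = paste0("t", 1:3),
                      test_subject = paste0("s", 1:5),
                      fraction = seq(0.1, 1, by = 0.1),
                      stringsAsFactors = FALSE)
  fake$f1 <- runif(nrow(fake))
  fake$accuracy <- runif(nrow(fake))
  rep <- structure(fake, class = c("eval_report", "data.frame"))
  sw <- fraction_sweep_report(rep)
  expect_equal(nrow(sw), 2 * 10)
  expect_equal(sum(sw$target == "valence"), 10)
  expect_true(all(c("q1", "median", "q3", "lo", "hi") %in% names(sw)))
  expect_true(all(sw$q1 <= sw$median & sw$median <= sw$q3))
})
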