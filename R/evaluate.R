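#' F1 score for the positive (high) class
#'
#' Harmonic mean of precision and recall. When nothing is predicted
#' positive the score is 0 by convention.
#'
#' @param y_true,y_pred binary labels (factors or characters).
#' @param positive label of the positive class.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(y_true, y_pred, positive = "high") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stop_if(length(y_true) != length(y_pred), "labels must align")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  if (tp + fp + fn == 0) return(0)
  tp / (tp + 0.5 * (fp + fn))
}

#' Default SVM hyperparameter grid
#'
#' Cost `C` in {.025, .5, 1, 10, 100} for both the linear and RBF kernels,
#' with RBF kernel scale in {0.001, 2, 10, 50, 100}. Linear rows come
#' first, so exact ties in the inner cross-validation resolve to the
#' (more stable) linear kernel.
#'
#' @return data.frame with columns `kernel`, `cost`, `gamma` (NA for
#'   linear rows).
#' @export
default_svm_grid <- function() {
  costs <- c(0.025, 0.5, 1, 10, 100)
  scales <- c(0.001, 2, 10, 50, 100)
  rbind(data.frame(kernel = "linear", cost = costs, gamma = NA_real_),
        expand.grid(kernel = "radial", cost = costs, gamma = scales,
                    stringsAsFactors = FALSE))
}

# Macro-averaged F1 (mean of the class-wise F1s). Used as the inner
# model-selection metric: a degenerate always-one-class predictor scores
# ~0.33 on balanced data instead of gaming the positive-class F1.
macro_f1 <- function(y_true, y_pred) {
  (f1_score(y_true, y_pred, positive = "high") +
     f1_score(y_true, y_pred, positive = "low")) / 2
}

# Fit an SVM for one grid row and predict.
fit_predict_svm <- function(Xtr, ytr, Xte, kernel, cost, gamma) {
  cw <- length(ytr) / (2 * table(ytr))
  args <- list(x = Xtr, y = ytr, kernel = kernel, cost = cost,
               class.weights = cw, scale = TRUE)
  if (kernel == "radial") args$gamma <- gamma
  fit <- suppressWarnings(do.call(e1071::svm, args))
  stats::predict(fit, Xte)
}

# Stratified assignment of subjects to inner folds, deterministic given seed.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    folds <- integer(length(labels))
    for (lev in unique(labels)) {
      idx <- sample(which(labels == lev))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    folds
  })
}

#' Leave-one-subject-out nested cross-validation
#'
#' Subject-independent evaluation of the full selection pipeline. The
#' outer loop holds out one subject per stimulus. All selection steps see
#' training subjects only: the per-subject unsupervised rankings of the
#' training subjects are aggregated to choose the channel subset (at each
#' requested fraction) and the Laplacian-ranked feature subset, and the
#' supervised MI best-k refinement and the SVM grid search run inside a
#' stratified inner cross-validation over training subjects. The winning
#' configuration is refit on all training subjects and scored on the
#' held-out subject's epochs (epoch-level F1/accuracy, plus a
#' majority-vote subject-level prediction).
#'
#' @param study a ranked study from [rank_study()].
#' @param targets which affect dimensions to evaluate.
#' @param fractions channel fractions to sweep.
#' @param grid hyperparameter grid (see [default_svm_grid()]).
#' @param lap_fraction fraction of Laplacian-ranked features kept.
#' @param mi_k number of feature columns kept by the MI refinement.
#' @param bins MI discretisation bins.
#' @param inner_folds inner CV folds over training subjects.
#' @param seed seed for the stratified fold assignment.
#' @param shuffle_labels permutation control: shuffle the subject x trial
#'   label table before evaluation (chance-level reference).
#' @return An `eval_report`: data.frame of per-(stimulus, fold, target,
#'   fraction) results with attributes `majority` (subject-level votes) and
#'   `audit` (fold bookkeeping proving the held-out subject was excluded
#'   from selection).
#' @export
nested_cv <- function(study, targets = c("valence", "arousal"),
                      fractions = seq(0.1, 1, by = 0.1),
                      grid = default_svm_grid(), lap_fraction = 1 / 3,
                      mi_k = 24, bins = 8, inner_folds = 3, seed = 1,
                      shuffle_labels = FALSE) {
  stop_if(is.null(study$channel_rankings),
          "study has no rankings; call rank_study() first")
  subjects <- names(study$features)
  stop_if(length(subjects) < 4, "need at least 4 subjects")
  stimuli <- unique(study$labels$trial)
  labels <- study$labels
  if (shuffle_labels) {
    labels <- with_seed(derive_seed(seed, 999), {
      idx <- sample(nrow(labels))
      labels[c("valence_class", "arousal_class")] <-
        labels[idx, c("valence_class", "arousal_class")]
      labels
    })
  }
  flat <- study$flat   # [[subject]][[trial]] epochs x (channel.feature)
  results <- NULL
  audit <- NULL
  majority <- NULL
  epoch_preds <- NULL
  for (target in targets) {
    lab_col <- paste0(target, "_class")
    for (stim in stimuli) {
      stim_labels <- labels[labels$trial == stim, ]
      lab_of <- stats::setNames(stim_labels[[lab_col]], stim_labels$subject)
      for (test_subj in subjects) {
        train_subj <- setdiff(subjects, test_subj)
        ytr_subj <- factor(lab_of[train_subj], levels = c("low", "high"))
        if (nlevels(droplevels(ytr_subj)) < 2) {
          warning(sprintf("stimulus %s / held-out %s: single-class training labels; fold skipped",
                          stim, test_subj))
          next
        }
        ch_rank <- aggregate_channel_rankings(study$channel_rankings[train_subj])
        ft_rank <- aggregate_feature_rankings(study$feature_rankings[train_subj])
        lap_feats <- select_top_features(ft_rank, lap_fraction)
        audit <- rbind(audit, data.frame(
          target = target, stimulus = stim, test_subject = test_subj,
          selection_subjects = paste(sort(train_subj), collapse = "+"),
          stringsAsFactors = FALSE))
        epochs_of <- function(subj) flat[[subj]][[stim]]
        ytr_ep <- factor(rep(lab_of[train_subj],
                             vapply(train_subj, function(s) nrow(epochs_of(s)), 1L)),
                         levels = c("low", "high"))
        yte_ep <- factor(rep(lab_of[test_subj], nrow(epochs_of(test_subj))),
                         levels = c("low", "high"))
        folds <- stratified_folds(as.character(ytr_subj),
                                  min(inner_folds, length(train_subj)),
                                  derive_seed(seed, match(stim, stimuli) * 131 +
                                                match(test_subj, subjects)))
        for (fraction in fractions) {
          chans <- select_top_fraction(ch_rank, fraction)
          cols <- as.vector(outer(lap_feats, chans,
                                  function(f, ch) paste(ch, f, sep = ".")))
          Xtr <- do.call(rbind, lapply(train_subj, function(s)
            epochs_of(s)[, cols, drop = FALSE]))
          Xte <- epochs_of(test_subj)[, cols, drop = FALSE]
          k_use <- min(mi_k, ncol(Xtr))
          # inner CV: grid search with MI selection inside each fold;
          # validation predictions are pooled across folds before scoring so
          # that single-class validation subjects cannot distort the F1
          inner_true <- character(0)
          inner_pred <- vector("list", nrow(grid))
          for (f in seq_len(max(folds))) {
            inner_tr <- train_subj[folds != f]
            inner_va <- train_subj[folds == f]
            if (length(inner_va) == 0 || length(inner_tr) == 0) next
            yin <- factor(rep(lab_of[inner_tr],
                              vapply(inner_tr, function(s) nrow(epochs_of(s)), 1L)),
                          levels = c("low", "high"))
            if (nlevels(droplevels(yin)) < 2) next
            Xin <- do.call(rbind, lapply(inner_tr, function(s)
              epochs_of(s)[, cols, drop = FALSE]))
            Xva <- do.call(rbind, lapply(inner_va, function(s)
              epochs_of(s)[, cols, drop = FALSE]))
            yva <- factor(rep(lab_of[inner_va],
                              vapply(inner_va, function(s) nrow(epochs_of(s)), 1L)),
                          levels = c("low", "high"))
            if (nrow(Xin) < 10) next   # too few epochs for the MI estimate
            sel <- suppressWarnings(select_best_k(Xin, yin, k_use, bins))
            keep <- if (length(sel$kept)) sel$kept else colnames(Xin)[seq_len(k_use)]
            inner_true <- c(inner_true, as.character(yva))
            for (g in seq_len(nrow(grid))) {
              pred <- fit_predict_svm(Xin[, keep, drop = FALSE], yin,
                                      Xva[, keep, drop = FALSE],
                                      grid$kernel[g], grid$cost[g], grid$gamma[g])
              inner_pred[[g]] <- c(inner_pred[[g]], as.character(pred))
            }
          }
          pooled_f1 <- vapply(inner_pred, function(p)
            if (length(p)) macro_f1(inner_true, p) else NA_real_, numeric(1))
          best <- if (all(is.na(pooled_f1))) 1L else which.max(pooled_f1)
          # ties: first row (linear kernel first)
          if (nrow(Xtr) < 10) {
            warning(sprintf("stimulus %s / held-out %s: fewer than 10 training epochs; fold skipped",
                            stim, test_subj))
            next
          }
          sel <- suppressWarnings(select_best_k(Xtr, ytr_ep, k_use, bins))
          keep <- if (length(sel$kept)) sel$kept else colnames(Xtr)[seq_len(k_use)]
          pred <- fit_predict_svm(Xtr[, keep, drop = FALSE], ytr_ep,
                                  Xte[, keep, drop = FALSE],
                                  grid$kernel[best], grid$cost[best],
                                  grid$gamma[best])
          vote <- names(which.max(table(pred)))
          epoch_preds <- rbind(epoch_preds, data.frame(
            target = target, stimulus = stim, subject = test_subj,
            fraction = fraction, true = as.character(yte_ep),
            pred = as.character(pred), stringsAsFactors = FALSE))
          results <- rbind(results, data.frame(
            target = target, stimulus = stim, test_subject = test_subj,
            fraction = fraction,
            f1 = f1_score(yte_ep, pred),
            accuracy = mean(as.character(pred) == as.character(yte_ep)),
            kernel = grid$kernel[best], cost = grid$cost[best],
            gamma = grid$gamma[best],
            n_channels = length(chans), n_features = length(keep),
            channels = paste(chans, collapse = "|"),
            stringsAsFactors = FALSE))
          majority <- rbind(majority, data.frame(
            target = target, stimulus = stim, subject = test_subj,
            fraction = fraction, true = as.character(lab_of[test_subj]),
            pred = vote, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(results)) {
    warning("no evaluable fold (single-class training labels throughout); returning an empty report")
    results <- data.frame(target = character(), stimulus = character(),
                          test_subject = character(), fraction = numeric(),
                          f1 = numeric(), accuracy = numeric(),
                          kernel = character(), cost = numeric(),
                          gamma = numeric(), n_channels = integer(),
                          n_features = integer(), channels = character())
  }
  structure(results, majority = majority, audit = audit,
            epoch_predictions = epoch_preds,
            seed = seed, shuffled = shuffle_labels,
            class = c("eval_report", "data.frame"))
}

#' Summarise an evaluation report
#'
#' Per target and channel fraction: the pooled epoch-level F1 over all
#' leave-one-subject-out predictions (the headline number - per-fold F1 is
#' degenerate because a fold holds a single subject with a single true
#' label), the mean epoch accuracy, and the majority-vote (subject-level)
#' F1.
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return data.frame of aggregates.
#' @export
summary.eval_report <- function(object, ...) {
  maj <- attr(object, "majority")
  ep <- attr(object, "epoch_predictions")
  agg <- NULL
  for (target in unique(object$target)) {
    for (fraction in unique(object$fraction)) {
      sub <- object[object$target == target & object$fraction == fraction, ]
      m <- maj[maj$target == target & maj$fraction == fraction, ]
      e <- ep[ep$target == target & ep$fraction == fraction, ]
      agg <- rbind(agg, data.frame(
        target = target, fraction = fraction,
        pooled_f1 = f1_score(e$true, e$pred),
        mean_accuracy = mean(sub$accuracy),
        majority_f1 = f1_score(m$true, m$pred),
        n_folds = nrow(sub)))
    }
  }
  agg
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds (%d stimuli, %d subjects, %d fractions)%s\n",
              nrow(x), length(unique(x$stimulus)),
              length(unique(x$test_subject)), length(unique(x$fraction)),
              if (isTRUE(attr(x, "shuffled"))) " [label-shuffled control]" else ""))
  print(summary(x))
  invisible(x)
}

#' Channel-fraction sweep statistics
#'
#' Box-plot statistics (quartiles, whisker bounds) of the epoch-level F1
#' per target and channel fraction, in the layout used to compare
#' fractions 10%..100%. Monotonicity over fractions is not asserted
#' anywhere: performance typically plateaus once the informative channels
#' are included.
#'
#' @param report an `eval_report`.
#' @return data.frame with one row per target x fraction.
#' @export
fraction_sweep_report <- function(report) {
  out <- NULL
  for (target in unique(report$target)) {
    for (fraction in sort(unique(report$fraction))) {
      f1 <- report$f1[report$target == target & report$fraction == fraction]
      q <- stats::quantile(f1, c(0.25, 0.5, 0.75), names = FALSE)
      out <- rbind(out, data.frame(
        target = target, fraction = fraction, n = length(f1),
        q1 = q[1], median = q[2], q3 = q[3],
        lo = min(f1), hi = max(f1), mean = mean(f1)))
    }
  }
  out
}

#' @export
plot.eval_report <- function(x, target = unique(x$target)[1], ...) {
  sub <- x[x$target == target, ]
  graphics::boxplot(f1 ~ fraction, data = sub,
                    xlab = "channel fraction", ylab = "epoch-level F1",
                    main = sprintf("%s (LOSO)", target), ...)
  invisible(x)
}
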