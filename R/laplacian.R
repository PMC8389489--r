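#' k-nearest-neighbour similarity graph
#'
#' Builds the heat-kernel similarity matrix underlying the Laplacian score:
#' `S_ij = exp(-||x_i - x_j||^2 / t)` when samples i and j are connected in
#' the symmetrised kNN graph (edge when i is among the k nearest neighbours
#' of j *or* vice versa), 0 otherwise, with a zero diagonal.
#'
#' @param X numeric matrix, samples x features.
#' @param k neighbourhood size (must be < number of samples).
#' @param t kernel width; `"mean_sq_dist"` (default) sets it to the mean
#'   squared distance over connected pairs, or pass a positive number.
#' @return symmetric similarity matrix with attributes `t` (resolved width)
#'   and `adjacency`.
#' @export
knn_similarity <- function(X, k = 5, t = "mean_sq_dist") {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if(!is_count(k), "k must be a positive integer")
  stop_if(k >= n, sprintf("k = %d must be smaller than the number of samples (%d)", k, n))
  D2 <- as.matrix(stats::dist(X))^2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn <- order(D2[i, ])[-1][seq_len(k)]   # self excluded, ties by index
    adj[i, nn] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  t_val <- if (identical(t, "mean_sq_dist")) mean(D2[adj]) else {
    stop_if(!is_number(t) || t <= 0, "t must be 'mean_sq_dist' or a positive number")
    t
  }
  S <- exp(-D2 / t_val) * adj
  diag(S) <- 0
  structure(S, t = t_val, k = k, adjacency = adj)
}

#' Laplacian score feature ranking
#'
#' Scores each feature r as
#' `L_r = sum_ij (f_ri - f_rj)^2 S_ij / Var(f_r)`: features that vary
#' smoothly over the sample-similarity graph relative to their overall
#' variance score low, and lower scores rank higher. Zero-variance features
#' receive an infinite sentinel score and rank last. Ties are broken by
#' feature name. The graph Laplacian `L = D - S` is exposed as an attribute
#' for inspection.
#'
#' @param X numeric matrix, samples x features (columns named).
#' @param S similarity matrix from [knn_similarity()].
#' @return A `feature_ranking`: list with `scores` (named, ascending order
#'   is better), `order` (feature names sorted best-first), `flagged`
#'   (zero-variance features) and `params`.
#' @export
laplacian_score <- function(X, S) {
  X <- as.matrix(X)
  stop_if(nrow(X) != nrow(S) || nrow(S) != ncol(S),
          "X and S have incompatible shapes")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  Xc <- sweep(X, 2, colMeans(X))
  Dg <- diag(rowSums(S))
  L <- Dg - S
  num <- 2 * colSums(Xc * (L %*% Xc))   # sum_ij (f_i - f_j)^2 S_ij
  v <- apply(X, 2, stats::var)
  scores <- ifelse(v > 0, num / v, Inf)
  names(scores) <- colnames(X)
  ord <- names(scores)[order(scores, names(scores))]
  structure(list(scores = scores, order = ord,
                 flagged = names(scores)[!is.finite(scores)],
                 params = list(k = attr(S, "k"), t = attr(S, "t")),
                 laplacian = L),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<feature_ranking> %d features (lower score = better)\n",
              length(x$scores)))
  top <- utils::head(x$order, n)
  cat("  best:", paste(top, collapse = ", "), "\n")
  if (length(x$flagged))
    cat("  flagged zero-variance:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Unsupervised per-subject feature ranking
#'
#' Pools every epoch x channel feature vector of one subject's trials into
#' a sample matrix (as many rows as epochs times channels), z-scores the
#' feature columns for the distance computation, builds the kNN heat-kernel
#' graph and returns the Laplacian-score ranking of the 54 features.
#'
#' @param tensors list of `feature_tensor` objects (one per trial of the
#'   same subject).
#' @param k,t passed to [knn_similarity()].
#' @param max_samples optional cap on the number of pooled samples (rows are
#'   subsampled deterministically when exceeded, keeping the graph tractable).
#' @return A `feature_ranking`.
#' @export
rank_subject_features <- function(tensors, k = 5, t = "mean_sq_dist",
                                  max_samples = 2000) {
  stop_if(!length(tensors), "need at least one feature tensor")
  rows <- lapply(tensors, function(ft) {
    d <- dim(ft)
    m <- matrix(aperm(ft, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
    colnames(m) <- dimnames(ft)[[3]]
    m
  })
  X <- do.call(rbind, rows)
  if (nrow(X) > max_samples) {
    idx <- round(seq(1, nrow(X), length.out = max_samples))
    X <- X[idx, , drop = FALSE]
  }
  sdv <- apply(X, 2, stats::sd)
  Z <- sweep(X, 2, colMeans(X))
  Z[, sdv > 0] <- sweep(Z[, sdv > 0, drop = FALSE], 2, sdv[sdv > 0], "/")
  S <- knn_similarity(Z, k = k, t = t)
  laplacian_score(X, S)
}

#' Aggregate per-subject feature rankings by mean rank
#'
#' @param rankings list of `feature_ranking` objects.
#' @return A `feature_ranking` whose scores are mean ranks (lower = better).
#' @export
aggregate_feature_rankings <- function(rankings) {
  stop_if(!length(rankings), "need at least one ranking")
  feats <- rankings[[1]]$order
  rankmat <- vapply(rankings, function(r) match(feats, r$order), numeric(length(feats)))
  mean_rank <- rowMeans(rankmat)
  names(mean_rank) <- feats
  ord <- feats[order(mean_rank, feats)]
  structure(list(scores = mean_rank, order = ord, flagged = character(),
                 params = list(aggregated = length(rankings))),
            class = "feature_ranking")
}

#' Top fraction of a feature ranking
#'
#' @param ranking a `feature_ranking`.
#' @param fraction fraction of features to keep (default 1/3).
#' @return character vector of kept feature names (best first).
#' @export
select_top_features <- function(ranking, fraction = 1 / 3) {
  stop_if(!is_number(fraction) || fraction <= 0 || fraction > 1,
          "fraction must be in (0, 1]")
  utils::head(ranking$order, ceiling(fraction * length(ranking$order)))
}
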