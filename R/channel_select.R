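#' Inter-channel similarity for one epoch
#'
#' Pearson correlation between the per-channel feature vectors of a single
#' epoch. Feature columns are z-scored across channels first so that
#' large-magnitude features (band energies) do not dominate the
#' correlation. Channels whose feature vector has zero variance get zero
#' similarity to everything and are flagged.
#'
#' @param X_t numeric matrix, channels x features (one epoch).
#' @return symmetric correlation matrix with unit diagonal and attribute
#'   `flagged` (names of zero-variance channels).
#' @export
channel_similarity <- function(X_t) {
  X_t <- as.matrix(X_t)
  stop_if(ncol(X_t) < 2, "need at least 2 features per channel")
  if (is.null(rownames(X_t))) rownames(X_t) <- paste0("ch", seq_len(nrow(X_t)))
  sdv <- apply(X_t, 2, stats::sd)
  Z <- sweep(X_t, 2, colMeans(X_t))
  Z[, sdv > 0] <- sweep(Z[, sdv > 0, drop = FALSE], 2, sdv[sdv > 0], "/")
  rv <- apply(Z, 1, stats::sd) == 0 | apply(X_t, 1, stats::sd) == 0
  S <- suppressWarnings(stats::cor(t(Z)))
  S[!is.finite(S)] <- 0
  flagged <- rownames(X_t)[rv]
  S[rv, ] <- 0
  S[, rv] <- 0
  diag(S) <- 1
  structure(S, flagged = flagged)
}

# Spatial discount factor from the topological distance matrix: close pairs
# (0 < delta <= kappa_max) are down-weighted by delta / (kappa_max + 1);
# far pairs (delta = 0, beyond the cap) keep full weight.
spatial_factor <- function(delta) {
  kmax <- attr(delta, "kappa_max")
  ifelse(delta > 0 & delta <= kmax, delta / (kmax + 1), 1)
}

#' Spatially discounted co-activation graph for one epoch
#'
#' Edge weight `w_ij = L_ij * max(S_ij, 0) * spatial_factor(delta_ij)`:
#' only co-clustered channel pairs are connected, anticorrelation does not
#' count as co-activation, and spatially close pairs (which tend to read
#' the same underlying sources through volume conduction) are discounted by
#' `delta_ij / (kappa_max + 1)`.
#'
#' @param S channel similarity matrix ([channel_similarity()]).
#' @param L co-membership matrix from [affinity_propagation()].
#' @param delta topological distance matrix ([neighboring_matrix()]).
#' @return symmetric weighted adjacency matrix, zero diagonal.
#' @export
build_coactivation_graph <- function(S, L, delta) {
  stop_if(!all(dim(S) == dim(L)) || !all(dim(S) == dim(delta)),
          "S, L and delta must have identical shapes")
  fac <- spatial_factor(delta)
  G <- L * pmax(S, 0) * fac
  diag(G) <- 0
  dimnames(G) <- dimnames(S)
  # maximum attainable discounted degree per channel (all pairs co-clustered
  # at similarity 1); channels with many close neighbours have more of their
  # edges discounted, and normalising by this ceiling removes the montage-
  # position bias a raw weighted degree would carry
  fac0 <- fac
  diag(fac0) <- 0
  attr(G, "max_degree") <- rowSums(fac0)
  G
}

#' Rank channels by cross-epoch consistency and functional strength
#'
#' Builds the consensus co-membership matrix M (mean of the per-epoch L
#' matrices) and scores each epoch by the Pearson correlation between its
#' vectorised L and M (diagonal excluded); epochs below the median
#' consistency are discarded. On the retained epochs each channel scores
#' `alpha * exemplar frequency + (1 - alpha) * functional strength`, where
#' functional strength is the mean weighted degree in the spatially
#' discounted co-activation graphs, normalised by each channel's maximum
#' attainable discounted degree (channels with many close neighbours have
#' more of their edges discounted, and the normalisation removes that
#' montage-position bias), then min-max rescaled to [0, 1]. Ties are broken
#' by exemplar frequency, then channel name.
#'
#' @param clusterings list of `ap_clustering` objects, one per epoch.
#' @param graphs list of co-activation graphs, one per epoch.
#' @param alpha blend weight between exemplar frequency and functional
#'   strength (default 0.5).
#' @return A `channel_ranking`: `scores` (named, descending = better),
#'   `order`, `retained_epochs` (indices), `consistency` (per epoch),
#'   `components` (per-channel exemplar_frequency / functional_strength)
#'   and `consensus` (M).
#' @export
rank_channels <- function(clusterings, graphs, alpha = 0.5) {
  stop_if(length(clusterings) < 2, "need at least 2 epochs to rank channels")
  stop_if(length(clusterings) != length(graphs),
          "clusterings and graphs must align")
  stop_if(!is_number(alpha) || alpha < 0 || alpha > 1, "alpha must be in [0, 1]")
  Ls <- lapply(clusterings, `[[`, "L")
  nm <- rownames(Ls[[1]])
  M <- Reduce(`+`, Ls) / length(Ls)
  offd <- row(M) != col(M)
  consistency <- vapply(Ls, function(L) {
    a <- L[offd]; b <- M[offd]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      if (all(a == b)) 1 else 0
    } else stats::cor(a, b)
  }, numeric(1))
  med <- stats::median(consistency)
  retained <- which(consistency >= med)
  if (length(retained) == 0) {
    warning("no epoch reaches median consistency; retaining all epochs")
    retained <- seq_along(Ls)
  }
  ex_freq <- rowMeans(vapply(clusterings[retained],
                             function(cl) nm %in% cl$exemplars,
                             logical(length(nm))))
  deg <- rowMeans(vapply(graphs[retained], function(G) {
    d <- rowSums(G)
    ceiling_deg <- attr(G, "max_degree")
    if (!is.null(ceiling_deg)) d / pmax(ceiling_deg, 1e-12) else d
  }, numeric(length(nm))))
  rng <- range(deg)
  strength <- if (diff(rng) > 0) (deg - rng[1]) / diff(rng) else rep(0, length(deg))
  scores <- alpha * ex_freq + (1 - alpha) * strength
  names(scores) <- names(ex_freq) <- names(strength) <- nm
  ord <- nm[order(-scores, -ex_freq, nm)]
  structure(list(scores = scores, order = ord, retained_epochs = retained,
                 consistency = consistency,
                 components = data.frame(channel = nm,
                                         exemplar_frequency = ex_freq,
                                         functional_strength = strength,
                                         row.names = NULL),
                 consensus = M, alpha = alpha),
            class = "channel_ranking")
}

#' Channel ranking for one trial of epoched features
#'
#' Runs the full per-epoch loop: channel similarity (Pearson on z-scored
#' features), affinity propagation, spatially discounted co-activation
#' graph, then the cross-epoch consistency ranking.
#'
#' @param ft a `feature_tensor` (epochs x channels x features).
#' @param delta topological distance matrix from [neighboring_matrix()];
#'   channel order must match the tensor.
#' @param features optional subset of feature names used for the channel
#'   similarity (default: all).
#' @param damping,preference,max_iter,convergence_iter passed to
#'   [affinity_propagation()].
#' @param alpha passed to [rank_channels()].
#' @return A `channel_ranking`.
#' @export
rank_trial_channels <- function(ft, delta, features = NULL, damping = 0.9,
                                preference = NULL, max_iter = 500,
                                convergence_iter = 25, alpha = 0.5) {
  d <- dim(ft)
  stop_if(d[1] < 2, "need at least 2 epochs")
  stop_if(nrow(delta) != d[2], "delta does not match the channel count")
  feat_idx <- if (is.null(features)) seq_len(d[3]) else {
    match(features, dimnames(ft)[[3]])
  }
  clusterings <- vector("list", d[1])
  graphs <- vector("list", d[1])
  for (e in seq_len(d[1])) {
    X_t <- ft[e, , feat_idx, drop = FALSE]
    X_t <- matrix(X_t, d[2], length(feat_idx),
                  dimnames = list(dimnames(ft)[[2]], dimnames(ft)[[3]][feat_idx]))
    S <- channel_similarity(X_t)
    cl <- affinity_propagation(S, damping = damping, preference = preference,
                               max_iter = max_iter,
                               convergence_iter = convergence_iter)
    clusterings[[e]] <- cl
    graphs[[e]] <- build_coactivation_graph(S, cl$L, delta)
  }
  rank_channels(clusterings, graphs, alpha = alpha)
}

#' Aggregate channel rankings by mean rank
#'
#' Combines per-trial (or per-subject) rankings into one ranking; the score
#' reported is `1 - mean_rank / C` so that higher remains better.
#'
#' @param rankings list of `channel_ranking` objects over the same channels.
#' @return A `channel_ranking` (consistency/consensus fields absent).
#' @export
aggregate_channel_rankings <- function(rankings) {
  stop_if(!length(rankings), "need at least one ranking")
  nm <- sort(rankings[[1]]$order)
  rankmat <- vapply(rankings, function(r) match(nm, r$order), numeric(length(nm)))
  mean_rank <- rowMeans(rankmat)
  scores <- 1 - mean_rank / length(nm)
  names(scores) <- nm
  ex_freq <- rowMeans(vapply(rankings, function(r)
    r$components$exemplar_frequency[match(nm, r$components$channel)],
    numeric(length(nm))))
  ord <- nm[order(-scores, -ex_freq, nm)]
  structure(list(scores = scores, order = ord, retained_epochs = NA,
                 consistency = NULL,
                 components = data.frame(channel = nm,
                                         exemplar_frequency = ex_freq,
                                         functional_strength = NA,
                                         row.names = NULL),
                 consensus = NULL, alpha = rankings[[1]]$alpha),
            class = "channel_ranking")
}

#' Select the top fraction of a channel ranking
#'
#' @param ranking a `channel_ranking`.
#' @param fraction fraction of channels, in (0, 1]; `ceiling(fraction * C)`
#'   channels are returned.
#' @return character vector of selected channel names (best first).
#' @export
select_top_fraction <- function(ranking, fraction) {
  stop_if(!is_number(fraction) || fraction <= 0 || fraction > 1,
          "fraction must be in (0, 1]")
  utils::head(ranking$order, ceiling(fraction * length(ranking$order)))
}

#' Selection-frequency table across runs
#'
#' Counts, for each channel, how often it appears in the top fraction of a
#' collection of rankings (different trials, sessions or seeds).
#'
#' @param rankings list of `channel_ranking` objects.
#' @param fraction top fraction defining "selected".
#' @return data.frame channel / times_selected / frequency, sorted.
#' @export
selection_frequency <- function(rankings, fraction = 0.25) {
  sel <- lapply(rankings, select_top_fraction, fraction = fraction)
  nm <- sort(unique(unlist(lapply(rankings, `[[`, "order"))))
  counts <- vapply(nm, function(ch) sum(vapply(sel, function(s) ch %in% s,
                                               logical(1))), numeric(1))
  out <- data.frame(channel = nm, times_selected = counts,
                    frequency = counts / length(rankings), row.names = NULL)
  out[order(-out$times_selected, out$channel), ]
}

#' @export
print.channel_ranking <- function(x, n = 8, ...) {
  cat(sprintf("<channel_ranking> %d channels\n", length(x$scores)))
  cat("  best:", paste(utils::head(x$order, n), collapse = ", "), "\n")
  if (!is.null(x$consistency))
    cat(sprintf("  retained %d/%d epochs (median consistency rule)\n",
                length(x$retained_epochs), length(x$consistency)))
  invisible(x)
}

#' @export
summary.channel_ranking <- function(object, ...) {
  comp <- object$components
  comp$score <- object$scores[comp$channel]
  comp <- comp[match(object$order, comp$channel), ]
  rownames(comp) <- NULL
  comp
}

#' @export
plot.channel_ranking <- function(x, montage = NULL, ...) {
  if (is.null(montage)) {
    graphics::barplot(x$scores[x$order], las = 2, cex.names = 0.6,
                      ylab = "ranking score", ...)
  } else {
    p <- montage$positions[match(names(x$scores), montage$positions$name), ]
    sc <- x$scores
    cex <- 1 + 3 * (sc - min(sc)) / max(1e-12, diff(range(sc)))
    graphics::plot(p$x, p$y, asp = 1, pch = 21, bg = "tomato", cex = cex,
                   xlab = "", ylab = "", axes = FALSE,
                   main = "channel ranking", ...)
    graphics::text(p$x, p$y, p$name, cex = 0.55, pos = 3)
  }
  invisible(x)
}
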