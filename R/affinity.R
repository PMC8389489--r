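#' Affinity propagation clustering
#'
#' Exemplar-based clustering by damped responsibility/availability message
#' passing on a similarity matrix. The number of clusters is not fixed in
#' advance; it emerges from the `preference` (the self-similarity placed on
#' the diagonal). Exemplars are the points k with
#' `availability(k,k) + responsibility(k,k) > 0`; every point is assigned
#' to the exemplar maximising `availability + responsibility`, and the
#' zero-diagonal co-membership matrix L marks pairs sharing a cluster.
#'
#' @param S square symmetric similarity matrix (larger = more similar).
#' @param damping message damping factor in `[0.5, 1)`.
#' @param preference diagonal self-similarity; default is the median
#'   off-diagonal similarity (moderate number of clusters).
#' @param max_iter iteration cap.
#' @param convergence_iter stop after this many iterations with an
#'   unchanged exemplar set.
#' @param min_iter iterations that must elapse before convergence can be
#'   declared. Damped messages evolve slowly (time constant about
#'   `1/(1 - damping)` iterations), and transient exemplar sets early in
#'   the schedule can otherwise masquerade as stable fixed points.
#' @return An object of class `ap_clustering`: `exemplars` (names or
#'   indices), `labels` (exemplar assigned to every point), `L`
#'   (co-membership matrix, zero diagonal), `converged`, `iterations`,
#'   and the final `responsibility`/`availability` matrices.
#' @export
affinity_propagation <- function(S, damping = 0.9, preference = NULL,
                                 max_iter = 500, convergence_iter = 25,
                                 min_iter = 100) {
  S <- as.matrix(S)
  n <- nrow(S)
  stop_if(n != ncol(S), "S must be square")
  stop_if(!is_number(damping) || damping < 0.5 || damping >= 1,
          "damping must be in [0.5, 1)")
  nm <- rownames(S) %||% as.character(seq_len(n))
  off <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; prev_ex <- NULL; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities: rho_ik = S_ik - max_{k' != k} (S_ik' + alpha_ik')
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- 0
    cs <- colSums(Rp)
    Anew <- matrix(pmin(0, rep(diag(R), each = n) + rep(cs, each = n) - Rp), n, n)
    diag(Anew) <- cs
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    # stability only counts once an exemplar set has emerged: early damped
    # iterations share an empty set, which must not trigger convergence
    if (length(ex) > 0 && identical(ex, prev_ex)) stable <- stable + 1L
    else stable <- 0L
    prev_ex <- ex
    if (it >= min_iter && stable >= convergence_iter) break
  }
  converged <- stable >= convergence_iter
  ex <- prev_ex
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  E <- A + R
  labels <- ex[max.col(E[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  L <- outer(labels, labels, "==") * 1L
  diag(L) <- 0L
  dimnames(L) <- list(nm, nm)
  structure(list(exemplars = nm[ex], exemplar_idx = ex,
                 labels = stats::setNames(nm[labels], nm),
                 L = L, converged = converged, iterations = it,
                 responsibility = R, availability = A,
                 preference = preference),
            class = "ap_clustering")
}

#' @export
print.ap_clustering <- function(x, ...) {
  cat(sprintf("<ap_clustering> %d points -> %d clusters (%s in %d iterations)\n",
              length(x$labels), length(x$exemplars),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  exemplars:", paste(x$exemplars, collapse = ", "), "\n")
  invisible(x)
}
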