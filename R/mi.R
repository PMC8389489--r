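#' Binarise affect ratings
#'
#' Ratings on the 1-9 self-assessment scale are split at the midpoint:
#' `> 5` is "high", otherwise "low".
#'
#' @param rating numeric vector of ratings.
#' @param threshold split point (default 5).
#' @return factor with levels low/high.
#' @export
binarize_ratings <- function(rating, threshold = 5) {
  factor(ifelse(rating > threshold, "high", "low"), levels = c("low", "high"))
}

# Equal-frequency discretisation; inputs with at most `bins` distinct values
# are used as-is (keeps MI symmetric for already-discrete variables).
discretize_ef <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 3) return(factor(x > br[1]))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Mutual information between a feature and a binary target
#'
#' Plug-in estimate of `MI(x, y) = H(x) + H(y) - H(x, y)` in bits, with the
#' continuous feature discretised into equal-frequency bins. Strictly
#' irrelevant features weigh (close to) zero; the estimate is clipped at 0.
#'
#' @param x numeric (or discrete) feature values.
#' @param y binary labels (both classes must be present).
#' @param bins number of equal-frequency bins for continuous `x`.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(x, y, bins = 8) {
  stop_if(length(x) != length(y), "x and y must align")
  stop_if(length(x) < 10, "need at least 10 samples")
  y <- factor(y)
  stop_if(nlevels(droplevels(y)) < 2, "y must contain both classes")
  xd <- if (is.numeric(x)) discretize_ef(x, bins) else factor(x)
  tab <- table(xd, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  max(0, mi)
}

#' Supervised best-k feature selection by mutual information
#'
#' Computes the MI of every feature column with the binary target, drops
#' zero-MI (irrelevant) features and keeps the top `k`. Ties are broken by
#' the upstream unsupervised rank (the column order of `X`, which callers
#' arrange best-first), so the refinement respects the unsupervised
#' pipeline ordering. Must be called on training rows only; the evaluation
#' module audits this.
#'
#' @param X numeric matrix, samples x features (columns named).
#' @param y binary labels.
#' @param k number of features to keep; if more than the surviving
#'   (nonzero-MI) features, all survivors are kept with a warning.
#' @param bins discretisation bins.
#' @return An object of class `mi_result`: `mi` (named vector, bits),
#'   `kept` (ordered names), `dropped_zero`, `binning`.
#' @export
select_best_k <- function(X, y, k, bins = 8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  stop_if(!is_count(k), "k must be a positive integer")
  mi <- vapply(seq_len(ncol(X)), function(j) mutual_information(X[, j], y, bins),
               numeric(1))
  names(mi) <- colnames(X)
  surviving <- which(mi > 0)
  if (length(surviving) < k) {
    warning(sprintf("k = %d exceeds the %d surviving (nonzero-MI) features; keeping all",
                    k, length(surviving)))
  }
  ord <- surviving[order(-mi[surviving], surviving)]  # ties: upstream order
  kept <- colnames(X)[utils::head(ord, k)]
  structure(list(mi = mi, kept = kept,
                 dropped_zero = colnames(X)[mi == 0],
                 binning = sprintf("equal-frequency, %d bins", bins)),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, n = 10, ...) {
  cat(sprintf("<mi_result> kept %d features (%d dropped at MI = 0); %s\n",
              length(x$kept), length(x$dropped_zero), x$binning))
  top <- utils::head(x$kept, n)
  cat("  top:", paste(sprintf("%s(%.3f)", top, x$mi[top]), collapse = ", "), "\n")
  invisible(x)
}
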