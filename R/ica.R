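# Deflation FastICA with the logcosh contrast.
#
# One-unit fixed-point iterations with Gram-Schmidt orthogonalisation
# against previously extracted components; initialisation is the sequence
# of unit vectors, so the decomposition is deterministic. Returns sources
# (components x time), the mixing matrix with X - center ~= mixing %*%
# sources, the per-component convergence flags and an overall flag
# (TRUE when a majority of components converged; strongly non-Gaussian
# artifact components converge in a handful of iterations, while
# near-Gaussian noise components may exhaust their budget without harming
# the artifact subspace - callers additionally check that the components
# they zero out converged).
fastica <- function(X, max_iter = 200, tol = 1e-4) {
  n <- nrow(X)
  center <- rowMeans(X)
  Xc <- X - center
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, max(eg$values) * 1e-12)
  K <- diag(1 / sqrt(ev)) %*% t(eg$vectors)       # whitening
  K_inv <- eg$vectors %*% diag(sqrt(ev))          # de-whitening
  Z <- K %*% Xc
  N <- ncol(Z)
  W <- matrix(0, n, n)
  comp_converged <- logical(n)
  for (i in seq_len(n)) {
    w <- numeric(n); w[i] <- 1
    if (i > 1) {
      P <- W[seq_len(i - 1), , drop = FALSE]
      w <- w - drop(t(P) %*% (P %*% w))
      w <- w / sqrt(sum(w^2))
    }
    for (it in seq_len(max_iter)) {
      g <- tanh(drop(crossprod(w, Z)))
      wn <- drop(Z %*% g) / N - mean(1 - g^2) * w
      if (i > 1) {
        P <- W[seq_len(i - 1), , drop = FALSE]
        wn <- wn - drop(t(P) %*% (P %*% wn))
      }
      nrm <- sqrt(sum(wn^2))
      if (nrm < 1e-12) break
      wn <- wn / nrm
      d <- abs(abs(sum(wn * w)) - 1)
      w <- wn
      if (d < tol) { comp_converged[i] <- TRUE; break }
    }
    W[i, ] <- w
  }
  sources <- W %*% Z
  mixing <- K_inv %*% t(W)
  list(sources = sources, mixing = mixing, center = center,
       comp_converged = comp_converged,
       converged = mean(comp_converged) >= 0.5,
       iterations = max_iter)
}
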