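# Daubechies-4 (8-tap) orthonormal scaling filter.
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)

# Convolve with symmetric (edge-replicating) extension and downsample by 2.
dwt_step <- function(x, filt) {
  L <- length(filt)
  nx <- length(x)
  pad <- min(L - 1L, nx)
  left <- x[pad:1]
  right <- x[nx:(nx - pad + 1L)]
  if (pad < L - 1L) {  # very short signals: keep reflecting
    while (length(left) < L - 1L) left <- c(left, rev(left))[seq_len(L - 1L)]
    while (length(right) < L - 1L) right <- c(right, rev(right))[seq_len(L - 1L)]
    left <- left[seq_len(L - 1L)]
    right <- right[seq_len(L - 1L)]
  }
  ext <- c(left, x, right)
  full <- stats::convolve(ext, rev(filt), type = "open")
  valid <- full[L:(L + length(ext) - L)]
  valid[seq(2L, length(valid), by = 2L)]
}

#' Multi-level discrete wavelet transform (db4)
#'
#' Mallat pyramid decomposition with the Daubechies-4 filter pair and
#' symmetric boundary extension. Returns the detail coefficient sequences
#' D1 (highest frequency) through D`levels` and the final approximation.
#'
#' @param x numeric vector, `length(x) >= 2^levels`.
#' @param levels number of decomposition levels (default 6).
#' @return list with `details` (list D1..D`levels`) and `approx` (A
#'   sequence at the coarsest level).
#' @export
dwt_db4 <- function(x, levels = 6) {
  stop_if(!is_count(levels), "levels must be a positive integer")
  stop_if(length(x) < 2^levels,
          sprintf("signal of length %d too short for %d DWT levels", length(x), levels))
  h <- DB4_H
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # quadrature mirror wavelet filter
  details <- vector("list", levels)
  names(details) <- paste0("D", seq_len(levels))
  a <- x
  for (l in seq_len(levels)) {
    details[[l]] <- dwt_step(a, g)
    a <- dwt_step(a, h)
  }
  list(details = details, approx = a)
}

# Teager-Kaiser energy operator psi[c_n] = c_n^2 - c_{n-1} c_{n+1}.
teager_kaiser <- function(c) {
  n <- length(c)
  if (n < 3) return(numeric(0))
  c[2:(n - 1)]^2 - c[1:(n - 2)] * c[3:n]
}
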