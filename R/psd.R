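#' Welch power spectral density estimate
#'
#' Mean modified periodogram over 50%-overlapping Hamming-windowed segments
#' with per-segment mean removal. Segment length defaults to
#' `min(length(x), 256)` samples (2 s at 128 Hz). One-sided density
#' normalisation: `sum(psd) * df` approximates the signal variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @return list with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 256L)) {
  n <- length(x)
  stop_if(n < 8, "signal too short for a PSD estimate")
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / scale
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- 2:(nf - if (nperseg %% 2L == 0L) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = seq(0, nf - 1) * fs / nperseg, psd = psd)
}

# Trapezoidal integral of psd over [lo, hi].
band_energy <- function(freq, psd, lo, hi) {
  idx <- which(freq >= lo & freq <= hi)
  if (length(idx) < 2) return(0)
  f <- freq[idx]; p <- psd[idx]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Band power of a signal via the Welch estimate
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz.
#' @param nperseg Welch segment length.
#' @return integrated power in the band.
#' @export
band_power <- function(x, fs, lo, hi, nperseg = min(length(x), 256L)) {
  sp <- welch_psd(x, fs, nperseg)
  band_energy(sp$freq, sp$psd, lo, hi)
}
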