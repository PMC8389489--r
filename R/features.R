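#' The fixed 54-feature name contract
#'
#' 17 time-domain, 17 frequency-domain and 20 time-frequency features, in
#' the fixed order used throughout the package.
#' @return character vector of length 54.
#' @export
feature_names <- function() {
  c("mean", "var", "std", "skw", "kurts", "entrpA", "entrpS", "entrpSp",
    "hjorthM", "hjorthC", "ptp", "higuchi", "katz", "zcross", "lnlen",
    "decorr", "hurst",
    "spec_frq", "hjorthMsp", "hjorthCsp",
    paste0("spc_slp", 1:4), paste0("enrg_bnd", 1:5), paste0("powfreq", 1:5),
    paste0("wvlet", 1:6), paste0("tk", 1:14))
}

#' Frequency-band definition used for band features
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30 Hz and gamma from 30 Hz to
#' the Nyquist frequency. With the default 0.5-40 Hz band-pass in place the
#' gamma band content mostly reflects filter roll-off; the band is kept as
#' defined so the five-band feature layout is invariant to preprocessing.
#'
#' @param fs sampling rate in Hz (sets the gamma upper edge at `fs/2`).
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
band_definition <- function(fs) {
  stop_if(!is_number(fs) || fs <= 60, "fs must exceed 60 Hz for the canonical bands")
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 12, 30), hi = c(4, 8, 12, 30, fs / 2))
}

# --- time-domain helpers ----------------------------------------------------

# Vectorised approximate and sample entropy (m = 2, Chebyshev distance).
# ApEn includes self-matches (Pincus); SampEn excludes them (Richman-Moorman).
apen_sampen <- function(x, r) {
  n <- length(x)
  if (n < 8 || r <= 0) return(c(0, 0))
  # Chebyshev template matches via the thresholded lag-0 distance matrix:
  # a pair of m-templates matches iff all m pointwise distances are <= r.
  B1 <- abs(outer(x, x, "-")) <= r
  M2 <- B1[-n, -n] & B1[-1, -1]                                  # m = 2
  M3 <- M2[-(n - 1), -(n - 1)] & B1[-(1:2), -(1:2)]              # m = 3
  n2 <- n - 1; n3 <- n - 2
  c2 <- rowSums(M2)
  c3 <- rowSums(M3)
  apen <- mean(log(c2 / n2)) - mean(log(c3 / n3))
  B <- (sum(M2[seq_len(n3), seq_len(n3)]) - n3) / 2
  A <- (sum(M3) - n3) / 2
  sampen <- if (A > 0 && B > 0) -log(A / B) else 0
  c(apen, sampen)
}

# slope (and optionally intercept) of a simple least-squares line
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

higuchi_fd <- function(x, k_max = 10) {
  n <- length(x)
  if (n < k_max + 1) return(0)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    d <- abs(x[(k + 1):n] - x[seq_len(n - k)])
    off <- ((seq_along(d) - 1) %% k) + 1
    sums <- rowsum(d, off)[, 1]
    counts <- tabulate(off, nbins = k)
    ok <- counts > 0
    lk[k] <- mean(sums[ok] * (n - 1) / (k^2 * counts[ok]))
  }
  ok <- lk > 0
  if (sum(ok) < 2) return(0)
  -ls_slope(log(seq_len(k_max)[ok]), log(lk[ok]))
}

katz_fd <- function(x) {
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) return(0)
  nsteps <- length(x) - 1
  log10(nsteps) / (log10(nsteps) + log10(d / L))
}

zero_crossings <- function(x) {
  s <- sign(x - mean(x))
  s <- s[s != 0]                 # exact zeros: the surrounding change counts once
  if (length(s) < 2) return(0)
  sum(diff(s) != 0)
}

decorrelation_time <- function(x, fs) {
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  ac <- stats::acf(x, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  below <- which(ac < exp(-1))
  if (length(below) == 0) return((n - 1) / fs)
  (below[1] - 1) / fs
}

# Rescaled-range Hurst exponent over dyadic window sizes >= 8 samples.
hurst_rs <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0 || n < 16) return(0)
  sizes <- 2^(3:floor(log2(n / 2)))
  sizes <- sizes[sizes >= 8]
  if (length(sizes) < 2) return(0)
  rs <- vapply(sizes, function(w) {
    nb <- floor(n / w)
    M <- matrix(x[seq_len(nb * w)], w, nb)
    Mc <- sweep(M, 2, colMeans(M))
    Z <- apply(Mc, 2, cumsum)
    rng <- apply(Z, 2, function(z) max(z) - min(z))
    s <- apply(M, 2, stats::sd)
    vals <- ifelse(s > 0, rng / s, NA_real_)
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(0)
  ls_slope(log(sizes[ok]), log(rs[ok]))
}

#' Time-domain features of one epoch channel
#'
#' Moments (mean, unbiased variance, sd, skewness, excess kurtosis),
#' approximate/sample entropy (m = 2, r = 0.2 sd), spectral entropy
#' (Shannon, log2, of the sum-normalised Welch PSD, not normalised by bin
#' count), Hjorth mobility and complexity, peak-to-peak, Higuchi
#' (k_max = 10) and Katz fractal dimensions, zero crossings on the
#' mean-centred signal, line length, decorrelation time (first lag with
#' autocorrelation below 1/e, in seconds) and the rescaled-range Hurst
#' exponent. Degenerate (constant) input yields zeros for the
#' variance-normalised features rather than NaN.
#'
#' @param x numeric vector (one channel of one epoch).
#' @param fs sampling rate in Hz.
#' @param spectrum optional precomputed [welch_psd()] result.
#' @return named numeric vector of length 17.
#' @export
time_domain_features <- function(x, fs, spectrum = NULL) {
  n <- length(x)
  stop_if(n < 4, "need at least 4 samples")
  m <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  out <- c(mean = m, var = v, std = s, skw = 0, kurts = 0, entrpA = 0,
           entrpS = 0, entrpSp = 0, hjorthM = 0, hjorthC = 0,
           ptp = max(x) - min(x), higuchi = 0, katz = 0,
           zcross = zero_crossings(x), lnlen = sum(abs(diff(x))),
           decorr = decorrelation_time(x, fs), hurst = 0)
  if (s > 0) {
    xc <- x - m
    m2 <- mean(xc^2)
    out["skw"] <- mean(xc^3) / m2^1.5
    out["kurts"] <- mean(xc^4) / m2^2 - 3
    ent <- apen_sampen(x, 0.2 * s)
    out["entrpA"] <- ent[1]
    out["entrpS"] <- ent[2]
    d1 <- diff(x)
    vd1 <- stats::var(d1)
    mob <- sqrt(vd1 / v)
    out["hjorthM"] <- mob
    if (vd1 > 0) {
      d2 <- diff(d1)
      out["hjorthC"] <- sqrt(stats::var(d2) / vd1) / mob
    }
    out["higuchi"] <- higuchi_fd(x)
    out["katz"] <- katz_fd(x)
    out["hurst"] <- hurst_rs(x)
    if (is.null(spectrum)) spectrum <- welch_psd(x, fs)
    p <- spectrum$psd
    p <- p[p > 0]
    if (length(p) > 0) {
      p <- p / sum(p)
      out["entrpSp"] <- -sum(p * log2(p))
    }
  }
  out
}

#' Frequency-domain features of one epoch channel
#'
#' From the Welch PSD: spectral edge frequency (95% cumulative power),
#' Hjorth mobility/complexity applied to the PSD sequence, the intercept,
#' slope, mean squared residual and R^2 of the least-squares line through
#' log10(PSD) vs log10(frequency) over 1-40 Hz, trapezoidal band energies
#' and mean band power for the five canonical bands.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param bands band table from [band_definition()].
#' @param spectrum optional precomputed [welch_psd()] result.
#' @return named numeric vector of length 17.
#' @export
freq_domain_features <- function(x, fs, bands = band_definition(fs),
                                 spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- welch_psd(x, fs)
  f <- spectrum$freq; p <- spectrum$psd
  nm <- c("spec_frq", "hjorthMsp", "hjorthCsp", paste0("spc_slp", 1:4),
          paste0("enrg_bnd", 1:5), paste0("powfreq", 1:5))
  out <- stats::setNames(numeric(17), nm)
  tot <- sum(p)
  if (tot <= 0) return(out)
  cum <- cumsum(p) / tot
  out["spec_frq"] <- f[which(cum >= 0.95)[1]]
  vp <- stats::var(p)
  if (vp > 0) {
    dp <- diff(p)
    vdp <- stats::var(dp)
    mob <- sqrt(vdp / vp)
    out["hjorthMsp"] <- mob
    if (vdp > 0 && mob > 0)
      out["hjorthCsp"] <- sqrt(stats::var(diff(dp)) / vdp) / mob
  }
  sl <- which(f >= 1 & f <= 40 & p > 0)
  if (length(sl) >= 3) {
    lx <- log10(f[sl]); ly <- log10(p[sl])
    slope <- ls_slope(lx, ly)
    intercept <- mean(ly) - slope * mean(lx)
    res <- ly - (intercept + slope * lx)
    ss_tot <- sum((ly - mean(ly))^2)
    out["spc_slp1"] <- intercept
    out["spc_slp2"] <- slope
    out["spc_slp3"] <- mean(res^2)
    out["spc_slp4"] <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  }
  for (b in seq_len(nrow(bands))) {
    out[paste0("enrg_bnd", b)] <- band_energy(f, p, bands$lo[b], bands$hi[b])
    idx <- which(f >= bands$lo[b] & f <= bands$hi[b])
    out[paste0("powfreq", b)] <- if (length(idx) > 0) mean(p[idx]) else 0
  }
  out
}

#' Time-frequency features of one epoch channel
#'
#' A 6-level db4 discrete wavelet transform yields `wvlet1..wvlet6`, the
#' log10 mean squared detail coefficients per level (log floor -30 for
#' silent sub-bands). The seven sub-band sequences (D1..D6, A6) each
#' contribute the mean and standard deviation of their Teager-Kaiser energy
#' sequence, giving `tk1..tk14` ordered D1.mean, D1.sd, ..., A6.mean,
#' A6.sd - matching the (levels + 1) * 2 count. Sub-bands with fewer than
#' 3 coefficients contribute zeros.
#'
#' @param x numeric vector, length >= 64.
#' @param fs sampling rate in Hz (unused; kept for interface symmetry).
#' @param levels DWT decomposition depth.
#' @return named numeric vector of length 20.
#' @export
timefreq_domain_features <- function(x, fs = NULL, levels = 6) {
  stop_if(length(x) < 2^levels, "epoch too short for the DWT decomposition")
  dec <- dwt_db4(x, levels)
  wv <- vapply(dec$details, function(d) {
    ms <- mean(d^2)
    if (ms <= 1e-30) -30 else log10(ms)
  }, numeric(1))
  subbands <- c(dec$details, list(A = dec$approx))
  tk <- unlist(lapply(subbands, function(d) {
    psi <- teager_kaiser(d)
    if (length(psi) < 2) c(0, 0) else c(mean(psi), stats::sd(psi))
  }), use.names = FALSE)
  stats::setNames(c(wv, tk),
                  c(paste0("wvlet", seq_len(levels)), paste0("tk", seq_len(2 * (levels + 1)))))
}

#' Extract the full 54-feature battery from epoched data
#'
#' Computes, per epoch and channel, the 17 time-domain, 17 frequency-domain
#' and 20 time-frequency features (54 per channel; 1728 per epoch on a
#' 32-channel montage).
#'
#' @param ep an `eeg_epochs` object from [epoch_recording()].
#' @return A `feature_tensor`: numeric array epochs x channels x 54 with
#'   dimnames, plus attributes `fs`, `w`, `band_edges`, `subject_id`,
#'   `trial_id` and `zero_variance` (logical epochs x channels matrix
#'   flagging degenerate inputs).
#' @export
extract_features <- function(ep) {
  stop_if(!inherits(ep, "eeg_epochs"), "ep must come from epoch_recording()")
  dims <- dim(ep$epochs)
  stop_if(dims[3] < 128, "epochs must contain at least 128 samples")
  bands <- band_definition(ep$fs)
  fn <- feature_names()
  vals <- array(NA_real_, dim = c(dims[1], dims[2], length(fn)),
                dimnames = list(NULL, ep$channel_names, fn))
  degen <- matrix(FALSE, dims[1], dims[2])
  for (e in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      x <- ep$epochs[e, c, ]
      spectrum <- welch_psd(x, ep$fs)
      degen[e, c] <- stats::sd(x) == 0
      vals[e, c, ] <- c(time_domain_features(x, ep$fs, spectrum),
                        freq_domain_features(x, ep$fs, bands, spectrum),
                        timefreq_domain_features(x, ep$fs))
    }
  }
  structure(vals, fs = ep$fs, w = ep$w, band_edges = bands,
            subject_id = ep$subject_id, trial_id = ep$trial_id,
            zero_variance = degen,
            class = c("feature_tensor", "array"))
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_tensor> %d epochs x %d channels x %d features (w = %g s @ %g Hz)\n",
              d[1], d[2], d[3], attr(x, "w"), attr(x, "fs")))
  cat(sprintf("  %d features per epoch in total\n", d[2] * d[3]))
  invisible(x)
}
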