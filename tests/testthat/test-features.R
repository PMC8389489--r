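test_that("the feature battery honours the 54-name contract", {
  fn <- feature_names()
  expect_length(fn, 54)
  expect_false(anyDuplicated(fn) > 0)
  # 17 time + 17 frequency + 20 time-frequency
  x <- sin(2 * pi * 10 * (0:255) / 128) + 0.1 * rnorm(256)
  td <- time_domain_features(x, 128)
  fd <- freq_domain_features(x, 128)
  tf <- timefreq_domain_features(x, 128)
  expect_length(td, 17)
  expect_length(fd, 17)
  expect_length(tf, 20)
  expect_identical(c(names(td), names(fd), names(tf)), fn)
})

test_that("extraction yields 54 features per channel (1728 on 32 channels)", {
  set.seed(1)
  mats <- replicate(2, matrix(rnorm(32 * 256), 32, 256,
                              dimnames = list(paste0("c", 1:32), NULL)),
                    simplify = FALSE)
  ep <- epochs_from_matrixlist(mats, fs = 128, w = 2)
  ft <- extract_features(ep)
  expect_equal(dim(ft), c(2, 32, 54))
  expect_equal(prod(dim(ft)[2:3]), 1728)
  expect_false(anyNA(ft))

  mats14 <- lapply(mats, function(m) m[1:14, ])
  ft14 <- extract_features(epochs_from_matrixlist(mats14, fs = 128, w = 2))
  expect_equal(prod(dim(ft14)[2:3]), 756)
})

test_that("moments, peak-to-peak and counting features match hand values", {
  const <- rep(1, 256)
  td <- time_domain_features(const, 128)
  expect_equal(td[["mean"]], 1)
  expect_equal(td[["var"]], 0)
  expect_equal(td[["ptp"]], 0)
  expect_equal(td[["zcross"]], 0)
  expect_equal(td[["lnlen"]], 0)
  expect_equal(td[["entrpA"]], 0)   # degenerate input flagged to zero
  expect_equal(td[["hurst"]], 0)

  x <- sin(2 * pi * 7 * (0:511) / 128)
  td <- time_domain_features(x, 128)
  expect_lt(abs(td[["ptp"]] - 2), 1e-3)
  expect_lt(abs(td[["mean"]]), 1e-9)

  n <- 64
  alt <- rep(c(1, -1), n / 2)
  td <- time_domain_features(alt, 128)
  expect_equal(td[["zcross"]], n - 1)
  expect_equal(td[["lnlen"]], 2 * (n - 1))
})

test_that("entropy features agree with an independent implementation", {
  set.seed(4)
  for (x in list(rnorm(200), sin(2 * pi * 5 * (0:199) / 100) + 0.2 * rnorm(200))) {
    r <- 0.2 * stats::sd(x)
    ours <- eegsel:::apen_sampen(x, r)
    expect_equal(ours[1], pracma::approx_entropy(x, edim = 2, r = r),
                 tolerance = 1e-10)
    expect_equal(ours[2], pracma::sample_entropy(x, edim = 2, r = r),
                 tolerance = 1e-10)
  }
})

test_that("spectral features locate a pure tone correctly", {
  x <- sin(2 * pi * 10 * (0:511) / 128)
  fd <- freq_domain_features(x, 128)
  pf <- fd[paste0("powfreq", 1:5)]
  expect_equal(which.max(pf), 3L, ignore_attr = TRUE)  # alpha band wins
  expect_gte(fd[["spec_frq"]], 9)
  expect_lte(fd[["spec_frq"]], 11)
})

test_that("spectral slope is flat for white noise and bands order sensibly", {
  set.seed(8)
  x <- rnorm(8192)
  fd <- freq_domain_features(x, 128, spectrum = welch_psd(x, 128, 256))
  expect_lt(abs(fd[["spc_slp2"]]), 0.2)
  expect_gt(fd[["spc_slp4"]], -0.5)  # R^2 defined, low for flat spectrum

  # EEG-like (1/f) signal band-passed 0.5-40 Hz: gamma is the weakest band
  set.seed(20)
  pink <- eegsel:::pink_noise(256 * 16, 256, 1, 1)
  rec <- eeg_recording(matrix(pink, 1), fs = 256, channel_names = "c1")
  bp <- bandpass_filter(rec, 0.5, 40)
  ds <- downsample(bp, 128)
  fd2 <- freq_domain_features(ds$samples[1, ], 128)
  eb <- fd2[paste0("enrg_bnd", 1:5)]
  expect_equal(which.min(eb), 5L, ignore_attr = TRUE)
})

test_that("wavelet sub-band features follow the (levels+1)*2 count", {
  x <- rnorm(256)
  tf <- timefreq_domain_features(x, 128)
  expect_length(grep("^tk", names(tf)), 14)   # (6 + 1) * 2
  expect_length(grep("^wvlet", names(tf)), 6)

  z <- rep(0, 256)
  tfz <- timefreq_domain_features(z, 128)
  expect_true(all(tfz[paste0("wvlet", 1:6)] == -30))
  expect_true(all(tfz[paste0("tk", 1:14)] == 0))
})

test_that("white-noise wavelet energy concentrates in the finest detail", {
  # an orthonormal DWT spreads white-noise energy evenly per coefficient,
  # so the finest level (most coefficients) carries the most total energy
  set.seed(42)
  x <- rnorm(4096)
  dec <- dwt_db4(x, 6)
  tot <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  expect_equal(which.max(tot), 1L, ignore_attr = TRUE)
  # and energy is conserved up to boundary handling
  all_e <- sum(tot) + sum(dec$approx^2)
  expect_lt(abs(all_e / sum(x^2) - 1), 0.05)
})

test_that("the DWT agrees with an independent wavelet implementation", {
  set.seed(9)
  x <- rnorm(8192)
  dec <- dwt_db4(x, 3)
  out <- run_python(c(
    "import numpy as np, pywt",
    sprintf("x = np.array([%s])", paste(sprintf("%.12g", x), collapse = ",")),
    "c = pywt.wavedec(x, 'db4', mode='symmetric', level=3)",
    "print(' '.join('%.10g' % float(np.mean(d**2)) for d in c[1:][::-1]))"))
  ref <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  ours <- vapply(dec$details, function(d) mean(d^2), numeric(1))
  # same filter bank, independent implementation; boundary conventions and
  # decimation phase differ, so per-level energies agree statistically
  expect_equal(unname(ours), ref, tolerance = 0.05)
})

test_that("features transform correctly under scaling and shifting", {
  set.seed(5)
  x <- rnorm(256)
  a <- 3.7
  f1 <- time_domain_features(x, 128)
  f2 <- time_domain_features(a * x, 128)
  for (nm in c("zcross", "higuchi", "katz", "hurst", "decorr")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-8, label = nm)
  }
  expect_equal(f2[["ptp"]], a * f1[["ptp"]], tolerance = 1e-8)
  expect_equal(f2[["lnlen"]], a * f1[["lnlen"]], tolerance = 1e-8)
  expect_equal(f2[["std"]], a * f1[["std"]], tolerance = 1e-8)
  expect_equal(f2[["var"]], a^2 * f1[["var"]], tolerance = 1e-8)

  g1 <- freq_domain_features(x, 128)
  g2 <- freq_domain_features(a * x, 128)
  expect_equal(g2[["spc_slp2"]], g1[["spc_slp2"]], tolerance = 1e-8)
  expect_equal(g2[["spec_frq"]], g1[["spec_frq"]], tolerance = 1e-8)

  f3 <- time_domain_features(x + 100, 128)
  expect_equal(f3[["mean"]], f1[["mean"]] + 100, tolerance = 1e-8)
  expect_equal(f3[["zcross"]], f1[["zcross"]])  # computed on centred signal
  expect_equal(f3[["var"]], f1[["var"]], tolerance = 1e-8)
})

test_that("no feature is NaN or infinite on pathological inputs", {
  inputs <- list(rep(0, 256), rep(5, 256), c(rep(0, 255), 1),
                 seq_len(256) * 1e-9, rep(c(0, 0, 0, 1e8), 64))
  for (x in inputs) {
    v <- c(time_domain_features(x, 128), freq_domain_features(x, 128),
           timefreq_domain_features(x, 128))
    expect_true(all(is.finite(v)))
  }
})
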