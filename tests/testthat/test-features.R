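# Random-epoch oracle equivalence: every per-epoch feature must match an
# independent brute-force single-window implementation.

test_that("per-epoch features match brute-force oracles on random epochs", {
  withr::local_seed(101)
  fs <- 128
  n_sec <- 25
  x <- rnorm(fs * n_sec, sd = 20) + sin(2 * pi * 6 * (0:(fs * n_sec - 1)) / fs)

  teo <- teo_feature(x, fs)
  zcr <- zcr_feature(x, fs)
  lzc <- lzc_feature(x, fs)
  sh <- shannon_entropy_feature(x, fs)
  fd <- higuchi_fd_feature(x, fs)
  s2 <- variance_feature(x, fs)
  c60 <- mean_amplitude(x, fs, 25)   # covers warm-up and full-window seconds
  c2 <- mean_amplitude(x, fs, 2)
  stft <- stft_features(x, fs)

  o_teo <- oracle_teo(x, fs)
  o_zcr <- oracle_zcr(x, fs)
  epochs <- sample(n_sec, 20)
  for (t in epochs) {
    ep <- x[((t - 1) * fs + 1):(t * fs)]
    expect_equal(teo[t], o_teo[t], tolerance = 1e-9)
    expect_identical(as.integer(zcr[t]), as.integer(o_zcr[t]))
    expect_identical(as.integer(lzc[t]),
                     as.integer(oracle_lz76(as.integer(ep > median(ep)))))
    expect_equal(sh[t], oracle_shent(ep), tolerance = 1e-9)
    expect_equal(fd[t], oracle_higuchi(ep), tolerance = 1e-9)
    expect_equal(s2[t], oracle_variance(ep), tolerance = 1e-9)
  }
  expect_equal(c60, oracle_mean_amplitude(x, fs, 25), tolerance = 1e-12)
  expect_equal(c2, oracle_mean_amplitude(x, fs, 2), tolerance = 1e-12)
  for (t in sample(3:n_sec, 10)) {
    seg <- x[((t - 3) * fs + 1):(t * fs)]
    o <- oracle_stft_window(seg, fs)
    expect_equal(stft$Max_freq[t], o$max_freq, tolerance = 1e-9)
    expect_equal(stft$Mean_freq[t], o$mean_freq, tolerance = 1e-9)
    expect_equal(stft$Spec_area[t], o$spec_area, tolerance = 1e-9)
  }
})

test_that("mean amplitude windows share all but one second with their successor", {
  fs <- 128
  x <- abs(rnorm(fs * 70)) + 1
  c60 <- mean_amplitude(x, fs, 60, overlap = 59)
  # second 61 window = seconds 1..60; manually shifting one second reproduces it
  sums <- colSums(abs(matrix(x, nrow = fs)))
  expect_equal(c60[61], mean(abs(x[(1 * fs + 1):(61 * fs)])), tolerance = 1e-12)
  expect_error(mean_amplitude(x, fs, 60, overlap = 58), "1 Hz")
  expect_error(mean_amplitude(x, fs, 100), "longer")
  expect_equal(mean_amplitude(rep(3, fs * 10) * c(1, -1), fs, 2),
               rep(3, 10))   # constant |x| stays constant through warm-up
})

test_that("the macro-micro structure descriptor follows its defining ratio", {
  c_long <- runif(50, 1, 2)
  expect_equal(mmsd(c_long, c_long), rep(0, 50))
  expect_equal(mmsd(2 * c_long, c_long), rep(1, 50))
  # scale invariance for positive amplitudes
  expect_equal(mmsd(2.7 * c_long, 0.9 * c_long),
               mmsd(5 * 2.7 * c_long, 5 * 0.9 * c_long), tolerance = 1e-12)
  expect_warning(mmsd(c(1, 1), c(1, 0)), "floored")
  expect_error(mmsd(1:3, 1:4), "aligned")
})

test_that("MMSD localises a planted delta burst", {
  fs <- 128
  n_sec <- 200
  withr::local_seed(55)
  t <- (0:(fs * n_sec - 1)) / fs
  x <- sin(2 * pi * 2 * t) * 10 + rnorm(fs * n_sec, sd = 0.5)
  burst <- rep(1, fs * n_sec)
  burst[(100 * fs + 1):(110 * fs)] <- 2    # delta amplitude x2 for 10 s
  x <- x * burst
  c_long <- mean_amplitude(x, fs, 60)
  c_short <- mean_amplitude(x, fs, 2)
  m <- mmsd(c_short, c_long)
  expect_gt(mean(m[103:110]), 0.6)         # approximately 1 inside the burst
  expect_lt(max(abs(m[10:95])), 0.25)      # approximately 0 well outside
})

test_that("Teager energy matches closed forms", {
  fs <- 128
  expect_equal(teo_feature(rep(4, fs * 3), fs), rep(0, 3))
  expect_equal((function(x) x[2]^2 - x[1] * x[3])(c(1, 2, 3)), 1)
  # A*sin(Omega n): interior TEO is exactly A^2 sin^2(Omega)
  omega <- 2 * pi * 7 / fs
  x <- 3 * sin(omega * (0:(fs * 5)))
  expect_equal(teo_feature(x, fs), rep(9 * sin(omega)^2, 5), tolerance = 1e-9)
})

test_that("zero-crossing counts follow signal frequency", {
  fs <- 128
  expect_equal(zcr_feature(rep(2, fs * 4), fs), rep(0, 4))
  alt <- rep(c(1, -1), fs * 2)[1:(fs * 4)]
  expect_equal(zcr_feature(alt, fs)[1], 127)
  tone5 <- sin(2 * pi * 5 * (0:(fs * 6 - 1)) / fs + 0.3)
  expect_equal(as.numeric(zcr_feature(tone5, fs)[2:5]), rep(10, 4))
})

test_that("Lempel-Ziv complexity behaves as the parsing oracle dictates", {
  expect_equal(oracle_lz76(rep(0L, 128)), 2L)
  expect_equal(as.integer(lzc_feature(rep(c(1, 1), 128)[1:128] + 0:127 * 0, 128)), 2L)
  withr::local_seed(9)
  periodic <- rep(c(0L, 1L), 64)
  random <- sample(0:1, 128, replace = TRUE)
  expect_lt(oracle_lz76(periodic), oracle_lz76(random))
  # constant epoch has complexity 2 through the feature path as well
  expect_equal(as.integer(lzc_feature(rep(5, 256), 128)), c(2L, 2L))
})

test_that("STFT descriptors localise tones", {
  fs <- 128
  zero <- stft_features(rep(0, fs * 5), fs)
  expect_equal(zero$Spec_area, rep(0, 5))
  expect_equal(zero$Max_freq, rep(0, 5))
  tone <- sin(2 * pi * 10 * (0:(fs * 10 - 1)) / fs)
  st <- stft_features(tone, fs)
  expect_true(all(abs(st$Max_freq[4:10] - 10) <= 1 / 3 + 1e-9))
  mix <- sin(2 * pi * 5 * (0:(fs * 10 - 1)) / fs) +
    sin(2 * pi * 20 * (0:(fs * 10 - 1)) / fs)
  sm <- stft_features(mix, fs)
  expect_true(all(sm$Mean_freq[4:10] > 5 & sm$Mean_freq[4:10] < 20))
})

test_that("EMD always reports 12 levels and reconstructs its input", {
  withr::local_seed(77)
  fs <- 128
  x <- rnorm(fs * 20)
  dec <- emd_decompose(x)
  recon <- Reduce(`+`, dec$imfs) + dec$residual
  expect_equal(recon, x, tolerance = 1e-6)
  feats <- emd_features(x, fs)
  expect_equal(ncol(feats), 12)
  expect_equal(nrow(feats), 20)
  expect_error(emd_features(rnorm(fs * 5), fs), "10 s")
  # a pure tone concentrates in the first IMF
  tone <- sin(2 * pi * 10 * (0:(fs * 20 - 1)) / fs)
  dt <- emd_decompose(tone)
  expect_gte(sum(dt$imfs[[1]]^2) / sum(tone^2), 0.9)
})

test_that("Shannon entropy matches hand-computed histograms", {
  expect_equal(shannon_entropy_feature(rep(1, 256), 128), c(0, 0))
  # half the samples in each of two bins -> exactly 1 bit
  two_level <- rep(c(0, 1), each = 64)
  expect_equal(shannon_entropy_feature(two_level, 128), 1)
})

test_that("Higuchi dimension separates smooth from rough epochs", {
  ramp <- seq(0, 1, length.out = 128)
  fd_ramp <- higuchi_fd_feature(ramp, 128)
  expect_gte(fd_ramp, 1.0 - 1e-6)
  expect_lte(fd_ramp, 1.1)
  withr::local_seed(13)
  noise <- rnorm(128)
  fd_noise <- higuchi_fd_feature(noise, 128)
  expect_gte(fd_noise, 1.8)
  expect_lte(fd_noise, 2.05)
  expect_equal(higuchi_fd_feature(rep(2, 128), 128), 1.0)
})

test_that("variance feature implements the unbiased estimator", {
  expect_equal(variance_feature(rep(7, 256), 128), c(0, 0))
  x <- c(rep(c(1, 2, 3), length.out = 128))
  expect_equal(variance_feature(x, 128), var(x))
})

test_that("the extracted matrix has exactly the 55-name inventory", {
  nm <- cap_feature_names()
  expect_length(nm, 55)
  expect_false(any(duplicated(nm)))
  # band membership: MMSD/C/TEO sub-bands only, ZCR/LZC/variance include BB
  expect_length(grep("^MMSD_", nm), 5)
  expect_length(grep("^C_tau_", nm), 5)
  expect_length(grep("^C_tau0_", nm), 5)
  expect_length(grep("^TEO_", nm), 5)
  expect_length(grep("^ZCR_", nm), 6)
  expect_length(grep("^LZC_", nm), 6)
  expect_length(grep("^EMD_", nm), 12)
  expect_length(grep("^s2_", nm), 6)
  expect_true(all(c("Max_freq", "Mean_freq", "Spec_area", "ShEnt", "FD") %in% nm))
  expect_false(any(c("MMSD_BB", "TEO_BB", "C_tau_BB") %in% nm))
})

test_that("feature extraction is deterministic with one row per second", {
  rec <- generate_background(150, 128, 25, seed = 21)
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 150)
  expect_equal(setdiff(names(f1), c("subject", "second")), cap_feature_names())
  expect_true(all(vapply(f1[cap_feature_names()], \(v) all(is.finite(v)), TRUE)))
  expect_error(extract_features(eeg_recording(rnorm(128 * 60), 128)), "120")
})
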