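#' Canonical names of the 55 per-second features
#'
#' Fixed inventory and order: the macro--micro structure descriptor and the
#' two mean-amplitude series over the five sub-bands, Teager energy over the
#' sub-bands, zero-crossing rate, Lempel--Ziv complexity and variance over
#' the broadband signal plus all sub-bands, three short-time Fourier
#' descriptors, twelve empirical-mode-decomposition levels, Shannon entropy
#' and Higuchi fractal dimension on the broadband signal.
#'
#' @return Character vector of 55 names.
#' @export
cap_feature_names <- function() {
  sb <- sub_bands()
  c(paste0("MMSD_", sb),
    paste0("C_tau_", sb),
    paste0("C_tau0_", sb),
    paste0("TEO_", sb),
    paste0("ZCR_", all_bands()),
    paste0("LZC_", all_bands()),
    "Max_freq", "Mean_freq", "Spec_area",
    paste0("EMD_", 1:12),
    "ShEnt", "FD",
    paste0("s2_", all_bands()))
}

# split a signal into 1 s non-overlapping epochs (columns)
epoch_matrix <- function(x, fs) {
  n_sec <- floor(length(x) / fs)
  matrix(x[seq_len(n_sec * fs)], nrow = fs)
}

#' Trailing-window mean amplitude at 1 Hz
#'
#' Mean of the rectified (absolute) band signal over a trailing window
#' ending at `t + 1` s, emitted every second. With `window = 60`,
#' `overlap = 59` this is the background amplitude (consecutive windows
#' share 59 s); with `window = 2`, `overlap = 1` the instantaneous
#' amplitude. Seconds earlier than the window length use all samples
#' available so far, so every second has a value.
#'
#' @param x Band-filtered signal.
#' @param fs Sampling rate (Hz).
#' @param window Window length in seconds.
#' @param overlap Overlap between consecutive windows in seconds; the step
#'   `window - overlap` must be 1 s so the output is sampled at 1 Hz.
#' @return Numeric vector, one value per complete second.
#' @export
mean_amplitude <- function(x, fs, window, overlap = window - 1) {
  if (window - overlap != 1)
    abort("`window - overlap` must be 1 s (features are sampled at 1 Hz).")
  n_sec <- floor(length(x) / fs)
  if (window > n_sec) abort("`window` is longer than the signal.")
  sec_sums <- colSums(abs(epoch_matrix(x, fs)))
  cs <- c(0, cumsum(sec_sums))
  t1 <- seq_len(n_sec)                      # t + 1 for t = 0 .. n_sec-1
  lo <- pmax(t1 - window, 0)
  (cs[t1 + 1] - cs[lo + 1]) / ((t1 - lo) * fs)
}

#' Macro--micro structure descriptor
#'
#' Relative excess of the short-window mean amplitude over the long-window
#' background amplitude, `(C_short - C_long) / C_long`, computed
#' elementwise on aligned 1 Hz series. Denominators below `eps` are floored
#' at `eps` with a warning.
#'
#' @param c_short Instantaneous amplitude series (2 s window).
#' @param c_long Background amplitude series (60 s window).
#' @param eps Denominator floor in uV (default `1e-12`).
#' @return Numeric vector, same length as the inputs.
#' @export
mmsd <- function(c_short, c_long, eps = 1e-12) {
  if (length(c_short) != length(c_long))
    abort("`c_short` and `c_long` must be aligned (equal length).")
  if (any(c_long < eps))
    warn("Background amplitude below epsilon floored for MMSD.")
  (c_short - c_long) / pmax(c_long, eps)
}

#' Teager energy feature at 1 Hz
#'
#' The Teager energy operator `x[n]^2 - x[n-1] * x[n+1]` is applied to the
#' whole sequence first (it is non-causal), then each 1 s non-overlapping
#' epoch is represented by its maximum value.
#'
#' @param x Band-filtered signal (length >= 3).
#' @param fs Sampling rate (Hz).
#' @return Numeric vector, one value per complete second.
#' @export
teo_feature <- function(x, fs) {
  n <- length(x)
  if (n < 3) abort("Signal must have at least 3 samples.")
  teo <- rep(NA_real_, n)
  teo[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  m <- epoch_matrix(teo, fs)
  apply(m, 2, max, na.rm = TRUE)
}

#' Zero-crossing rate at 1 Hz
#'
#' Sign changes of the signal counted per 1 s non-overlapping epoch; a
#' crossing between samples `n` and `n + 1` is attributed to the epoch of
#' sample `n + 1`. A sample equal to zero takes the sign of the previous
#' nonzero sample, so only strict sign changes count.
#'
#' @param x Band-filtered signal.
#' @param fs Sampling rate (Hz).
#' @return Integer-valued numeric vector, one count per complete second.
#' @export
zcr_feature <- function(x, fs) {
  s <- sign(x)
  nz <- s != 0
  if (any(nz)) {
    idx <- cummax(seq_along(s) * nz)
    first_sign <- s[nz][1]
    filled <- ifelse(idx > 0, s[nz][cumsum(nz)], first_sign)
  } else {
    filled <- rep(1, length(s))
  }
  crossing <- c(0, as.numeric(diff(filled) != 0))  # position n+1 flags a crossing
  colSums(epoch_matrix(crossing, fs))
}

# Lempel-Ziv 1976 complexity (number of phrases in the exhaustive
# production history), Kaspar-Schuster formulation.
lz76 <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  cplx <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cplx <- cplx + 1L; break }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cplx <- cplx + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cplx
}

#' Lempel--Ziv complexity at 1 Hz
#'
#' Each 1 s epoch is binarised against a threshold (samples strictly above
#' it become 1) and the Lempel--Ziv 1976 exhaustive-parsing complexity (the
#' unnormalised dictionary size) is returned. The default threshold is the
#' epoch median.
#'
#' @param x Band-filtered signal.
#' @param fs Sampling rate (Hz).
#' @param threshold_rule `"median"` (default) or `"mean"`.
#' @return Integer-valued numeric vector, one complexity per second.
#' @export
lzc_feature <- function(x, fs, threshold_rule = c("median", "mean")) {
  threshold_rule <- match.arg(threshold_rule)
  m <- epoch_matrix(x, fs)
  thr_fun <- if (threshold_rule == "median") median else mean
  apply(m, 2, function(ep) lz76(as.integer(ep > thr_fun(ep))))
}

#' Short-time Fourier descriptors at 1 Hz
#'
#' A Hamming-windowed discrete Fourier transform over a trailing 3 s window
#' (2 s overlap between consecutive windows, i.e. the window covers
#' `[t - 2, t + 1)`; early seconds use the samples available so far). From
#' the one-sided magnitude spectrum three descriptors are extracted: the
#' frequency of maximum energy (`Max_freq`, Hz; 0 for an all-zero
#' spectrum), the magnitude-weighted mean frequency, i.e. the spectral
#' centroid (`Mean_freq`, Hz), and the trapezoidal area under the magnitude
#' spectrum (`Spec_area`).
#'
#' @param x Broadband signal.
#' @param fs Sampling rate (Hz).
#' @return Tibble with columns `Max_freq`, `Mean_freq`, `Spec_area`, one
#'   row per complete second.
#' @export
stft_features <- function(x, fs) {
  n_sec <- floor(length(x) / fs)
  if (n_sec < 3) abort("Signal must be at least 3 s long.")
  out <- matrix(0, nrow = n_sec, ncol = 3)
  for (t in seq_len(n_sec) - 1L) {
    i0 <- max(0L, (t - 2L)) * fs
    seg <- x[(i0 + 1L):((t + 1L) * fs)]
    nw <- length(seg)
    w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))
    sp <- fft(seg * w)
    half <- 1:(nw %/% 2 + 1)
    mag <- Mod(sp[half])
    freqs <- (half - 1) * fs / nw
    tot <- sum(mag)
    max_f <- if (tot == 0) 0 else freqs[which.max(mag)]
    mean_f <- if (tot == 0) 0 else sum(freqs * mag) / tot
    area <- sum(diff(freqs) * (mag[-1] + mag[-length(mag)]) / 2)
    out[t + 1L, ] <- c(max_f, mean_f, area)
  }
  tibble(Max_freq = out[, 1], Mean_freq = out[, 2], Spec_area = out[, 3])
}

#' Empirical-mode-decomposition features at 1 Hz
#'
#' The broadband signal is decomposed once over its full length (windowing
#' first would distort the sifting), then each IMF is averaged over 1 s
#' non-overlapping epochs. Always returns 12 series; when the sifting
#' yields fewer IMFs the missing levels are zero-filled, and extra IMFs are
#' discarded.
#'
#' @param x Broadband signal (at least 10 s).
#' @param fs Sampling rate (Hz).
#' @param levels Number of decomposition levels (default 12).
#' @return Tibble with columns `EMD_1` ... `EMD_<levels>`, one row per
#'   complete second.
#' @export
emd_features <- function(x, fs, levels = 12L) {
  if (length(x) < 10 * fs) abort("Signal must be at least 10 s long for EMD.")
  dec <- emd_decompose(x, max_imfs = levels)
  n_sec <- floor(length(x) / fs)
  cols <- lapply(seq_len(levels), function(l) {
    if (l <= length(dec$imfs)) colMeans(epoch_matrix(dec$imfs[[l]], fs))
    else rep(0, n_sec)
  })
  names(cols) <- paste0("EMD_", seq_len(levels))
  tibble::as_tibble(cols)
}

#' Shannon entropy at 1 Hz
#'
#' Entropy (bits) of the amplitude distribution per 1 s epoch, over a
#' fixed-count equal-width histogram spanning the epoch's own range. A
#' constant epoch has entropy 0.
#'
#' @param x Broadband signal.
#' @param fs Sampling rate (Hz).
#' @param bins Histogram bin count (default 16).
#' @return Numeric vector, one entropy per second.
#' @export
shannon_entropy_feature <- function(x, fs, bins = 16L) {
  m <- epoch_matrix(x, fs)
  apply(m, 2, function(ep) {
    r <- range(ep)
    if (r[1] == r[2]) return(0)
    breaks <- seq(r[1], r[2], length.out = bins + 1L)
    cnt <- tabulate(pmin(findInterval(ep, breaks, rightmost.closed = TRUE), bins),
                    nbins = bins)
    p <- cnt / length(ep)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

higuchi_fd_epoch <- function(ep, k_max) {
  n <- length(ep)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lms <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) { lms[m] <- NA_real_; next }
      lms[m] <- sum(abs(diff(ep[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lms, na.rm = TRUE)
  }
  if (any(lk <= 0) || !all(is.finite(lk))) return(1.0)
  stats::coef(lm(y ~ x, data = data.frame(y = log(lk), x = log(1 / seq_len(k_max)))))[[2]]
}

#' Higuchi fractal dimension at 1 Hz
#'
#' Higuchi's curve-length estimator per 1 s non-overlapping epoch: the
#' least-squares slope of log mean curve length against log(1/k) for
#' `k = 1 .. k_max`. Constant epochs are reported as 1 by convention.
#'
#' @param x Broadband signal.
#' @param fs Sampling rate (Hz).
#' @param k_max Maximum interval (default 8).
#' @return Numeric vector, one dimension per second.
#' @export
higuchi_fd_feature <- function(x, fs, k_max = 8L) {
  m <- epoch_matrix(x, fs)
  apply(m, 2, higuchi_fd_epoch, k_max = k_max)
}

#' Sample variance at 1 Hz
#'
#' Unbiased sample variance (divisor `N - 1`) per 1 s non-overlapping
#' epoch.
#'
#' @param x Band-filtered signal.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector, one variance per second.
#' @export
variance_feature <- function(x, fs) {
  m <- epoch_matrix(x, fs)
  n <- nrow(m)
  colSums((m - matrix(colMeans(m), n, ncol(m), byrow = TRUE))^2) / (n - 1)
}

#' Extract the 55 per-second features of a recording
#'
#' Runs the full feature bank on one recording: band decomposition, then
#' every feature on its prescribed bands and windows, all aligned on the
#' 1 Hz grid (early seconds of the trailing-window features use growing
#' windows, so all 55 series share one time base).
#'
#' @param recording An [eeg_recording()] of at least 120 s.
#' @param tau Background amplitude window in seconds (default 60).
#' @param tau0 Instantaneous amplitude window in seconds (default 2).
#' @return Tibble with columns `subject`, `second` (0-based) and the 55
#'   feature columns of [cap_feature_names()], one row per second.
#' @export
extract_features <- function(recording, tau = 60, tau0 = 2) {
  if (tau <= tau0 || tau0 < 1) abort("Windows must satisfy tau > tau0 >= 1.")
  n_sec <- recording_seconds(recording)
  if (n_sec < 120) abort("Recording must be at least 120 s long.")
  fs <- recording$fs
  bs <- decompose_bands(recording)
  sb <- sub_bands()
  cols <- list()
  c_tau <- lapply(sb, function(b) mean_amplitude(bs$signals[[b]], fs, tau))
  c_tau0 <- lapply(sb, function(b) mean_amplitude(bs$signals[[b]], fs, tau0))
  names(c_tau) <- names(c_tau0) <- sb
  for (b in sb) cols[[paste0("MMSD_", b)]] <- mmsd(c_tau0[[b]], c_tau[[b]])
  for (b in sb) cols[[paste0("C_tau_", b)]] <- c_tau[[b]]
  for (b in sb) cols[[paste0("C_tau0_", b)]] <- c_tau0[[b]]
  for (b in sb) cols[[paste0("TEO_", b)]] <- teo_feature(bs$signals[[b]], fs)
  for (b in all_bands()) cols[[paste0("ZCR_", b)]] <- zcr_feature(bs$signals[[b]], fs)
  for (b in all_bands()) cols[[paste0("LZC_", b)]] <- lzc_feature(bs$signals[[b]], fs)
  stft <- stft_features(bs$signals$BB, fs)
  cols$Max_freq <- stft$Max_freq
  cols$Mean_freq <- stft$Mean_freq
  cols$Spec_area <- stft$Spec_area
  emd <- emd_features(bs$signals$BB, fs)
  for (nm in names(emd)) cols[[nm]] <- emd[[nm]]
  cols$ShEnt <- shannon_entropy_feature(bs$signals$BB, fs)
  cols$FD <- higuchi_fd_feature(bs$signals$BB, fs)
  for (b in all_bands()) cols[[paste0("s2_", b)]] <- variance_feature(bs$signals[[b]], fs)
  cols <- cols[cap_feature_names()]
  dplyr::bind_cols(
    tibble(subject = recording$subject_id, second = seq_len(n_sec) - 1L),
    tibble::as_tibble(cols)
  )
}
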