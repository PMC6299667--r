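# Independent brute-force single-window implementations used to cross-check
# the vectorised feature extractors. Each one follows the defining formula
# directly, with explicit loops, sharing no code with the package.

oracle_mean_amplitude <- function(x, fs, window) {
  n_sec <- floor(length(x) / fs)
  out <- numeric(n_sec)
  for (t in seq_len(n_sec) - 1) {
    lo <- max(0, t + 1 - window)
    seg <- x[(lo * fs + 1):((t + 1) * fs)]
    out[t + 1] <- mean(abs(seg))
  }
  out
}

oracle_teo <- function(x, fs) {
  n <- length(x)
  teo <- numeric(n - 2)
  for (i in 2:(n - 1)) teo[i - 1] <- x[i]^2 - x[i - 1] * x[i + 1]
  n_sec <- floor(n / fs)
  out <- numeric(n_sec)
  for (t in seq_len(n_sec)) {
    # positions of the epoch in the original signal, interior only
    pos <- ((t - 1) * fs + 1):(t * fs)
    pos <- pos[pos >= 2 & pos <= n - 1]
    out[t] <- max(teo[pos - 1])
  }
  out
}

oracle_zcr <- function(x, fs) {
  # previous-nonzero-sign rule applied with an explicit scan
  s <- numeric(length(x))
  last <- 0
  first_nz <- sign(x[which(x != 0)[1]])
  if (is.na(first_nz)) first_nz <- 1
  for (i in seq_along(x)) {
    if (x[i] != 0) last <- sign(x[i])
    s[i] <- if (last == 0) first_nz else last
  }
  n_sec <- floor(length(x) / fs)
  out <- integer(n_sec)
  for (i in 2:length(x)) {
    if (s[i] != s[i - 1]) {
      ep <- floor((i - 1) / fs) + 1   # epoch of sample i (1-based)
      if (ep <= n_sec) out[ep] <- out[ep] + 1L
    }
  }
  out
}

# Exhaustive production-history parser: each phrase is the longest prefix of
# the remainder reproducible from the already-seen text, extended by one
# novel symbol (the final phrase may be fully reproducible).
oracle_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  phrases <- 0L
  pos <- 1L
  while (pos <= n) {
    l <- 0L
    while (pos + l <= n) {
      cand <- substr(s, pos, pos + l)
      if (grepl(cand, substr(s, 1, pos + l - 1), fixed = TRUE)) l <- l + 1L
      else break
    }
    phrases <- phrases + 1L
    pos <- pos + l + 1L
  }
  phrases
}

oracle_shent <- function(ep, bins = 16) {
  r <- range(ep)
  if (r[1] == r[2]) return(0)
  h <- hist(ep, breaks = seq(r[1], r[2], length.out = bins + 1), plot = FALSE)
  p <- h$counts / length(ep)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_variance <- function(ep) {
  m <- sum(ep) / length(ep)
  acc <- 0
  for (v in ep) acc <- acc + (v - m)^2
  acc / (length(ep) - 1)
}

oracle_higuchi <- function(ep, k_max = 8) {
  n <- length(ep)
  lk <- numeric(k_max)
  for (k in 1:k_max) {
    lm <- c()
    for (m in 1:k) {
      steps <- floor((n - m) / k)
      if (steps < 1) next
      len <- 0
      for (i in 1:steps) len <- len + abs(ep[m + i * k] - ep[m + (i - 1) * k])
      lm <- c(lm, len * (n - 1) / (steps * k) / k)
    }
    lk[k] <- mean(lm)
  }
  if (any(lk <= 0)) return(1)
  fit <- lm(log(lk) ~ log(1 / (1:k_max)))
  unname(coef(fit)[2])
}

oracle_stft_window <- function(seg, fs) {
  nw <- length(seg)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  sp <- fft(seg * w)
  half <- 1:(nw %/% 2 + 1)
  mag <- abs(sp[half])
  freqs <- (half - 1) * fs / nw
  area <- 0
  for (i in 2:length(mag)) area <- area + (freqs[i] - freqs[i - 1]) * (mag[i] + mag[i - 1]) / 2
  list(max_freq = if (sum(mag) == 0) 0 else freqs[which.max(mag)],
       mean_freq = if (sum(mag) == 0) 0 else sum(freqs * mag) / sum(mag),
       spec_area = area)
}

oracle_fft_gain <- function(filter_out, filter_in, fs, freq) {
  # steady-state amplitude ratio at `freq` via the discrete spectrum of the
  # second half of the signals (transient discarded)
  n <- length(filter_in)
  keep <- (n %/% 2 + 1):n
  amp <- function(x) {
    sp <- abs(fft(x[keep]))
    k <- round(freq * length(keep) / fs) + 1
    max(sp[max(1, k - 1):(k + 1)])
  }
  amp(filter_out) / amp(filter_in)
}
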