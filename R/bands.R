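#' Conventional EEG frequency bands
#'
#' Band edges (Hz) used throughout: the clinical broadband signal `BB`
#' (0.3--35 Hz) and the five conventional sub-bands delta (0.3--4), theta
#' (4--8), alpha (8--13), sigma (13--16) and beta (16--35).
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
cap_band_edges <- function() {
  list(BB    = c(0.3, 35),
       delta = c(0.3, 4),
       theta = c(4, 8),
       alpha = c(8, 13),
       sigma = c(13, 16),
       beta  = c(16, 35))
}

sub_bands <- function() c("delta", "theta", "alpha", "sigma", "beta")
all_bands <- function() c("BB", sub_bands())

# Third-order Butterworth band-pass as a cascade of biquad sections.
# Direct-form order-6 transfer functions are ill-conditioned for a 0.3 Hz
# edge at 512 Hz; the cascade keeps each section well-scaled. A band-pass
# Butterworth has all zeros at z = +/-1, so every section is (1 - z^-2)
# over a conjugate pole pair, with the overall gain applied once.
butter_bp_sos <- function(fs, low, high, order = 3L) {
  key <- sprintf("%.10g|%.10g|%.10g|%d", fs, low, high, order)
  hit <- .sos_cache[[key]]
  if (!is.null(hit)) return(hit)
  ba <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  p <- polyroot(rev(ba$a))
  is_real <- abs(Im(p)) < 1e-8
  upper <- p[!is_real & Im(p) > 0]
  upper <- upper[order(Mod(upper), decreasing = TRUE)]
  sects <- lapply(upper, function(pk) c(1, -2 * Re(pk), Mod(pk)^2))
  re <- sort(Re(p[is_real]))
  while (length(re) >= 2) {
    sects <- c(sects, list(c(1, -(re[1] + re[2]), re[1] * re[2])))
    re <- re[-(1:2)]
  }
  stopifnot(length(sects) == order, length(re) == 0)
  out <- list(gain = ba$b[1], sections = sects)
  .sos_cache[[key]] <- out
  out
}

.sos_cache <- new.env(parent = emptyenv())

#' Causal Butterworth band-pass filter
#'
#' Applies a third-order band-pass Butterworth filter in a single causal
#' pass (no forward--backward filtering: the per-second amplitude features
#' are defined on past samples, so the whole chain stays causal; the phase
#' delay is accepted).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Filter order (default 3).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low, high, order = 3L) {
  if (!(low > 0 && high > low && high < fs / 2))
    abort("Band edges must satisfy 0 < low < high < fs/2.")
  sos <- butter_bp_sos(fs, low, high, order)
  y <- x * sos$gain
  for (a in sos$sections) {
    y <- as.numeric(signal::filter(signal::Arma(b = c(1, 0, -1), a = a), y))
  }
  y
}

#' Decompose a recording into the six frequency bands
#'
#' Produces the broadband signal and the five conventional sub-band signals
#' via [bandpass()], all the same length as the input.
#'
#' @param recording An [eeg_recording()].
#' @return An object of class `band_set`: list with `signals` (named list of
#'   six numeric vectors, `BB`, `delta`, `theta`, `alpha`, `sigma`, `beta`),
#'   `fs`, `band_edges` and `subject_id`.
#' @export
decompose_bands <- function(recording) {
  edges <- cap_band_edges()
  sigs <- lapply(edges, function(e)
    bandpass(recording$samples, recording$fs, e[1], e[2]))
  structure(
    list(signals = sigs, fs = recording$fs, band_edges = edges,
         subject_id = recording$subject_id),
    class = "band_set"
  )
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> subject %s: %d samples @ %g Hz in bands %s\n",
              x$subject_id, length(x$signals$BB), x$fs,
              paste(names(x$signals), collapse = ", ")))
  invisible(x)
}
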