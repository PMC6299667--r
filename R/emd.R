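#' Empirical mode decomposition by classical sifting
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) with
#' cubic-spline upper/lower envelopes (mirrored end extrema) and the
#' classical Cauchy-type stopping criterion. By construction the IMFs plus
#' the returned residual reconstruct the input exactly.
#'
#' @param x Numeric signal.
#' @param max_imfs Maximum number of IMFs to extract (default 12).
#' @param max_sifts Sifting iterations allowed per IMF (default 200).
#' @param tol Cauchy stopping tolerance on the normalised squared change
#'   between consecutive sifts (default 0.2).
#' @return List with `imfs` (list of numeric vectors, possibly shorter than
#'   `max_imfs` when the residual runs out of oscillations) and `residual`.
#' @export
emd_decompose <- function(x, max_imfs = 12L, max_sifts = 200L, tol = 0.2) {
  n <- length(x)
  r <- x
  imfs <- list()
  for (l in seq_len(max_imfs)) {
    ext <- local_extrema(r)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    h <- r
    for (s in seq_len(max_sifts)) {
      ext <- local_extrema(h)
      if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
      upper <- envelope_spline(ext$maxima, h, n)
      lower <- envelope_spline(ext$minima, h, n)
      m <- (upper + lower) / 2
      h_new <- h - m
      denom <- sum(h^2)
      sdval <- if (denom > 0) sum((h - h_new)^2) / denom else 0
      h <- h_new
      if (sdval < tol) break
    }
    imfs[[l]] <- h
    r <- r - h
  }
  list(imfs = imfs, residual = r)
}

# Strict local extrema; plateaus are collapsed via the sign of the
# first difference carried over zero runs.
local_extrema <- function(x) {
  d <- sign(diff(x))
  nz <- d != 0
  if (!any(nz)) return(list(maxima = integer(), minima = integer()))
  filled <- d
  idx <- cummax(seq_along(d) * nz)
  has <- idx > 0
  filled[has] <- d[nz][cumsum(nz)][has]
  dd <- diff(filled)
  maxima <- which(dd < 0) + 1L
  minima <- which(dd > 0) + 1L
  list(maxima = maxima, minima = minima)
}

envelope_spline <- function(knots, x, n) {
  xs <- knots
  ys <- x[knots]
  # mirror the first and last extremum around the signal ends
  xs <- c(2 - xs[1], xs, 2 * n - xs[length(xs)])
  ys <- c(ys[1], ys, ys[length(ys)])
  stats::spline(xs, ys, xout = seq_len(n), method = "natural")$y
}
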