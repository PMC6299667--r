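#' Causal moving-average smoothing
#'
#' Order-`order` uniform FIR filter: the value at `t` is the mean of the
#' current and the previous `order` values (`order + 1` taps). Initial
#' samples are averaged over the history available so far, so the output
#' has no warm-up gap.
#'
#' @param x Numeric series at 1 Hz.
#' @param order Filter order, i.e. number of delays (default 30).
#' @return Smoothed series, same length.
#' @export
causal_moving_average <- function(x, order = 30L) {
  if (order < 1) abort("`order` must be at least 1.")
  n <- length(x)
  cs <- c(0, cumsum(x))
  t1 <- seq_len(n)
  lo <- pmax(t1 - order - 1L, 0)
  (cs[t1 + 1] - cs[lo + 1]) / (t1 - lo)
}

#' Replace outliers by the series median
#'
#' Values more than `sd_threshold` standard deviations from the mean are
#' replaced by the series median; mean, SD and median all come from the
#' original series in a single pass. The threshold defaults to 4 rather
#' than the customary 3 because A-phases are themselves large excursions
#' that must not be clipped. A zero-variance series is returned unchanged.
#'
#' @param x Numeric series.
#' @param sd_threshold Threshold in standard deviations (default 4).
#' @return Series with outliers replaced.
#' @export
replace_outliers <- function(x, sd_threshold = 4) {
  if (sd_threshold <= 0) abort("`sd_threshold` must be positive.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x)
  out <- abs(x - mean(x)) > sd_threshold * s
  x[out] <- median(x)
  x
}

#' Min--max normalisation to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant series maps to all zeros by
#' convention. Invariant under positive affine transforms of the input.
#'
#' @param x Numeric series.
#' @return Normalised series in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Conditioning configuration
#'
#' @param smoothing_order Moving-average order (default 30).
#' @param outlier_sd Outlier threshold in standard deviations (default 4).
#' @param exempt_prefixes Feature-name prefixes exempt from smoothing.
#'   Default `c("MMSD", "TEO", "EMD")`: these detect transient amplitude or
#'   frequency changes that smoothing would erase. The amplitude series
#'   `C_tau`/`C_tau0` are *not* exempt (the exemption list is read
#'   literally).
#' @return List of class `conditioning_config`.
#' @export
conditioning_config <- function(smoothing_order = 30L, outlier_sd = 4,
                                exempt_prefixes = c("MMSD", "TEO", "EMD")) {
  if (smoothing_order < 1) abort("`smoothing_order` must be at least 1.")
  if (outlier_sd <= 0) abort("`outlier_sd` must be positive.")
  structure(list(smoothing_order = as.integer(smoothing_order),
                 outlier_sd = outlier_sd,
                 exempt_prefixes = exempt_prefixes),
            class = "conditioning_config")
}

#' Condition a feature table
#'
#' Applies, in this fixed order and independently per feature column and
#' per subject: (1) causal moving-average smoothing of every feature whose
#' name does not start with an exempt prefix; (2) outlier replacement by
#' the median; (3) min--max normalisation to `[0, 1]`. Statistics are never
#' shared across subjects, so the step is leakage-free by construction.
#'
#' @param features Tibble from [extract_features()] (columns `subject`,
#'   `second` and feature columns).
#' @param config A [conditioning_config()].
#' @return Tibble of the same shape with conditioned feature values, all
#'   finite and in `[0, 1]`.
#' @export
condition_features <- function(features, config = conditioning_config()) {
  feat_cols <- setdiff(names(features), c("subject", "second", "label"))
  exempt <- vapply(feat_cols, function(nm)
    any(startsWith(nm, config$exempt_prefixes)), logical(1))
  features |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(feat_cols),
      function(v) {
        nm <- dplyr::cur_column()
        if (!exempt[[nm]]) v <- causal_moving_average(v, config$smoothing_order)
        v <- replace_outliers(v, config$outlier_sd)
        minmax_normalize(v)
      }
    )) |>
    dplyr::ungroup()
}
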