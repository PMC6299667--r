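#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Build a ready-to-classify dataset from a synthetic cohort
#'
#' Convenience wrapper over the full per-subject pipeline: extract the 55
#' features of every recording, condition them per subject, and join the
#' ground-truth per-second labels.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [conditioning_config()].
#' @return Tibble with `subject`, `second`, `label` and the 55 conditioned
#'   feature columns, all subjects stacked.
#' @export
cohort_dataset <- function(cohort, config = conditioning_config()) {
  feats <- dplyr::bind_rows(lapply(cohort$recordings, extract_features))
  feats <- condition_features(feats, config)
  dplyr::inner_join(cohort_labels(cohort), feats, by = c("subject", "second"))
}
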