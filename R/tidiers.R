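#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a leave-one-subject-out evaluation
#'
#' @param x A `cap_loso` object.
#' @param ... Unused.
#' @return Tibble with one row per fold: `subject`, `wac`, `ac`.
#' @method tidy cap_loso
#' @export
tidy.cap_loso <- function(x, ...) {
  dplyr::select(x$folds, "subject", "wac", "ac")
}

#' One-row summary of a leave-one-subject-out evaluation
#'
#' @param x A `cap_loso` object.
#' @param ... Unused.
#' @return Tibble with `task`, `classifier`, `n_folds`, `mean_wac`,
#'   `mean_ac`, `pooled_wac`, `pooled_ac`.
#' @method glance cap_loso
#' @export
glance.cap_loso <- function(x, ...) {
  tibble(task = x$task, classifier = x$classifier, n_folds = nrow(x$folds),
         mean_wac = x$mean_wac, mean_ac = x$mean_ac,
         pooled_wac = x$pooled_metrics$wac, pooled_ac = x$pooled_metrics$ac)
}

#' Tidy a confusion matrix
#'
#' @param x A `cap_confusion` matrix.
#' @param ... Unused.
#' @return Long tibble with `predicted`, `true`, `n` and `percent` (of the
#'   true class).
#' @method tidy cap_confusion
#' @export
tidy.cap_confusion <- function(x, ...) {
  pct <- confusion_percent(x)
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("predicted", "true", "n")
  df$percent <- as.vector(pct)
  tibble::as_tibble(df)
}

#' Tidy performance metrics
#'
#' @param x A `cap_metrics` object.
#' @param ... Unused.
#' @return Tibble with per-class `se` and `sp`.
#' @method tidy cap_metrics
#' @export
tidy.cap_metrics <- function(x, ...) x$per_class

#' One-row summary of performance metrics
#'
#' @param x A `cap_metrics` object.
#' @param ... Unused.
#' @return Tibble with `ac`, `wac`, `n`.
#' @method glance cap_metrics
#' @export
glance.cap_metrics <- function(x, ...) tibble(ac = x$ac, wac = x$wac, n = x$n)

#' Tidy an mRMR ranking
#'
#' @param x A `cap_ranking` tibble.
#' @param ... Unused.
#' @return The ranking tibble (`rank`, `feature`, `score`).
#' @method tidy cap_ranking
#' @export
tidy.cap_ranking <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a grid-search result
#'
#' @param x A `cap_grid_search` object.
#' @param ... Unused.
#' @return The grid tibble with WAC per `(C, gamma)` pair.
#' @method tidy cap_grid_search
#' @export
tidy.cap_grid_search <- function(x, ...) x$grid

#' One-row summary of a grid search
#'
#' @param x A `cap_grid_search` object.
#' @param ... Unused.
#' @return Tibble with `best_C`, `best_gamma`, `protocol`.
#' @method glance cap_grid_search
#' @export
glance.cap_grid_search <- function(x, ...) {
  tibble(best_C = x$best_C, best_gamma = x$best_gamma, protocol = x$protocol)
}
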