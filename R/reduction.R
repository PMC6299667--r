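discretize_tertiles <- function(v) {
  qs <- unique(quantile(v, c(1 / 3, 2 / 3), names = FALSE))
  findInterval(v, qs, left.open = TRUE)
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pr, pc)[idx]))
}

#' Rank features by minimum-redundancy maximum-relevance
#'
#' Greedy forward mRMR ranking in the mutual-information difference (MID)
#' form: the first feature maximises mutual information with the class
#' labels; each subsequent pick maximises relevance minus the mean mutual
#' information with the already-selected features. Features are discretised
#' into tertiles before mutual-information estimation. Ties break toward
#' the earlier column, making the ranking deterministic.
#'
#' @param data Tibble with a `label` column (factor) and feature columns
#'   (any `subject`/`second` columns are ignored).
#' @return Tibble of class `cap_ranking` with columns `rank`, `feature`,
#'   `score` (relevance minus redundancy at selection time).
#' @export
mrmr_rank <- function(data) {
  labels <- data$label
  if (is.null(labels)) abort("`data` must contain a `label` column.")
  if (length(unique(labels)) < 2)
    abort("mRMR needs at least 2 classes present in the labels.")
  feat_cols <- setdiff(names(data), c("subject", "second", "label"))
  disc <- lapply(data[feat_cols], discretize_tertiles)
  relevance <- vapply(disc, mutual_information, numeric(1), b = labels)
  p <- length(feat_cols)
  selected <- integer(0)
  scores <- numeric(0)
  red <- matrix(NA_real_, p, p)              # pairwise MI cache
  remaining <- seq_len(p)
  for (step in seq_len(p)) {
    if (step == 1L) {
      crit <- relevance
    } else {
      crit <- vapply(remaining, function(j) {
        for (s in selected) {
          if (is.na(red[s, j])) red[s, j] <<- red[j, s] <<-
              mutual_information(disc[[s]], disc[[j]])
        }
        relevance[j] - mean(red[selected, j])
      }, numeric(1))
    }
    if (step == 1L) {
      best <- remaining[which.max(crit[remaining])]
      scores <- c(scores, relevance[best])
    } else {
      best <- remaining[which.max(crit)]
      scores <- c(scores, crit[which.max(crit)])
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  structure(
    tibble(rank = seq_len(p), feature = feat_cols[selected], score = scores),
    class = c("cap_ranking", class(tibble())))
}

#' Fit a principal-component projection
#'
#' Centred-data eigendecomposition via [stats::prcomp()] (no rescaling:
#' features are already min--max normalised). Components are orthonormal
#' and sorted by decreasing explained variance. If `n_components` exceeds
#' the data rank the retained set is truncated with a warning.
#'
#' @param data Tibble with feature columns (any `subject`, `second`,
#'   `label` columns are ignored).
#' @param n_components Number of directions to retain.
#' @return Object of class `cap_pca`: list with `mean`, `rotation`,
#'   `sdev`, `feature_names`, `n_components`.
#' @export
pca_fit <- function(data, n_components) {
  feat_cols <- setdiff(names(data), c("subject", "second", "label"))
  if (n_components > length(feat_cols))
    abort("`n_components` cannot exceed the number of features.")
  m <- as.matrix(data[feat_cols])
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > rank) {
    warn(sprintf("Requested %d components but data rank is %d; truncating.",
                 n_components, rank))
    n_components <- rank
  }
  structure(
    list(mean = pc$center, rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
         sdev = pc$sdev[seq_len(n_components)], feature_names = feat_cols,
         n_components = n_components),
    class = "cap_pca")
}

#' Project a feature table on fitted principal components
#'
#' Centres with the training means and projects on the retained directions.
#'
#' @param model A [pca_fit()] model.
#' @param data Tibble containing at least the model's feature columns;
#'   `subject`, `second` and `label` columns are carried through.
#' @return Tibble with carried-through id columns and `PC1` ... `PCk`.
#' @export
pca_transform <- function(model, data) {
  if (!all(model$feature_names %in% names(data)))
    abort("`data` is missing feature columns the PCA model was fitted on.")
  m <- as.matrix(data[model$feature_names])
  proj <- sweep(m, 2, model$mean) %*% model$rotation
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  keep <- intersect(c("subject", "second", "label"), names(data))
  dplyr::bind_cols(data[keep], tibble::as_tibble(proj))
}
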