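#' Duration post-filter for A-phase predictions
#'
#' An A-phase lasts 2--60 s, so maximal runs of consecutive A-labelled
#' seconds of length 1, or longer than 60, are relabelled as background.
#' Runs are identified on the A-vs-B collapse; a surviving run keeps its
#' per-second subtype labels. The filter is idempotent.
#'
#' @param predicted Factor (or character) of per-second labels, either
#'   `B/A1/A2/A3` or `B/A`.
#' @param min_run,max_run Retained run-length bounds in seconds (defaults
#'   2 and 60).
#' @return Factor with the same levels as the input.
#' @export
duration_filter <- function(predicted, min_run = 2L, max_run = 60L) {
  lv <- if (is.factor(predicted)) levels(predicted) else
    unique(c("B", unique(as.character(predicted))))
  x <- as.character(predicted)
  is_a <- x != "B"
  r <- rle(is_a)
  bad <- r$values & (r$lengths < min_run | r$lengths > max_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(bad)) x[starts[j]:ends[j]] <- "B"
  factor(x, levels = lv)
}

#' Confusion matrix of per-second predictions
#'
#' Counts with rows = predicted class and columns = true class.
#'
#' @param true,predicted Aligned label vectors (factor or character).
#' @param classes Ordered class labels; defaults to the union of levels.
#' @return Integer matrix of class `cap_confusion` (rows predicted,
#'   columns true).
#' @export
confusion_cap <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted))
    abort("`true` and `predicted` must have the same length.")
  classes <- classes %||% union(levels(factor(true)), levels(factor(predicted)))
  t_f <- factor(as.character(true), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  m <- unclass(table(predicted = p_f, true = t_f))
  structure(m, class = c("cap_confusion", "matrix"))
}

#' Performance metrics from a confusion matrix
#'
#' Per-class sensitivity `SE_k = TP_k / (TP_k + FN_k)` and specificity
#' `SP_k = TN_k / (TN_k + FP_k)`, overall accuracy `AC` (trace over total;
#' for two classes this equals the per-class accuracy formula), and the
#' weighted accuracy `WAC = (1/K) sum_j n_jj / n_+j` -- the mean of
#' per-true-class recall, insensitive to class imbalance. A class with no
#' true instances has undefined sensitivity; it is reported as `NA` and
#' excluded from WAC with a warning.
#'
#' @param cm A [confusion_cap()] matrix (rows predicted, columns true).
#' @return List of class `cap_metrics`: `per_class` tibble (`class`, `se`,
#'   `sp`), `ac`, `wac`, `n`.
#' @export
cap_metrics <- function(cm) {
  n <- sum(cm)
  if (n == 0) abort("Confusion matrix is empty.")
  tp <- diag(cm)
  col_tot <- colSums(cm)   # true-class counts n_{+,k}
  row_tot <- rowSums(cm)   # predicted-class counts n_{k,+}
  fn <- col_tot - tp
  fp <- row_tot - tp
  tn <- n - tp - fn - fp
  se <- ifelse(col_tot > 0, tp / (tp + fn), NA_real_)
  sp <- ifelse((tn + fp) > 0, tn / (tn + fp), NA_real_)
  if (any(col_tot == 0))
    warn("Class(es) with no true instances excluded from WAC.")
  wac <- mean(se, na.rm = TRUE)
  structure(
    list(per_class = tibble(class = colnames(cm), se = unname(se), sp = unname(sp)),
         ac = sum(tp) / n, wac = wac, n = n),
    class = "cap_metrics")
}

#' @export
print.cap_metrics <- function(x, ...) {
  cat(sprintf("<cap_metrics> n = %d, AC = %.1f%%, WAC = %.1f%%\n",
              x$n, 100 * x$ac, 100 * x$wac))
  print(x$per_class)
  invisible(x)
}

reduce_fold <- function(train, test, reduction, n_features) {
  if (reduction == "none") return(list(train = train, test = test))
  if (reduction == "mrmr") {
    rk <- mrmr_rank(train)
    keep <- rk$feature[seq_len(min(n_features, nrow(rk)))]
    cols <- c(intersect(c("subject", "second", "label"), names(train)), keep)
    return(list(train = train[cols], test = test[cols]))
  }
  model <- pca_fit(train, n_features)
  list(train = pca_transform(model, train), test = pca_transform(model, test))
}

fit_fold <- function(train, classifier, k, C, gamma, max_train) {
  switch(classifier,
         lda = train_da(train, "linear"),
         qda = train_da(train, "quadratic"),
         knn = train_knn(train, k = k),
         svm = train_svm_ova(train, C = C, gamma = gamma, max_train = max_train),
         abort("Unknown classifier."))
}

#' Leave-one-subject-out evaluation of a scoring pipeline
#'
#' For each subject in turn: feature ranking or projection is fitted on the
#' remaining (training) subjects only, a classifier is trained, the held-out
#' subject is predicted second by second, predictions are duration-filtered,
#' and a confusion matrix is accumulated. Train/test subject disjointness is
#' asserted on every fold. Feature conditioning is per subject and must be
#' applied to `data` beforehand (see [condition_features()]); it shares no
#' statistics across subjects, so it cannot leak.
#'
#' @param data Tibble with `subject`, `second`, `label` and feature
#'   columns, conditioned per subject.
#' @param task `"binary"` (A vs B) or `"multiclass"` (B, A1, A2, A3).
#' @param classifier `"knn"`, `"lda"`, `"qda"` or `"svm"`.
#' @param reduction `"mrmr"`, `"pca"` or `"none"`.
#' @param n_features Features (or components) retained per fold.
#' @param k Neighbours for k-NN.
#' @param C,gamma SVM parameters.
#' @param max_train Cap on SVM training seconds (see [train_svm_ova()]).
#' @param apply_duration_filter Apply [duration_filter()] to predictions.
#' @return Object of class `cap_loso`: list with `folds` (tibble: `subject`,
#'   `wac`, `ac`, `confusion` list-column), `pooled_confusion`,
#'   `pooled_metrics`, `mean_wac`, `mean_ac`, `task`, `classifier`.
#' @export
loso_evaluate <- function(data,
                          task = c("binary", "multiclass"),
                          classifier = c("knn", "lda", "qda", "svm"),
                          reduction = c("mrmr", "pca", "none"),
                          n_features = 30L, k = 25L, C = 0.5, gamma = 0.5,
                          max_train = Inf, apply_duration_filter = TRUE) {
  task <- match.arg(task)
  classifier <- match.arg(classifier)
  reduction <- match.arg(reduction)
  if (is.null(data$subject) || is.null(data$label))
    abort("`data` must contain `subject` and `label` columns.")
  work <- data
  if (task == "binary") work$label <- collapse_binary(work$label)
  classes <- if (task == "binary") c("B", "A") else cap_classes()
  subjects <- unique(work$subject)
  if (length(subjects) < 2) abort("Need at least 2 subjects.")
  folds <- lapply(subjects, function(s) {
    train <- work[work$subject != s, ]
    test <- work[work$subject == s, ]
    stopifnot(length(intersect(unique(train$subject), unique(test$subject))) == 0)
    if (all(test$label == "B"))
      warn(sprintf("Subject %s has no A-phases; fold kept.", s))
    red <- reduce_fold(train, test, reduction, n_features)
    mod <- fit_fold(red$train, classifier, k, C, gamma, max_train)
    pred <- predict(mod, red$test)
    if (apply_duration_filter) pred <- duration_filter(pred)
    cm <- confusion_cap(test$label, pred, classes = classes)
    met <- suppressWarnings(cap_metrics(cm))
    tibble(subject = s, wac = met$wac, ac = met$ac, confusion = list(cm))
  })
  folds <- dplyr::bind_rows(folds)
  pooled <- Reduce(`+`, folds$confusion)
  pooled <- structure(pooled, class = c("cap_confusion", "matrix"))
  structure(
    list(folds = folds, pooled_confusion = pooled,
         pooled_metrics = suppressWarnings(cap_metrics(pooled)),
         mean_wac = mean(folds$wac, na.rm = TRUE),
         mean_ac = mean(folds$ac, na.rm = TRUE),
         task = task, classifier = classifier),
    class = "cap_loso")
}

#' @export
print.cap_loso <- function(x, ...) {
  cat(sprintf("<cap_loso> %s %s: %d folds, mean WAC = %.1f%%, mean AC = %.1f%%\n",
              x$task, x$classifier, nrow(x$folds),
              100 * x$mean_wac, 100 * x$mean_ac))
  invisible(x)
}

#' Column-normalised confusion matrix (percent of each true class)
#'
#' @param cm A [confusion_cap()] matrix.
#' @return Numeric matrix of percentages, columns summing to 100 where the
#'   true class is non-empty.
#' @export
confusion_percent <- function(cm) {
  ct <- colSums(cm)
  sweep(unclass(cm), 2, ifelse(ct > 0, ct, 1), "/") * 100
}
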