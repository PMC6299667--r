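feature_matrix_of <- function(data, feature_names = NULL) {
  feat_cols <- feature_names %||%
    setdiff(names(data), c("subject", "second", "label"))
  if (!all(feat_cols %in% names(data)))
    abort("`data` is missing required feature columns.")
  as.matrix(data[feat_cols])
}

label_vector_of <- function(data) {
  if (is.null(data$label)) abort("`data` must contain a `label` column.")
  droplevels(factor(data$label))
}

new_cap_classifier <- function(kind, fit, classes, feature_names, params = list()) {
  structure(list(kind = kind, fit = fit, classes = classes,
                 feature_names = feature_names, params = params),
            class = "cap_classifier")
}

#' @export
print.cap_classifier <- function(x, ...) {
  p <- paste(names(x$params), unlist(lapply(x$params, format)),
             sep = " = ", collapse = ", ")
  cat(sprintf("<cap_classifier> %s (%s): %d features, classes %s\n",
              x$kind, p, length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Train a discriminant-analysis classifier
#'
#' Closed-form Gaussian discriminants: class means with a pooled covariance
#' (linear) or per-class covariances (quadratic), plus log priors. A small
#' ridge proportional to the mean diagonal is always added to each
#' covariance, so near-singular within-class scatter is handled without
#' failure. Prediction assigns the class whose discriminant is largest.
#'
#' @param data Tibble with a `label` column and feature columns.
#' @param form `"linear"` (LDA) or `"quadratic"` (QDA).
#' @param ridge Relative ridge added to covariance diagonals.
#' @return A `cap_classifier`.
#' @export
train_da <- function(data, form = c("linear", "quadratic"), ridge = 1e-8) {
  form <- match.arg(form)
  y <- label_vector_of(data)
  x <- feature_matrix_of(data)
  classes <- levels(y)
  if (length(classes) < 2) abort("Need at least 2 classes to train.")
  if (any(table(y) < 2)) abort("Every class needs at least 2 samples.")
  d <- ncol(x)
  n <- nrow(x)
  means <- lapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]))
  priors <- as.numeric(table(y)[classes]) / n
  covs <- lapply(classes, function(k) {
    xk <- x[y == k, , drop = FALSE]
    stats::cov(xk)
  })
  regularize <- function(S) {
    lam <- ridge * (mean(diag(S)) + 1)
    S + diag(lam, d)
  }
  if (form == "linear") {
    nk <- as.numeric(table(y)[classes])
    pooled <- Reduce(`+`, Map(function(S, m) S * (m - 1), covs, nk)) / (n - length(classes))
    pooled <- regularize(pooled)
    inv <- solve(pooled)
    fit <- list(means = means, priors = priors, inv = inv)
  } else {
    covs <- lapply(covs, regularize)
    invs <- lapply(covs, solve)
    logdets <- vapply(covs, function(S) determinant(S, logarithm = TRUE)$modulus[1],
                      numeric(1))
    fit <- list(means = means, priors = priors, invs = invs, logdets = logdets)
  }
  new_cap_classifier(if (form == "linear") "LDA" else "QDA", fit, classes,
                     colnames(x), list(form = form))
}

#' Train a k-nearest-neighbours classifier
#'
#' Stores the training set; prediction uses the Euclidean metric and a
#' majority vote over the `k` nearest training points. Vote ties are broken
#' toward the class of the single nearest neighbour among the tied classes,
#' making prediction fully deterministic.
#'
#' @param data Tibble with a `label` column and feature columns.
#' @param k Number of neighbours (the evaluation grid of interest is
#'   `c(3, 5, 7, 9, 15, 25)`).
#' @return A `cap_classifier`.
#' @export
train_knn <- function(data, k = 25L) {
  y <- label_vector_of(data)
  x <- feature_matrix_of(data)
  if (k > nrow(x)) abort("`k` cannot exceed the training-set size.")
  new_cap_classifier("KNN", list(x = x, y = y), levels(y), colnames(x),
                     list(k = as.integer(k)))
}

stratified_subsample <- function(y, max_train) {
  n <- length(y)
  if (!is.finite(max_train) || n <= max_train) return(seq_len(n))
  tabs <- table(y)
  take <- unlist(lapply(names(tabs), function(k) {
    idx <- which(y == k)
    m <- max(1L, round(length(idx) / n * max_train))
    idx[unique(round(seq(1, length(idx), length.out = m)))]
  }))
  sort(take)
}

#' Train a one-against-all Gaussian-kernel SVM
#'
#' One soft-margin radial-basis SVM per class, each trained with that
#' class as +1 and all others as -1 (kernel
#' `exp(-gamma * ||xi - xj||^2)`); a new point is assigned to the class
#' whose machine returns the largest decision value. Binary machines are
#' fitted with [e1071::svm()] at fixed solver tolerance, so training is
#' deterministic.
#'
#' @param data Tibble with a `label` column and feature columns.
#' @param C Soft-margin cost.
#' @param gamma Kernel width parameter.
#' @param max_train Optional cap on training seconds: a deterministic
#'   stratified (evenly spaced per class) subsample is used when the
#'   training set is larger. Default `Inf` (use everything).
#' @return A `cap_classifier`.
#' @export
train_svm_ova <- function(data, C = 0.5, gamma = 0.5, max_train = Inf) {
  y <- label_vector_of(data)
  x <- feature_matrix_of(data)
  classes <- levels(y)
  if (length(classes) < 2) abort("Need at least 2 classes to train.")
  keep <- stratified_subsample(y, max_train)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  machines <- lapply(classes, function(k) {
    yy <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, yy, scale = FALSE, kernel = "radial", gamma = gamma,
               cost = C, tolerance = 0.001)
  })
  names(machines) <- classes
  new_cap_classifier("SVM_OVA", list(machines = machines), classes,
                     colnames(x), list(C = C, gamma = gamma))
}

#' Predict per-second classes
#'
#' @param object A `cap_classifier`.
#' @param newdata Tibble containing the classifier's feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels (levels = training classes).
#' @export
predict.cap_classifier <- function(object, newdata, ...) {
  x <- feature_matrix_of(newdata, object$feature_names)
  classes <- object$classes
  scores <- switch(
    object$kind,
    LDA = {
      inv <- object$fit$inv
      vapply(seq_along(classes), function(i) {
        m <- object$fit$means[[i]]
        drop(x %*% (inv %*% m)) - 0.5 * drop(t(m) %*% inv %*% m) +
          log(object$fit$priors[i])
      }, numeric(nrow(x)))
    },
    QDA = {
      vapply(seq_along(classes), function(i) {
        m <- object$fit$means[[i]]
        xc <- sweep(x, 2, m)
        q <- rowSums((xc %*% object$fit$invs[[i]]) * xc)
        -0.5 * object$fit$logdets[i] - 0.5 * q + log(object$fit$priors[i])
      }, numeric(nrow(x)))
    },
    KNN = {
      return(knn_predict(object, x))
    },
    SVM_OVA = {
      vapply(classes, function(k) {
        dv <- attr(predict(object$fit$machines[[k]], x, decision.values = TRUE),
                   "decision.values")
        # libsvm orders the binary labels by first occurrence in the data;
        # orient so that positive always means the "pos" (one) class
        sgn <- if (startsWith(colnames(dv)[1], "pos/")) 1 else -1
        sgn * drop(dv[, 1])
      }, numeric(nrow(x)))
    },
    abort("Unknown classifier kind.")
  )
  scores <- matrix(scores, nrow = nrow(x))
  factor(classes[max.col(scores, ties.method = "first")], levels = classes)
}

knn_predict <- function(object, x) {
  tr <- object$fit$x
  y <- object$fit$y
  k <- object$params$k
  classes <- levels(y)
  tr_sq <- rowSums(tr^2)
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    d2 <- tr_sq - 2 * drop(tr %*% x[i, ]) + sum(x[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      # tie: the tied class whose member appears first in distance order wins
      out[i] <- as.character(y[nn][match(TRUE, as.character(y[nn]) %in% top)])
    }
  }
  factor(out, levels = classes)
}

#' Grid search for the one-against-all SVM
#'
#' Evaluates every `(C, gamma)` pair by mean weighted accuracy over
#' leave-one-subject-out folds. With `protocol = "outer"` (default) the
#' pair maximising the outer-fold mean WAC is returned, the behaviour this
#' operation's contract defines; `protocol = "nested"` instead selects, for
#' each outer fold, the best pair by an inner leave-one-subject-out search
#' restricted to the training subjects, reporting the modal selected pair
#' and the honest outer WAC. Grid ties break toward smaller `C`, then
#' smaller `gamma`.
#'
#' @param data Tibble with `subject`, `label` and feature columns (already
#'   reduced/selected).
#' @param C_grid,gamma_grid Numeric grids; defaults are the full
#'   `2^seq(-5, 15, 2)` by `2^seq(-15, 5, 2)` grid (121 pairs).
#' @param protocol `"outer"` or `"nested"`.
#' @param reduction `"none"` (default: `data` is used as given) or
#'   `"mrmr"`: the top `n_features` features are re-ranked on the training
#'   subjects of every fold, so no ranking information leaks from the
#'   held-out subject.
#' @param n_features Features kept per fold when `reduction = "mrmr"`.
#' @param max_train Per-fit cap on training seconds (see
#'   [train_svm_ova()]).
#' @param apply_duration_filter Post-filter predictions by A-phase run
#'   duration before scoring (default `TRUE`).
#' @return Object of class `cap_grid_search`: list with `grid` (tibble of
#'   `C`, `gamma`, `wac`), `best_C`, `best_gamma`, `protocol`.
#' @export
grid_search_svm <- function(data, C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 5, 2),
                            protocol = c("outer", "nested"),
                            reduction = c("none", "mrmr"),
                            n_features = 40L,
                            max_train = Inf,
                            apply_duration_filter = TRUE) {
  protocol <- match.arg(protocol)
  reduction <- match.arg(reduction)
  if (length(C_grid) == 0 || length(gamma_grid) == 0)
    abort("`C_grid` and `gamma_grid` must be non-empty.")
  subjects <- unique(data$subject)
  if (length(subjects) < 2) abort("Grid search needs at least 2 subjects.")
  fold_wac <- function(train, test, C, gamma) {
    mod <- train_svm_ova(train, C = C, gamma = gamma, max_train = max_train)
    pred <- predict(mod, test)
    if (apply_duration_filter) pred <- duration_filter(pred)
    cm <- confusion_cap(test$label, pred, classes = levels(droplevels(train$label)))
    suppressWarnings(cap_metrics(cm)$wac)
  }
  if (protocol == "outer") {
    # per-fold train/test splits, reduced once and reused across the grid
    folds <- lapply(subjects, function(s) {
      tr <- data[data$subject != s, ]
      te <- data[data$subject == s, ]
      if (reduction == "mrmr") {
        keep <- mrmr_rank(tr)$feature[seq_len(n_features)]
        cols <- c(intersect(c("subject", "second", "label"), names(data)), keep)
        tr <- tr[cols]; te <- te[cols]
      }
      list(train = tr, test = te)
    })
    grid <- tidyr::expand_grid(C = C_grid, gamma = gamma_grid)
    grid$wac <- purrr::pmap_dbl(grid, function(C, gamma) {
      mean(vapply(folds, function(fl) {
        fold_wac(fl$train, fl$test, C, gamma)
      }, numeric(1)))
    })
    ord <- order(-grid$wac, grid$C, grid$gamma)
    best <- grid[ord[1], ]
    structure(list(grid = grid, best_C = best$C, best_gamma = best$gamma,
                   protocol = protocol),
              class = "cap_grid_search")
  } else {
    picks <- lapply(subjects, function(s) {
      inner <- grid_search_svm(data[data$subject != s, ], C_grid, gamma_grid,
                               protocol = "outer", reduction = reduction,
                               n_features = n_features, max_train = max_train,
                               apply_duration_filter = apply_duration_filter)
      wac <- fold_wac(data[data$subject != s, ], data[data$subject == s, ],
                      inner$best_C, inner$best_gamma)
      tibble(subject = s, C = inner$best_C, gamma = inner$best_gamma, wac = wac)
    })
    folds <- dplyr::bind_rows(picks)
    tab <- dplyr::count(folds, .data$C, .data$gamma, sort = TRUE)
    structure(list(grid = folds, best_C = tab$C[1], best_gamma = tab$gamma[1],
                   protocol = protocol),
              class = "cap_grid_search")
  }
}

#' @export
print.cap_grid_search <- function(x, ...) {
  cat(sprintf("<cap_grid_search> protocol %s: best C = %g, gamma = %g\n",
              x$protocol, x$best_C, x$best_gamma))
  invisible(x)
}
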