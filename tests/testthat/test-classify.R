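make_blobs <- function(n = 60, sep = 6, seed = 21) {
  withr::local_seed(seed)
  tibble::tibble(
    label = factor(rep(c("B", "A"), each = n), levels = c("B", "A")),
    x = c(rnorm(n), rnorm(n, sep)),
    y = c(rnorm(n), rnorm(n, sep)))
}

test_that("linear discriminant analysis separates Gaussian blobs", {
  d <- make_blobs()
  mod <- train_da(d, "linear")
  expect_equal(as.character(predict(mod, d)), as.character(d$label))
})

test_that("identical class distributions collapse to the majority class", {
  withr::local_seed(22)
  d <- tibble::tibble(
    label = factor(rep(c("B", "A"), c(150, 50)), levels = c("B", "A")),
    x = rnorm(200), y = rnorm(200))
  mod <- train_da(d, "linear")
  pred <- predict(mod, d)
  expect_gt(mean(pred == "B"), 0.95)   # only the priors differ
})

test_that("quadratic discriminants beat linear ones on ring-vs-centre data", {
  withr::local_seed(23)
  n <- 150
  theta <- runif(n, 0, 2 * pi)
  d <- tibble::tibble(
    label = factor(rep(c("B", "A"), each = n), levels = c("B", "A")),
    x = c(rnorm(n, sd = 0.4), 3 * cos(theta) + rnorm(n, sd = 0.2)),
    y = c(rnorm(n, sd = 0.4), 3 * sin(theta) + rnorm(n, sd = 0.2)))
  acc <- function(m) mean(predict(m, d) == d$label)
  expect_gt(acc(train_da(d, "quadratic")), acc(train_da(d, "linear")))
})

test_that("discriminant analysis agrees with the MASS reference on clean data", {
  d <- make_blobs(sep = 4)
  ours <- predict(train_da(d, "linear"), d)
  mass <- predict(MASS::lda(label ~ x + y, data = d), d)$class
  expect_equal(as.character(ours), as.character(mass))
  ours_q <- predict(train_da(d, "quadratic"), d)
  mass_q <- predict(MASS::qda(label ~ x + y, data = d), d)$class
  expect_equal(as.character(ours_q), as.character(mass_q))
})

test_that("degenerate within-class scatter is handled by the ridge", {
  d <- make_blobs()
  d$z <- 1   # zero-variance feature in every class
  expect_silent(mod <- train_da(d, "quadratic"))
  expect_equal(as.character(predict(mod, d)), as.character(d$label))
  expect_error(train_da(d[c(1, 61), ], "linear"), "2 samples")
})

test_that("k-NN predicts its own training labels at k = 1 and votes at k = 3", {
  d <- make_blobs(n = 20)
  mod1 <- train_knn(d, k = 1)
  expect_equal(as.character(predict(mod1, d)), as.character(d$label))
  # query equidistant from 2 A and 1 B neighbours goes to A
  tr <- tibble::tibble(label = factor(c("A", "A", "B"), levels = c("B", "A")),
                       x = c(1, -1, 0), y = c(0, 0, 1))
  mod3 <- train_knn(tr, k = 3)
  expect_equal(as.character(predict(mod3, tibble::tibble(x = 0, y = 0))), "A")
  expect_error(train_knn(tr, k = 10), "training-set size")
})

test_that("k-NN vote ties break toward the nearest tied class, deterministically", {
  tr <- tibble::tibble(label = factor(c("A", "B", "A", "B"), levels = c("B", "A")),
                       x = c(1, 1.5, 3, 4), y = 0)
  mod <- train_knn(tr, k = 4)
  # 2 votes each; nearest neighbour (x = 1, class A) decides
  expect_equal(as.character(predict(mod, tibble::tibble(x = 0.9, y = 0))), "A")
  p1 <- predict(mod, tibble::tibble(x = 2, y = 0))
  expect_identical(p1, predict(mod, tibble::tibble(x = 2, y = 0)))
})

test_that("k-NN agrees with class::knn away from vote ties", {
  d <- make_blobs(n = 50, sep = 3, seed = 29)
  q <- make_blobs(n = 25, sep = 3, seed = 31)
  mod <- train_knn(d, k = 5)
  ours <- predict(mod, q)
  ref <- class::knn(as.matrix(d[c("x", "y")]), as.matrix(q[c("x", "y")]),
                    d$label, k = 5)
  expect_gt(mean(as.character(ours) == as.character(ref)), 0.98)
})

test_that("one-against-all SVM trains one machine per class and separates", {
  d3 <- tibble::tibble(
    label = factor(rep(c("B", "A1", "A2"), each = 40),
                   levels = c("B", "A1", "A2")),
    x = c(rnorm(40), rnorm(40, 6), rnorm(40, -6)),
    y = c(rnorm(40), rnorm(40, 6), rnorm(40, 0)))
  mod <- train_svm_ova(d3, C = 100, gamma = 0.5)
  expect_length(mod$fit$machines, 3)
  expect_named(mod$fit$machines, c("B", "A1", "A2"))
  expect_gt(mean(predict(mod, d3) == d3$label), 0.97)
  # hard-margin limit on separable binary data: zero training errors
  d2 <- make_blobs(sep = 8)
  mod2 <- train_svm_ova(d2, C = 1e3, gamma = 1)
  expect_equal(as.character(predict(mod2, d2)), as.character(d2$label))
  expect_error(train_svm_ova(d2[d2$label == "B", ]), "2 classes")
})

test_that("SVM predictions are invariant to a consistent feature permutation", {
  d <- make_blobs(sep = 4, seed = 37)
  mod <- train_svm_ova(d, C = 1, gamma = 0.5)
  q <- make_blobs(n = 15, sep = 4, seed = 41)
  expect_identical(predict(mod, q), predict(mod, q[c("y", "x", "label")]))
})

test_that("the default SVM grid spans 121 pairs and ties break low", {
  expect_equal(nrow(tidyr::expand_grid(C = 2^seq(-5, 15, 2),
                                       gamma = 2^seq(-15, 5, 2))), 121)
  withr::local_seed(43)
  # two subjects with identical structure: flat WAC surface forces the tie rule
  d <- dplyr::bind_rows(lapply(c("S1", "S2"), function(s) {
    tibble::tibble(subject = s,
                   label = factor(rep(c("B", "A"), each = 30), levels = c("B", "A")),
                   x = c(rnorm(30), rnorm(30, 10)))
  }))
  gs <- grid_search_svm(d, C_grid = c(1, 4), gamma_grid = c(0.25, 1),
                        apply_duration_filter = FALSE)
  expect_equal(nrow(gs$grid), 4)
  expect_equal(max(gs$grid$wac), gs$grid$wac[gs$grid$C == gs$best_C &
                                               gs$grid$gamma == gs$best_gamma])
  top <- gs$grid[gs$grid$wac == max(gs$grid$wac), ]
  expect_equal(gs$best_C, min(top$C))
  expect_equal(gs$best_gamma, min(top$gamma[top$C == gs$best_C]))
})

test_that("grid search recovers a planted bandwidth scale", {
  withr::local_seed(47)
  # separation only resolvable at a narrow kernel: two interleaved stripes
  mk <- function(s) {
    x <- runif(160, 0, 4)
    tibble::tibble(subject = s,
                   label = factor(ifelse(floor(x * 2) %% 2 == 0, "B", "A"),
                                  levels = c("B", "A")),
                   x = x, y = runif(160))
  }
  d <- dplyr::bind_rows(mk("S1"), mk("S2"), mk("S3"))
  gs <- grid_search_svm(d, C_grid = c(1, 100), gamma_grid = c(0.01, 50),
                        apply_duration_filter = FALSE)
  expect_equal(gs$best_gamma, 50)   # only the narrow kernel resolves stripes
})

test_that("deterministic stratified subsampling caps the training set", {
  y <- factor(rep(c("B", "A"), c(900, 100)))
  idx <- capscore:::stratified_subsample(y, 200)
  expect_lte(length(idx), 210)
  expect_gte(sum(y[idx] == "A"), 15)   # minority class keeps its share
  expect_identical(idx, capscore:::stratified_subsample(y, 200))
  expect_identical(capscore:::stratified_subsample(y, Inf), seq_along(y))
})
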