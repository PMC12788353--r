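# two well separated Gaussian blobs in 2-D, labels 1/2
two_blobs <- function(n_per = 30, sep = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  list(X = X, y = rep(1:2, each = n_per))
}

test_that("stratified sampling applies the per-class count rule", {
  # a 20-pixel class under min 10 splits 10/10
  y <- rep(1:2, c(20, 200))
  sp <- stratified_sample(y, 0.10, min_per_class = 10, seed = 1)
  expect_equal(sum(y[sp$train_idx] == 1), 10L)
  expect_equal(sum(y[sp$test_idx] == 1), 10L)
  expect_equal(sum(y[sp$train_idx] == 2), 20L)      # ceil(0.1 * 200)

  # fraction 0.5, min 1, class of 4 -> 2 train
  sp2 <- stratified_sample(rep(1:2, c(4, 10)), 0.5, min_per_class = 1, seed = 1)
  expect_equal(sum(rep(1:2, c(4, 10))[sp2$train_idx] == 1), 2L)

  # 16-class fixture checked against a direct loop oracle
  set.seed(9)
  sizes <- c(46, 1428, 830, 237, 483, 730, 28, 478, 20, 972, 2455, 593, 205,
             1265, 386, 93)
  y16 <- rep(seq_along(sizes), sizes)
  sp16 <- stratified_sample(y16, 0.10, min_per_class = 10, seed = 4)
  for (cl in seq_along(sizes)) {
    n_c <- sizes[cl]
    want <- if (n_c <= 20) n_c %/% 2
            else min(max(ceiling(0.10 * n_c), 10), n_c %/% 2)
    expect_equal(sum(y16[sp16$train_idx] == cl), want, label = paste("class", cl))
  }

  # split partitions the pixels and is deterministic under the seed
  expect_length(intersect(sp16$train_idx, sp16$test_idx), 0)
  expect_setequal(c(sp16$train_idx, sp16$test_idx), seq_along(y16))
  expect_identical(sp16$train_idx,
                   stratified_sample(y16, 0.10, 10, seed = 4)$train_idx)
  expect_false(identical(sp16$train_idx,
                         stratified_sample(y16, 0.10, 10, seed = 5)$train_idx))
  expect_error(stratified_sample(c(1, 2, 2), 0.5), "at least 2")
})

test_that("grid search returns the best config with deterministic tie-breaks", {
  d <- two_blobs()
  # grid of one point -> that point
  one <- tune_hyperparameters(d$X, d$y, C_grid = 35, gamma_grid = 8, seed = 1)
  expect_equal(one$C, 35); expect_equal(one$gamma, 8)

  # clearly separable data: every grid point is perfect, so the tie-break
  # (smaller C then smaller gamma) decides
  cfg <- tune_hyperparameters(d$X, d$y, C_grid = c(32, 1, 8),
                              gamma_grid = c(0.2, 0.05), seed = 1)
  tab <- attr(cfg, "cv_table")
  expect_true(all(tab$accuracy == 1))
  expect_equal(cfg$C, 1)
  expect_equal(cfg$gamma, 0.05)

  # the chosen point attains the exhaustively evaluated grid maximum
  set.seed(5)
  Xh <- rbind(matrix(rnorm(40, sd = 1.5), 20, 2),
              matrix(rnorm(40, mean = 2, sd = 1.5), 20, 2))
  yh <- rep(1:2, each = 20)
  cfg2 <- tune_hyperparameters(Xh, yh, C_grid = c(0.1, 1, 10),
                               gamma_grid = c(0.1, 1), seed = 3)
  tab2 <- attr(cfg2, "cv_table")
  chosen <- tab2$accuracy[tab2$C == cfg2$C & tab2$gamma == cfg2$gamma]
  expect_equal(chosen, max(tab2$accuracy))

  # fold reduction warns when the smallest class is tiny
  expect_warning(
    tune_hyperparameters(d$X[c(1:3, 31:60), ], d$y[c(1:3, 31:60)],
                         C_grid = 1, gamma_grid = 1, folds = 5, seed = 1),
    "folds reduced")
  expect_error(tune_hyperparameters(d$X[1:30, ], d$y[1:30], C_grid = 1,
                                    gamma_grid = 1), "single-class")
})

test_that("seed probabilities are normalized, accurate and deterministic", {
  d <- two_blobs(n_per = 40)
  sp <- stratified_sample(d$y, 0.25, min_per_class = 5, seed = 2)
  cfg <- svm_config(C = 32, gamma = 1)
  pm <- fit_predict_proba(d$X, sp, cfg, d$y)
  expect_s3_class(pm, "ProbabilityMap")
  expect_equal(rowSums(pm$probs), rep(1, nrow(d$X)), tolerance = 1e-9)
  expect_true(all(pm$probs >= 0))

  # margin >> noise: held-out accuracy is 100%
  pred <- pm$class_ids[max.col(pm$probs, "first")]
  expect_equal(mean(pred[sp$test_idx] == d$y[sp$test_idx]), 1)

  # a training pixel duplicated in the test set keeps its label
  dup <- d$X[sp$train_idx[1], , drop = FALSE]
  pdup <- predict_seed(pm, dup)
  expect_equal(pdup$class[1], d$y[sp$train_idx[1]])

  # same seed -> identical split, config and probabilities
  pm2 <- fit_predict_proba(d$X, stratified_sample(d$y, 0.25, 5, seed = 2),
                           cfg, d$y)
  expect_identical(pm$probs, pm2$probs)
})

test_that("three-class probabilities cover all training classes", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40, mean = 6), 20, 2),
             cbind(rnorm(20, mean = -6), rnorm(20, mean = 6)))
  y <- rep(1:3, each = 20)
  sp <- stratified_sample(y, 0.3, min_per_class = 4, seed = 1)
  pm <- fit_predict_proba(X, sp, svm_config(16, 0.1), y)
  expect_equal(pm$class_ids, 1:3)
  expect_equal(dim(pm$probs), c(60L, 3L))
  expect_equal(mean(pm$class_ids[max.col(pm$probs, "first")][sp$test_idx] ==
                      y[sp$test_idx]), 1)
})
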