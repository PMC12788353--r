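### Seed classifier: per-pixel class probabilities from a kernel classifier
### trained on a small stratified sample. The decision function is
### argmax_k w_k' Phi(z) + b_k with an RBF feature map; probabilities come
### from ridge-penalized multinomial logistic regression on the RBF kernel
### columns (glmnet backend), with cost C mapped to lambda = 1/(C * n). The
### refinement stage only requires normalized probability rows, so any
### drop-in producer of softmax probabilities is accepted downstream.

#' Classifier configuration
#'
#' @param C positive cost (inverse regularization) weight.
#' @param gamma positive RBF width parameter,
#'   `k(x, y) = exp(-gamma * ||x - y||^2)`.
#' @param folds cross-validation fold count used during tuning.
#' @return an object of class `SvmConfig`.
#' @export
svm_config <- function(C, gamma, folds = 5L) {
  if (C <= 0 || gamma <= 0 || folds < 2L)
    stop("need C > 0, gamma > 0, folds >= 2")
  structure(list(C = C, gamma = gamma, folds = as.integer(folds)),
            class = "SvmConfig")
}

#' Per-pixel class probability map
#'
#' Rows are nonnegative and sum to 1 (within 1e-9); `class_ids` names the
#' columns; `coords` aligns rows with a `PixelTable`.
#'
#' @param probs `P' x K` matrix.
#' @param class_ids length-`K` integer label vector.
#' @param coords optional `P' x 2` matrix of `(row, col)` coordinates.
#' @return an object of class `ProbabilityMap`.
#' @export
probability_map <- function(probs, class_ids, coords = NULL) {
  probs <- as.matrix(probs)
  if (length(class_ids) != ncol(probs))
    stop("class_ids must match the probability columns")
  if (any(probs < -1e-12) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("probability rows must be nonnegative and sum to 1")
  structure(list(probs = probs, class_ids = as.integer(class_ids),
                 coords = coords),
            class = "ProbabilityMap")
}

#' @export
print.ProbabilityMap <- function(x, ...) {
  cat(sprintf("ProbabilityMap: %d pixels x %d classes\n",
              nrow(x$probs), ncol(x$probs)))
  invisible(x)
}

#' Stratified train/test split of labeled pixels
#'
#' Per class `c` with `n_c` members the train count is
#' `min(max(ceil(fraction * n_c), min_per_class), floor(n_c / 2))`, except
#' that classes with `n_c <= 2 * min_per_class` contribute
#' `floor(n_c / 2)` — so a 20-pixel class under a 10-pixel minimum splits
#' 10/10. Every class with at least two labeled pixels appears in the
#' training set; the split is deterministic given `seed`.
#'
#' @param labels integer class vector (all > 0).
#' @param fraction target train fraction in `(0, 1)`.
#' @param min_per_class minimum training pixels per class (default 10).
#' @param seed RNG seed.
#' @return an object of class `TrainSplit` with `train_idx`, `test_idx`,
#'   `fraction`, `min_per_class`, `seed`.
#' @export
stratified_sample <- function(labels, fraction, min_per_class = 10L,
                              seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every class needs at least 2 labeled pixels")
  train_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(labels)), function(cl) {
      ids <- which(labels == cl)
      n_c <- length(ids)
      n_train <- if (n_c <= 2L * min_per_class) n_c %/% 2L
                 else min(max(ceiling(fraction * n_c), min_per_class),
                          n_c %/% 2L)
      sample(ids, n_train)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  structure(list(train_idx = train_idx,
                 test_idx = setdiff(seq_along(labels), train_idx),
                 fraction = fraction, min_per_class = as.integer(min_per_class),
                 seed = seed),
            class = "TrainSplit")
}

# Gaussian RBF kernel matrix between row sets, k = exp(-gamma * ||a - b||^2).
rbf_kernel <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

klr_fit <- function(X, y, config) {
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes to fit")
  n <- nrow(X)
  lam <- 1 / (config$C * n)
  Ktr <- rbf_kernel(X, X, config$gamma)
  fit <- suppressWarnings(glmnet::glmnet(
    Ktr, factor(y, levels = classes), family = "multinomial",
    alpha = 0, lambda = lam * c(100, 10, 1), standardize = FALSE,
    maxit = 1e6))
  list(fit = fit, X = X, classes = classes, lambda = lam, config = config)
}

klr_predict <- function(model, Xnew, type = c("prob", "class")) {
  type <- match.arg(type)
  Knew <- rbf_kernel(as.matrix(Xnew), model$X, model$config$gamma)
  pr <- predict(model$fit, Knew, s = model$lambda, type = "response")
  pr <- pr[, , 1L, drop = TRUE]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
  pr <- pr / rowSums(pr)
  if (type == "prob") return(pr)
  model$classes[max.col(pr, ties.method = "first")]
}

#' Grid-search classifier hyperparameters by cross-validated accuracy
#'
#' Exhaustive search over the `(C, gamma)` grid using stratified k-fold
#' cross validation on overall accuracy. Ties prefer the smaller `C`, then
#' the smaller `gamma`. If the smallest class has fewer members than
#' `folds`, the fold count is reduced (with a warning) so every fold sees
#' every class.
#'
#' @param features training feature matrix (reduced spectra).
#' @param labels training class vector.
#' @param C_grid,gamma_grid candidate values. The defaults are a coarse
#'   bound bracketing the per-scene optima reported for the airborne
#'   benchmarks (C 34/35/43, gamma 7/8/11).
#' @param folds fold count, default 5.
#' @param seed RNG seed for the fold assignment.
#' @return the winning [svm_config()], with the full grid of mean CV
#'   accuracies attached as attribute `"cv_table"`.
#' @export
tune_hyperparameters <- function(features, labels,
                                 C_grid = c(1, 2, 4, 8, 16, 32, 34, 35, 43, 64, 100),
                                 gamma_grid = c(0.1, 0.5, 1, 2, 4, 7, 8, 11, 16),
                                 folds = 5L, seed = NULL) {
  if (!length(C_grid) || !length(gamma_grid)) stop("empty grid")
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("single-class input")
  min_class <- min(table(labels))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning(sprintf("smallest class has %d members; folds reduced to %d",
                    min_class, folds))
  }
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ids <- sample(which(labels == cl))
      fold_of[ids] <- rep_len(seq_len(folds), length(ids))
    }
  })
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- svm_config(grid$C[g], grid$gamma[g], folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      model <- klr_fit(features[tr, , drop = FALSE], labels[tr], cfg)
      pred <- klr_predict(model, features[!tr, , drop = FALSE], "class")
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / length(labels)
  }, numeric(1))
  # ties -> smaller C, then smaller gamma
  top <- which(acc >= max(acc) - 1e-15)
  best <- top[order(grid$C[top], grid$gamma[top])][1L]
  out <- svm_config(grid$C[best], grid$gamma[best], folds)
  attr(out, "cv_table") <- cbind(grid, accuracy = acc)
  out
}

#' Fit the seed classifier and predict probabilities for all labeled pixels
#'
#' Trains on `split$train_idx` and returns per-pixel class probabilities
#' (train and test alike) over the `K` training classes; the row-wise
#' argmax defines the initial classification map handed to refinement.
#'
#' @param features `P' x d` reduced feature matrix for all labeled pixels.
#' @param split a [stratified_sample()] result.
#' @param config an [svm_config()].
#' @param labels training label vector aligned with `features` rows.
#' @param coords optional `P' x 2` coordinates carried into the map.
#' @return a [probability_map()], with the fitted model attached as
#'   attribute `"model"`.
#' @export
fit_predict_proba <- function(features, split, config, labels, coords = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(inherits(split, "TrainSplit"), inherits(config, "SvmConfig"))
  if (max(c(split$train_idx, split$test_idx)) > nrow(features))
    stop("split indices exceed the feature table")
  model <- klr_fit(features[split$train_idx, , drop = FALSE],
                   labels[split$train_idx], config)
  probs <- klr_predict(model, features, "prob")
  out <- probability_map(probs, model$classes, coords)
  attr(out, "model") <- model
  out
}

#' Predict with the model attached to a seed probability map
#'
#' @param pm a [fit_predict_proba()] result (carries the fitted model).
#' @param newdata feature matrix of new pixels.
#' @return list with `probs` (rows sum to 1) and `class` (argmax labels).
#' @export
predict_seed <- function(pm, newdata) {
  model <- attr(pm, "model")
  if (is.null(model)) stop("probability map carries no fitted model")
  probs <- klr_predict(model, newdata, "prob")
  list(probs = probs, class = model$classes[max.col(probs, "first")])
}
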