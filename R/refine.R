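### Iterative spectral-spatial label refinement. A seed probability map from
### the pixel-wise classifier is refined by iterated conditional modes on a
### neighborhood energy that combines a Gaussian spatial nearness kernel S,
### a Gaussian spectral similarity kernel W, the current class probabilities
### of the neighbors, and a label-agreement indicator. Outer iterations
### alternate an ICM sweep with a softmax probability update until the total
### L1 probability change falls below epsilon.

#' Refinement parameters
#'
#' The defaults are the fixed cross-scene transfer set (`r = 4`,
#' `sigma_s = sigma_w = 1.3`, `beta = 0.4`): carrying these unchanged to a
#' new scene and re-tuning only the classifier cost is the intended
#' transfer protocol.
#'
#' @param r neighborhood radius in pixels (window `(2r+1) x (2r+1)`).
#' @param sigma_s spatial kernel width (pixel offsets).
#' @param sigma_w spectral kernel width (on min-max normalized reduced
#'   features).
#' @param beta trade-off in `[0, 1]` between the spectral-similarity term
#'   and the spatial-nearness/agreement term.
#' @param epsilon convergence threshold on the summed L1 probability change
#'   between outer iterations (absolute).
#' @param max_outer outer-iteration cap.
#' @param potential_form `"eq11_grouped"` (default) keeps the
#'   indicator inside the spatially-weighted group:
#'   `E_i(k) = -sum_j [(1-beta) W_ij P_j(k) + beta (S_ij P_j(k) + I(k, w_j))]`;
#'   `"eq9"` uses
#'   `E_i(k) = -sum_j [(1-beta)(W_ij + S_ij) P_j(k) + beta I(k, w_j)]`.
#' @return an object of class `RefineParams`.
#' @export
refine_params <- function(r = 4L, sigma_s = 1.3, sigma_w = 1.3, beta = 0.4,
                          epsilon = 1e-4, max_outer = 20L,
                          potential_form = c("eq11_grouped", "eq9")) {
  potential_form <- match.arg(potential_form)
  if (r < 1L || sigma_s <= 0 || sigma_w <= 0 || beta < 0 || beta > 1 ||
      epsilon <= 0 || max_outer < 1L)
    stop("invalid refinement parameters")
  structure(list(r = as.integer(r), sigma_s = sigma_s, sigma_w = sigma_w,
                 beta = beta, epsilon = epsilon,
                 max_outer = as.integer(max_outer),
                 potential_form = potential_form),
            class = "RefineParams")
}

#' Spatial nearness kernel over pixel offsets
#'
#' Weight at offset `(u, v)` is `exp(-(u^2 + v^2) / (2 sigma_s^2))`. The
#' center offset keeps its value 1 (`exp(0)`) but is marked excluded: the
#' neighborhood sums run over `j != i`.
#'
#' @param r neighborhood radius.
#' @param sigma_s kernel width.
#' @return `(2r+1) x (2r+1)` matrix with attribute `center_excluded = TRUE`.
#' @export
spatial_kernel <- function(r, sigma_s) {
  if (r < 1L || sigma_s <= 0) stop("need r >= 1 and sigma_s > 0")
  off <- seq.int(-r, r)
  S <- exp(-outer(off^2, off^2, "+") / (2 * sigma_s^2))
  dimnames(S) <- list(off, off)
  attr(S, "center_excluded") <- TRUE
  S
}

#' Spectral similarity weights for every pixel's neighborhood
#'
#' For each pixel `i` and offset neighbor `j`,
#' `W_ij = exp(-||f_i - f_j||^2 / (2 sigma_w^2))`, computed on the
#' mirror-padded feature raster so border pixels carry full neighborhoods.
#' Zero feature distance gives weight 1.
#'
#' @param features_padded `(M+2r) x (N+2r) x d` mirror-padded feature
#'   raster (min-max normalized reduced components).
#' @param r neighborhood radius used for the padding.
#' @param sigma_w kernel width.
#' @return `M x N x (2r+1)^2` array; the offset axis is the column-major
#'   flattening of the `(2r+1) x (2r+1)` offset grid.
#' @export
spectral_kernel <- function(features_padded, r, sigma_w) {
  if (sigma_w <= 0) stop("sigma_w must be > 0")
  if (!all(is.finite(features_padded))) stop("non-finite features")
  dm <- dim(features_padded)
  M <- dm[1L] - 2L * r; N <- dm[2L] - 2L * r
  if (M < 1L || N < 1L) stop("padded raster smaller than 2r")
  spectral_weights_cpp(features_padded, M, N, as.integer(r), sigma_w)
}

# Build the kernel stack used by the energy routines.
#' Precompute the spatial and spectral kernel stack
#' @param features `M x N x d` reduced feature raster (unpadded).
#' @param params a [refine_params()].
#' @return list with `S` (offset grid), `W` (per-pixel weights), `r`.
#' @export
kernel_stack <- function(features, params) {
  stopifnot(inherits(params, "RefineParams"))
  if (length(dim(features)) != 3L) stop("features must be M x N x d")
  padded <- pad_array(features, params$r)
  list(S = spatial_kernel(params$r, params$sigma_s),
       W = spectral_kernel(padded, params$r, params$sigma_w),
       r = params$r)
}

#' Class energies for every pixel
#'
#' Evaluates the neighborhood energy of assigning each class to each pixel
#' under the current labels and probabilities. Neighbor indices beyond the
#' scene reflect symmetrically (mirror boundary); neighbors labeled 0
#' (background) contribute nothing. Lower energy means stronger support.
#'
#' @param labels `M x N` integer matrix of current class indices in
#'   `1..K` (0 = background).
#' @param probs `M x N x K` probability array.
#' @param kernels a [kernel_stack()].
#' @param params a [refine_params()].
#' @return `M x N x K` energy array (background rows are 0 and unused).
#' @export
class_energies <- function(labels, probs, kernels, params) {
  form <- if (params$potential_form == "eq11_grouped") 0L else 1L
  energies_cpp(labels, probs, kernels$W, as.vector(kernels$S),
               kernels$r, params$beta, form)
}

#' One ICM sweep
#'
#' Visits pixels once in raster order and assigns each to the class of
#' minimum energy, using the already-updated labels of earlier-visited
#' pixels (Gauss-Seidel). Ties break toward the smallest class id. Pixels
#' marked in `clamp` (known training labels) are never reassigned.
#'
#' @inheritParams class_energies
#' @param clamp optional `M x N` logical matrix of pixels to hold fixed.
#' @return the updated `M x N` label matrix.
#' @export
icm_sweep <- function(labels, probs, kernels, params, clamp = NULL) {
  form <- if (params$potential_form == "eq11_grouped") 0L else 1L
  if (is.null(clamp))
    clamp <- matrix(FALSE, nrow(labels), ncol(labels))
  icm_sweep_cpp(labels, probs, kernels$W, as.vector(kernels$S),
                kernels$r, params$beta, form, clamp)
}

#' Softmax probability update from class energies
#'
#' `P_i(k) = exp(-E_i(k) + m_i) / sum_k' exp(-E_i(k') + m_i)` with
#' `m_i = min_k E_i(k)`, so the exponentials are shift-stabilized and
#' cannot overflow. Pixels with all energies equal get a uniform row.
#' Background pixels keep their previous row.
#'
#' @param energies `M x N x K` array from [class_energies()].
#' @param probs previous `M x N x K` probability array (supplies the
#'   background rows).
#' @param background optional `M x N` logical matrix of background pixels.
#' @return updated `M x N x K` probability array.
#' @export
update_probabilities <- function(energies, probs, background = NULL) {
  dm <- dim(energies)
  E <- matrix(energies, ncol = dm[3L])
  m <- do.call(pmin, lapply(seq_len(dm[3L]), function(k) E[, k]))
  ex <- exp(-(E - m))
  P <- ex / rowSums(ex)
  if (!is.null(background) && any(background)) {
    bg <- as.vector(background)
    P[bg, ] <- matrix(probs, ncol = dm[3L])[bg, ]
  }
  array(P, dim = dm)
}

#' Refine a seed probability map by iterated conditional modes
#'
#' Alternates [icm_sweep()] and [update_probabilities()] until the summed
#' L1 change of the probability map between outer iterations is at most
#' `params$epsilon`, or `params$max_outer` is reached. Non-convergence is a
#' reported state (`converged = FALSE`), not an error.
#'
#' @param seed `M x N x K` seed probability array (for labeled scenes built
#'   with [prob_raster()]), or a [probability_map()] together with `dims`.
#' @param features `M x N x d` reduced, min-max normalized feature raster.
#' @param params a [refine_params()].
#' @param train optional `M x N` integer matrix holding known training
#'   labels (0 elsewhere); when given these pixels are clamped to their
#'   label throughout, unless `clamp = FALSE`.
#' @param background optional `M x N` logical matrix of background pixels
#'   (never updated, contribute nothing to neighbors). Defaults to pixels
#'   whose seed rows are all zero, if any.
#' @param clamp honor `train` labels as hard constraints (default TRUE).
#' @param dims scene dimensions, required when `seed` is a
#'   [probability_map()].
#' @param class_ids class labels for the K probability columns.
#' @return an object of class `RefineState`: `labels` (`M x N`, original
#'   class ids, 0 background), `probs`, `class_ids`, `iteration`,
#'   `delta_history`, `converged`.
#' @export
refine <- function(seed, features, params = refine_params(), train = NULL,
                   background = NULL, clamp = TRUE, dims = NULL,
                   class_ids = NULL) {
  stopifnot(inherits(params, "RefineParams"))
  if (inherits(seed, "ProbabilityMap")) {
    if (is.null(dims)) stop("dims required with a ProbabilityMap seed")
    class_ids <- seed$class_ids
    seed <- prob_raster(seed, dims)
  }
  dm <- dim(seed)
  K <- dm[3L]
  if (is.null(class_ids)) class_ids <- seq_len(K)
  if (is.null(background))
    background <- apply(seed, c(1, 2), sum) < 0.5
  storage.mode(background) <- "logical"
  kernels <- kernel_stack(features, params)
  # initial map: per-pixel argmax of the seed
  P <- seed
  Pm <- matrix(P, ncol = K)
  labels <- matrix(max.col(Pm, ties.method = "first"), dm[1L], dm[2L])
  labels[background] <- 0L
  clamp_mask <- matrix(FALSE, dm[1L], dm[2L])
  if (!is.null(train) && clamp) {
    has <- train > 0L & !background
    idx <- match(train[has], class_ids)
    if (anyNA(idx)) stop("train labels outside the seed class set")
    labels[has] <- idx
    clamp_mask[has] <- TRUE
  }
  storage.mode(labels) <- "integer"
  delta_history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  nb <- !as.vector(background)
  for (n in seq_len(params$max_outer)) {
    iter <- n
    labels <- icm_sweep(labels, P, kernels, params, clamp_mask)
    E <- class_energies(labels, P, kernels, params)
    Pnew <- update_probabilities(E, P, background)
    delta <- sum(abs(matrix(Pnew, ncol = K)[nb, ] - matrix(P, ncol = K)[nb, ]))
    delta_history <- c(delta_history, delta)
    P <- Pnew
    if (delta <= params$epsilon) { converged <- TRUE; break }
  }
  out_labels <- matrix(0L, dm[1L], dm[2L])
  out_labels[!background] <- class_ids[labels[!background]]
  structure(list(labels = out_labels, probs = P, class_ids = class_ids,
                 iteration = iter, delta_history = delta_history,
                 converged = converged, params = params),
            class = "RefineState")
}

#' @export
print.RefineState <- function(x, ...) {
  cat(sprintf("RefineState: %d outer iteration(s), %s (last delta %.3g)\n",
              x$iteration,
              if (x$converged) "converged" else "iteration cap reached",
              if (length(x$delta_history)) tail(x$delta_history, 1) else NA))
  invisible(x)
}

#' Weak-label feedback
#'
#' Feeds the final probability map of a refinement back in as the seed and
#' re-runs [refine()], `n_runs` times. A fixed point of [refine()] is a
#' fixed point of the feedback loop.
#'
#' @param result a [refine()] result.
#' @param features the feature raster used for the original run.
#' @param params a [refine_params()].
#' @param n_runs number of feedback runs, at least 1.
#' @param ... further arguments passed to [refine()] (`train`,
#'   `background`, ...).
#' @return the final `RefineState`, whose `delta_history` concatenates all
#'   runs.
#' @export
weak_label_feedback <- function(result, features, params = refine_params(),
                                n_runs = 1L, ...) {
  stopifnot(inherits(result, "RefineState"))
  if (n_runs < 1L) stop("n_runs must be >= 1")
  history <- result$delta_history
  for (run in seq_len(n_runs)) {
    result <- refine(result$probs, features, params,
                     class_ids = result$class_ids, ...)
    history <- c(history, result$delta_history)
  }
  result$delta_history <- history
  result
}

#' Expand a pixel-table probability map onto the scene raster
#'
#' Labeled pixels take their classifier rows; all other pixels get
#' all-zero rows (treated as background by [refine()]).
#'
#' @param pm a [probability_map()] with `coords`.
#' @param dims `c(M, N)` scene dimensions.
#' @return `M x N x K` array.
#' @export
prob_raster <- function(pm, dims) {
  stopifnot(inherits(pm, "ProbabilityMap"))
  if (is.null(pm$coords)) stop("probability map carries no coordinates")
  K <- ncol(pm$probs)
  out <- array(0, dim = c(dims[1L], dims[2L], K))
  lin <- pm$coords[, 1L] + (pm$coords[, 2L] - 1L) * dims[1L]
  for (k in seq_len(K)) {
    slab <- out[, , k]
    slab[lin] <- pm$probs[, k]
    out[, , k] <- slab
  }
  out
}
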