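#' Fit a principal-component spectral projection
#'
#' Eigendecomposes the covariance of the pixel features and retains the
#' smallest number of leading components whose cumulative explained-variance
#' ratio reaches `evr_threshold`, optionally capped at `d_cap`. Fitting on
#' all non-background pixels of a scene (rather than only the training
#' pixels) is the intended transductive use; pass a training-only table to
#' opt out.
#'
#' @param table a `PixelTable` from [mask_background()], or a plain numeric
#'   matrix of pixel spectra (rows = pixels).
#' @param evr_threshold cumulative explained-variance ratio to reach, in
#'   `(0, 1]`. Default 0.92.
#' @param d_cap optional hard cap on the retained dimension, applied after
#'   threshold selection. Default 18 (classifier accuracy plateaus well
#'   before the variance curve does on the airborne benchmarks).
#' @return an object of class `SpectralProjection` with fields `mean`,
#'   `components` (`D x d`), `eigenvalues` (length `D`, nonincreasing), `d`
#'   and `evr_threshold`.
#' @export
fit_projection <- function(table, evr_threshold = 0.92, d_cap = 18L) {
  X <- if (inherits(table, "PixelTable")) table$features else as.matrix(table)
  if (nrow(X) < 2L) stop("need at least 2 pixels to fit a projection")
  if (!all(is.finite(X))) stop("non-finite features")
  if (evr_threshold <= 0 || evr_threshold > 1)
    stop("evr_threshold must be in (0, 1]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  evr <- cumsum(ev) / sum(ev)
  d <- which(evr >= evr_threshold - 1e-12)[1L]
  if (is.na(d)) d <- length(ev)
  if (!is.null(d_cap)) d <- min(d, as.integer(d_cap))
  structure(list(mean = mu, components = e$vectors[, seq_len(d), drop = FALSE],
                 eigenvalues = ev, d = d, evr_threshold = evr_threshold),
            class = "SpectralProjection")
}

#' @export
print.SpectralProjection <- function(x, ...) {
  evr <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  cat(sprintf("SpectralProjection: %d -> %d components (evr %.4f at d, threshold %.2f)\n",
              length(x$mean), x$d, evr[x$d], x$evr_threshold))
  invisible(x)
}

#' Project pixel spectra onto the retained principal subspace
#'
#' @param projection a [fit_projection()] result.
#' @param table a `PixelTable` or numeric matrix whose columns match the
#'   projection's input dimension.
#' @return `P' x d` matrix of component scores,
#'   `(features - mean) %*% components`.
#' @export
project <- function(projection, table) {
  stopifnot(inherits(projection, "SpectralProjection"))
  X <- if (inherits(table, "PixelTable")) table$features else as.matrix(table)
  if (ncol(X) != length(projection$mean))
    stop("feature dimension does not match the projection")
  sweep(X, 2L, projection$mean) %*% projection$components
}

# Project a whole cube to an M x N x d score raster, then min-max normalize
# each component so one spectral kernel width fits all components.
project_raster <- function(projection, cube, normalize = TRUE) {
  dm <- dim(cube$values)
  flat <- matrix(cube$values, nrow = dm[1L] * dm[2L], ncol = dm[3L])
  Z <- project(projection, flat)
  if (normalize) {
    for (j in seq_len(ncol(Z))) {
      lo <- min(Z[, j]); hi <- max(Z[, j])
      Z[, j] <- if (hi > lo) (Z[, j] - lo) / (hi - lo) else 0
    }
  }
  array(Z, dim = c(dm[1L], dm[2L], ncol(Z)))
}
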