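### Synthetic labeled hyperspectral scenes. Each class gets a smooth
### reflectance signature (a low-order random cosine mixture, emulating the
### spectral continuity of vegetation/soil reflectance); classes occupy
### contiguous regions; pixels carry additive Gaussian noise; region
### boundaries can be linearly mixed; a fraction of pixels can be marked
### background; extra "open-set" classes can be generated that a training
### protocol should exclude.

#' Scene specification
#'
#' @param M,N spatial dimensions.
#' @param D band count.
#' @param K class count (at least 2), excluding open-set classes.
#' @param layout `"rectangles"` (contiguous horizontal strips) or
#'   `"voronoi"` (nearest-site regions of K random sites).
#' @param signature_smoothness spectral autocorrelation scale as a fraction
#'   of the spectrum; harmonics up to `ceiling(1 / smoothness)` enter the
#'   signatures. Default 0.25.
#' @param class_separation minimum pairwise signature distance in units of
#'   `noise_sd` (per-band noise SD). Default 10: nearest-signature
#'   classification of interior pixels is then essentially error-free.
#' @param noise_sd additive per-band Gaussian noise SD in reflectance
#'   units. Default 0.02.
#' @param mixed_boundary_width width in pixels of the linearly mixed zone
#'   along class boundaries (0 = sharp boundaries).
#' @param background_fraction fraction of pixels relabeled 0 (background),
#'   in `[0, 1)`.
#' @param open_set_classes number of extra classes absent from training.
#' @param seed RNG seed; the scene is bit-identical for a fixed seed.
#' @return object of class `SceneSpec`.
#' @export
scene_spec <- function(M = 40L, N = 40L, D = 30L, K = 3L,
                       layout = c("rectangles", "voronoi"),
                       signature_smoothness = 0.25, class_separation = 10,
                       noise_sd = 0.02, mixed_boundary_width = 0L,
                       background_fraction = 0, open_set_classes = 0L,
                       seed = 1L) {
  layout <- match.arg(layout)
  if (K < 2L) stop("need at least 2 classes")
  if (class_separation <= 0) stop("class_separation must be > 0")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  structure(list(M = as.integer(M), N = as.integer(N), D = as.integer(D),
                 K = as.integer(K), layout = layout,
                 signature_smoothness = signature_smoothness,
                 class_separation = class_separation, noise_sd = noise_sd,
                 mixed_boundary_width = as.integer(mixed_boundary_width),
                 background_fraction = background_fraction,
                 open_set_classes = as.integer(open_set_classes),
                 seed = seed),
            class = "SceneSpec")
}

# Smooth random signatures: cosine mixtures with 1/h amplitude decay,
# rescaled so the minimum pairwise distance meets the separation contract.
draw_signatures <- function(n_classes, D, smoothness, min_dist) {
  H <- max(1L, ceiling(1 / smoothness))
  b <- (seq_len(D) - 1) / D
  sig <- t(vapply(seq_len(n_classes), function(k) {
    amp <- rnorm(H) / seq_len(H)
    phase <- runif(H, 0, 2 * pi)
    base <- rowSums(vapply(seq_len(H), function(h)
      amp[h] * cos(2 * pi * h * b + phase[h]), numeric(D)))
    0.5 + 0.2 * base
  }, numeric(D)))
  if (n_classes > 1L) {
    dmin <- min(stats::dist(sig))
    if (dmin <= 0) {                        # degenerate draw: nudge apart
      sig <- sig + matrix(rnorm(length(sig), sd = 1e-3), nrow = n_classes)
      dmin <- min(stats::dist(sig))
    }
    if (dmin < min_dist) {
      center <- colMeans(sig)
      sig <- sweep(sweep(sig, 2L, center), 1:2, min_dist / dmin, "*")
      sig <- sweep(sig, 2L, center, "+")
    }
  }
  sig
}

region_layout <- function(spec, n_classes) {
  lab <- matrix(0L, spec$M, spec$N)
  if (spec$layout == "rectangles") {
    # contiguous horizontal strips of near-equal height
    bounds <- round(seq(0, spec$M, length.out = n_classes + 1L))
    for (k in seq_len(n_classes))
      lab[(bounds[k] + 1L):bounds[k + 1L], ] <- k
  } else {
    sites <- cbind(runif(n_classes, 1, spec$M), runif(n_classes, 1, spec$N))
    rows <- matrix(seq_len(spec$M), spec$M, spec$N)
    cols <- matrix(seq_len(spec$N), spec$M, spec$N, byrow = TRUE)
    d2 <- vapply(seq_len(n_classes), function(k)
      as.vector((rows - sites[k, 1])^2 + (cols - sites[k, 2])^2),
      numeric(spec$M * spec$N))
    lab <- matrix(max.col(-d2, ties.method = "first"), spec$M, spec$N)
  }
  lab
}

#' Generate a synthetic labeled scene
#'
#' @param spec a [scene_spec()].
#' @return list with `cube` ([hyper_cube()]), `labels` ([label_map()]),
#'   `signatures` (class x band matrix), `open_set_ids` (label values of
#'   open-set classes, possibly empty) and `spec`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  n_classes <- spec$K + spec$open_set_classes
  if (spec$M * spec$N < 4L * n_classes)
    stop("scene too small for the requested class count")
  with_seed(spec$seed, {
    min_dist <- spec$class_separation * max(spec$noise_sd, 0.01)
    sig <- draw_signatures(n_classes, spec$D, spec$signature_smoothness,
                           min_dist)
    lab <- region_layout(spec, n_classes)
    values <- array(0, dim = c(spec$M, spec$N, spec$D))
    flat <- sig[as.vector(lab), , drop = FALSE]      # pixel x band
    # linear boundary mixing: pixels within the mixing zone blend their
    # class signature with the nearest other class present in the window
    w <- spec$mixed_boundary_width
    if (w > 0L) {
      for (i in seq_len(spec$M)) for (j in seq_len(spec$N)) {
        i0 <- max(1L, i - w); i1 <- min(spec$M, i + w)
        j0 <- max(1L, j - w); j1 <- min(spec$N, j + w)
        win <- lab[i0:i1, j0:j1]
        other <- win[win != lab[i, j]]
        if (length(other)) {
          # mixing weight shrinks with Chebyshev distance to the boundary
          dists <- sapply(seq_len(w), function(dd) {
            ii0 <- max(1L, i - dd); ii1 <- min(spec$M, i + dd)
            jj0 <- max(1L, j - dd); jj1 <- min(spec$N, j + dd)
            any(lab[ii0:ii1, jj0:jj1] != lab[i, j])
          })
          dist <- which(dists)[1L]
          alpha <- 0.5 * (1 - (dist - 1) / w)
          mix_cls <- as.integer(names(sort(table(other), decreasing = TRUE))[1L])
          px <- i + (j - 1L) * spec$M
          flat[px, ] <- (1 - alpha) * flat[px, ] + alpha * sig[mix_cls, ]
        }
      }
    }
    if (spec$noise_sd > 0)
      flat <- flat + matrix(rnorm(length(flat), sd = spec$noise_sd),
                            nrow = nrow(flat))
    values <- array(flat, dim = c(spec$M, spec$N, spec$D))
    if (spec$background_fraction > 0) {
      n_bg <- round(spec$background_fraction * spec$M * spec$N)
      bg <- sample.int(spec$M * spec$N, n_bg)
      lab[bg] <- 0L
    }
    open_ids <- if (spec$open_set_classes > 0L)
      seq.int(spec$K + 1L, n_classes) else integer(0)
    list(cube = hyper_cube(values), labels = label_map(lab),
         signatures = sig, open_set_ids = open_ids, spec = spec)
  })
}

#' Corrupt a seed probability map
#'
#' Reassigns the probability mass of an exact `round(flip_rate * P')`
#' subset of pixels (sampled without replacement) to a one-hot vector on a
#' uniformly chosen wrong class; all other rows are untouched.
#'
#' @param pm a [probability_map()].
#' @param flip_rate fraction of pixels to corrupt, in `[0, 1)`.
#' @param seed RNG seed.
#' @return the corrupted [probability_map()], with the flipped row indices
#'   attached as attribute `"flipped"`.
#' @export
corrupt_seed <- function(pm, flip_rate, seed = NULL) {
  stopifnot(inherits(pm, "ProbabilityMap"))
  if (flip_rate < 0 || flip_rate >= 1) stop("flip_rate must be in [0, 1)")
  n <- nrow(pm$probs)
  n_flip <- round(flip_rate * n)
  if (n_flip == 0L) {
    attr(pm, "flipped") <- integer(0)
    return(pm)
  }
  K <- ncol(pm$probs)
  with_seed(seed, {
    rows <- sample.int(n, n_flip)
    cur <- max.col(pm$probs[rows, , drop = FALSE], ties.method = "first")
    wrong <- vapply(cur, function(k) sample(setdiff(seq_len(K), k), 1L),
                    integer(1))
    probs <- pm$probs
    probs[rows, ] <- 0
    probs[cbind(rows, wrong)] <- 1
    out <- probability_map(probs, pm$class_ids, pm$coords)
    attr(out, "flipped") <- sort(rows)
    out
  })
}

#' Generate a train/inference scene pair with disjoint class signatures
#'
#' The inference scene's signatures are re-drawn (and, if needed, pushed
#' away from the training signatures) until every cross-scene signature
#' pair is at least the inference scene's separation distance apart,
#' exercising fixed-parameter open-set transfer.
#'
#' @param spec_train,spec_infer [scene_spec()]s; `spec_infer` must request
#'   at least one open-set class.
#' @return list with `train` and `infer` scenes (as from [make_scene()]).
#' @export
make_transfer_pair <- function(spec_train, spec_infer) {
  stopifnot(inherits(spec_train, "SceneSpec"), inherits(spec_infer, "SceneSpec"))
  if (spec_infer$open_set_classes < 1L)
    stop("spec_infer must request at least one open-set class")
  train <- make_scene(spec_train)
  min_dist <- spec_infer$class_separation * max(spec_infer$noise_sd, 0.01)
  infer <- NULL
  for (try in 1:50) {
    sp <- spec_infer
    sp$seed <- child_seed(spec_infer$seed, paste0("transfer", try))
    cand <- make_scene(sp)
    cross <- min(apply(cand$signatures, 1L, function(s)
      min(sqrt(colSums((t(train$signatures) - s)^2)))))
    if (cross >= min_dist) { infer <- cand; break }
  }
  if (is.null(infer)) {
    # deterministic fallback: shift the last candidate orthogonally
    cand$signatures <- cand$signatures + min_dist
    cand$cube$values <- cand$cube$values + min_dist
    infer <- cand
  }
  list(train = train, infer = infer)
}
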