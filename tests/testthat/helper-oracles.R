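# Independent brute-force oracles. These recompute every quantity from the
# definitions by explicit loops (reflecting boundary indices by hand) and
# never call the vectorized/C++ paths they are used to check.

# symmetric reflection with edge duplication, 1-based
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# class energies by triple loop straight from the potential definitions
oracle_energies <- function(labels, probs, features, r, sigma_s, sigma_w,
                            beta, form = c("eq11_grouped", "eq9")) {
  form <- match.arg(form)
  M <- nrow(labels); N <- ncol(labels); K <- dim(probs)[3]
  E <- array(0, c(M, N, K))
  for (i in seq_len(M)) for (j in seq_len(N)) {
    if (labels[i, j] == 0L) next
    for (k in seq_len(K)) {
      acc <- 0
      for (du in -r:r) for (dv in -r:r) {
        if (du == 0 && dv == 0) next
        ni <- oracle_reflect(i + du, M)
        nj <- oracle_reflect(j + dv, N)
        lj <- labels[ni, nj]
        if (lj == 0L) next
        w <- exp(-sum((features[i, j, ] - features[ni, nj, ])^2) /
                   (2 * sigma_w^2))
        s <- exp(-(du^2 + dv^2) / (2 * sigma_s^2))
        p <- probs[ni, nj, k]
        ind <- if (lj == k) 1 else -1
        acc <- acc + if (form == "eq11_grouped")
          (1 - beta) * w * p + beta * (s * p + ind)
        else
          (1 - beta) * (w + s) * p + beta * ind
      }
      E[i, j, k] <- -acc
    }
  }
  E
}

# sequential ICM sweep in raster order, recomputing each energy by loops
oracle_sweep <- function(labels, probs, features, r, sigma_s, sigma_w, beta,
                         form = "eq11_grouped") {
  M <- nrow(labels); N <- ncol(labels); K <- dim(probs)[3]
  lab <- labels
  for (i in seq_len(M)) for (j in seq_len(N)) {
    if (lab[i, j] == 0L) next
    e <- numeric(K)
    for (k in seq_len(K)) {
      acc <- 0
      for (du in -r:r) for (dv in -r:r) {
        if (du == 0 && dv == 0) next
        ni <- oracle_reflect(i + du, M)
        nj <- oracle_reflect(j + dv, N)
        lj <- lab[ni, nj]
        if (lj == 0L) next
        w <- exp(-sum((features[i, j, ] - features[ni, nj, ])^2) /
                   (2 * sigma_w^2))
        s <- exp(-(du^2 + dv^2) / (2 * sigma_s^2))
        p <- probs[ni, nj, k]
        ind <- if (lj == k) 1 else -1
        acc <- acc + if (form == "eq11_grouped")
          (1 - beta) * w * p + beta * (s * p + ind)
        else
          (1 - beta) * (w + s) * p + beta * ind
      }
      e[k] <- -acc
    }
    lab[i, j] <- which.min(e)          # which.min takes the smallest index
  }
  lab
}

# random refinement instance on a small raster (no background by default)
random_instance <- function(M = 7, N = 7, K = 3, d = 2, seed = 1,
                            bg_frac = 0) {
  set.seed(seed)
  labels <- matrix(sample.int(K, M * N, replace = TRUE), M, N)
  if (bg_frac > 0)
    labels[sample.int(M * N, round(bg_frac * M * N))] <- 0L
  probs <- array(runif(M * N * K), c(M, N, K))
  tot <- apply(probs, c(1, 2), sum)
  for (k in seq_len(K)) probs[, , k] <- probs[, , k] / tot
  features <- array(runif(M * N * d), c(M, N, d))
  list(labels = labels, probs = probs, features = features)
}

# one-hot probability array from a label matrix
onehot_raster <- function(labels, K) {
  P <- array(0, c(nrow(labels), ncol(labels), K))
  for (k in seq_len(K)) P[, , k][labels == k] <- 1
  P
}

# a clean scene plus a corrupted one-hot seed built from its ground truth
corrupted_scene <- function(seed, M = 40, N = 40, K = 3, D = 30,
                            flip_rate = 0.1) {
  sc <- make_scene(scene_spec(M = M, N = N, D = D, K = K, seed = seed))
  cube <- minmax_normalize(sc$cube)
  tab <- mask_background(cube, sc$labels)
  proj <- fit_projection(tab)
  Zr <- hsirefine:::project_raster(proj, cube)
  pm <- probability_map(diag(K)[tab$labels, ], seq_len(K), tab$coords)
  cor <- corrupt_seed(pm, flip_rate, seed = seed + 1000L)
  list(scene = sc, table = tab, features = Zr, seed_pm = cor,
       seed_oa = 100 * mean(max.col(cor$probs, "first") == tab$labels))
}

refined_oa <- function(inst, state) {
  100 * mean(state$labels[inst$table$coords] == inst$table$labels)
}
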