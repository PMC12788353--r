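test_that("spatial kernel matches its closed form and is symmetric", {
  S <- spatial_kernel(4, 1.3)
  expect_equal(dim(S), c(9L, 9L))
  expect_equal(S["0", "0"], 1)                       # exp(0), pre-exclusion
  expect_true(isTRUE(attr(S, "center_excluded")))
  expect_equal(S["1", "0"], exp(-1 / (2 * 1.3^2)), tolerance = 1e-12)
  expect_equal(S["1", "0"], 0.7438931, tolerance = 1e-6)
  # even function: weight(u, v) == weight(-u, -v)
  expect_equal(S, S[9:1, 9:1], ignore_attr = TRUE)
  expect_error(spatial_kernel(0, 1), "r >= 1")
})

test_that("spectral kernel equals the per-pair loop oracle", {
  inst <- random_instance(M = 6, N = 6, d = 2, seed = 21)
  r <- 2; sw <- 1.3
  W <- spectral_kernel(hsirefine:::pad_array(inst$features, r), r, sw)
  width <- 2 * r + 1
  for (i in 1:6) for (j in 1:6) {
    for (du in -r:r) for (dv in -r:r) {
      ni <- oracle_reflect(i + du, 6); nj <- oracle_reflect(j + dv, 6)
      want <- exp(-sum((inst$features[i, j, ] - inst$features[ni, nj, ])^2) /
                    (2 * sw^2))
      off <- (dv + r) * width + (du + r) + 1
      expect_equal(W[i, j, off], want, tolerance = 1e-12)
    }
  }
  # zero feature distance -> weight exactly 1 at the center offset
  expect_equal(as.vector(W[, , (width^2 + 1) / 2]), rep(1, 36))
  # ||f_i - f_j||^2 = 3.38 at sigma_w = 1.3 -> exp(-1)
  f <- array(0, c(1, 2, 1)); f[1, 2, 1] <- sqrt(3.38)
  W2 <- spectral_kernel(hsirefine:::pad_array(f, 1), 1, 1.3)
  expect_equal(W2[1, 1, 8], exp(-1), tolerance = 1e-12)  # offset (0, +1)
})

test_that("class energies reproduce the hand-worked homogeneous patch", {
  labels <- matrix(1L, 3, 3)
  P <- onehot_raster(labels, 2)
  kern <- list(S = structure(matrix(1, 3, 3), center_excluded = TRUE),
               W = array(1, c(3, 3, 9)), r = 1L)
  params <- refine_params(r = 1, beta = 0.4)
  E <- class_energies(labels, P, kern, params)
  expect_equal(E[2, 2, 1], -8 * (0.6 + 0.4 * 2))     # -11.2
  expect_equal(E[2, 2, 2], 8 * 0.4)                  # +3.2

  # beta = 0 reduces the grouped form to pure spectral support
  p0 <- refine_params(r = 1, beta = 0)
  E0 <- class_energies(labels, P, kern, p0)
  expect_equal(E0[2, 2, 1], -8)                      # -sum W_ij P_j(1)
  expect_equal(E0[2, 2, 2], 0)
})

test_that("vectorized energies match the triple-loop oracle on random instances", {
  for (s in 1:4) {
    inst <- random_instance(M = 7, N = 7, K = 3, d = 2, seed = s,
                            bg_frac = if (s > 2) 0.15 else 0)
    for (form in c("eq11_grouped", "eq9")) {
      params <- refine_params(r = 2, sigma_s = 1.1, sigma_w = 0.9,
                              beta = 0.4, potential_form = form)
      kern <- kernel_stack(inst$features, params)
      E <- class_energies(inst$labels, inst$probs, kern, params)
      Eo <- oracle_energies(inst$labels, inst$probs, inst$features,
                            r = 2, sigma_s = 1.1, sigma_w = 0.9,
                            beta = 0.4, form = form)
      expect_lt(max(abs(E - Eo)), 1e-10)
    }
  }
})

test_that("ICM sweep visits raster order with Gauss-Seidel updates", {
  # a constant-label one-hot scene is a fixed point of the sweep
  labels <- matrix(2L, 5, 5)
  P <- onehot_raster(labels, 3)
  params <- refine_params(r = 1, sigma_s = 1, sigma_w = 1, beta = 0.4)
  feat <- array(0.3, c(5, 5, 2))
  kern <- kernel_stack(feat, params)
  expect_identical(icm_sweep(labels, P, kern, params), labels)

  # a single flipped interior pixel is restored
  flip <- labels; flip[3, 3] <- 1L
  Pf <- onehot_raster(flip, 3)
  expect_identical(icm_sweep(flip, Pf, kern, params), labels)

  # one sweep equals the loop-oracle sweep on random instances
  for (s in 1:3) {
    inst <- random_instance(M = 5, N = 5, K = 3, d = 2, seed = 100 + s)
    params2 <- refine_params(r = 1, sigma_s = 1.2, sigma_w = 0.8, beta = 0.35)
    kern2 <- kernel_stack(inst$features, params2)
    got <- icm_sweep(inst$labels, inst$probs, kern2, params2)
    want <- oracle_sweep(inst$labels, inst$probs, inst$features,
                         r = 1, sigma_s = 1.2, sigma_w = 0.8, beta = 0.35)
    expect_identical(got, want)
  }

  # clamped pixels are never reassigned
  clamp <- matrix(FALSE, 5, 5); clamp[3, 3] <- TRUE
  expect_identical(icm_sweep(flip, Pf, kern, params, clamp)[3, 3], 1L)
})

test_that("probability update is a stabilized softmax", {
  E <- array(0, c(1, 1, 4))
  expect_equal(as.vector(update_probabilities(E, E)), rep(0.25, 4))

  # K = 2 with the worked energies
  E2 <- array(c(-11.2, 3.2), c(1, 1, 2))
  P2 <- update_probabilities(E2, E2)
  expect_equal(P2[1, 1, 1], 1 / (1 + exp(-14.4)), tolerance = 1e-12)

  # shift invariance
  E3 <- array(rnorm(6), c(1, 2, 3))
  expect_equal(update_probabilities(E3 + 5, E3), update_probabilities(E3, E3),
               tolerance = 1e-12)
  # enormous energies cannot overflow
  E4 <- array(c(-1e6, 1e6), c(1, 1, 2))
  expect_equal(as.vector(update_probabilities(E4, E4)), c(1, 0))
})

test_that("refine converges, respects epsilon and reports state", {
  sc <- corrupted_scene(seed = 300, M = 20, N = 20)
  K <- 3
  # enormous epsilon: exactly one outer iteration
  p1 <- refine_params(epsilon = 2 * 400 * K, max_outer = 20)
  st1 <- refine(sc$seed_pm, sc$features, p1, dims = c(20, 20))
  expect_equal(st1$iteration, 1L)
  expect_true(st1$converged)

  # homogeneous one-hot scene: converged at iteration 1 with numerically
  # zero delta, probabilities unchanged
  seed <- array(0, c(12, 12, 3)); seed[, , 2] <- 1
  feat <- array(0.5, c(12, 12, 2))
  st2 <- refine(seed, feat, refine_params())
  expect_true(st2$converged)
  expect_equal(st2$iteration, 1L)
  expect_lt(st2$delta_history[1], 1e-12)
  expect_true(all(st2$labels == 2L))
  expect_lt(max(abs(st2$probs - seed)), 1e-12)

  # termination and delta bookkeeping
  st3 <- refine(sc$seed_pm, sc$features, refine_params(max_outer = 3,
                                                       epsilon = 1e-12),
                dims = c(20, 20))
  expect_lte(st3$iteration, 3L)
  expect_length(st3$delta_history, st3$iteration)
  if (st3$converged)
    expect_lte(tail(st3$delta_history, 1), 1e-12)
})

test_that("refinement denoises a corrupted seed and feedback holds the gain", {
  wins <- 0L
  for (s in 1:5) {
    inst <- corrupted_scene(seed = 400 + s)
    st <- refine(inst$seed_pm, inst$features, refine_params(),
                 dims = c(40, 40))
    oa <- refined_oa(inst, st)
    if (oa >= inst$seed_oa) wins <- wins + 1L
    # one feedback run must not undo the denoising on these scenes
    fb <- weak_label_feedback(st, inst$features, refine_params(), n_runs = 1)
    expect_gte(refined_oa(inst, fb), oa - 1e-9)
  }
  expect_gte(wins, 4L)
  expect_error(weak_label_feedback(
    refine(array(1, c(3, 3, 1)), array(0, c(3, 3, 1)), refine_params(r = 1)),
    array(0, c(3, 3, 1)), n_runs = 0), "n_runs")
})

test_that("known training labels are clamped through refinement", {
  inst <- corrupted_scene(seed = 77, M = 15, N = 15)
  train <- matrix(0L, 15, 15)
  flipped <- attr(inst$seed_pm, "flipped")
  # clamp a handful of pixels to deliberately wrong labels: they must stay
  coords <- inst$table$coords[1:5, , drop = FALSE]
  wrong <- (inst$table$labels[1:5] %% 3L) + 1L
  train[coords] <- wrong
  st <- refine(inst$seed_pm, inst$features, refine_params(), train = train,
               dims = c(15, 15))
  expect_equal(st$labels[coords], wrong)
  st2 <- refine(inst$seed_pm, inst$features, refine_params(), train = train,
                clamp = FALSE, dims = c(15, 15))
  expect_false(all(st2$labels[coords] == wrong))
})

test_that("spatial term helps when the seed is spatially noisy (beta probe)", {
  wins <- 0L; n_runs <- 8L
  for (s in seq_len(n_runs)) {
    inst <- corrupted_scene(seed = 500 + s, M = 30, N = 30, flip_rate = 0.15)
    oa_b <- refined_oa(inst, refine(inst$seed_pm, inst$features,
                                    refine_params(beta = 0.4),
                                    dims = c(30, 30)))
    oa_0 <- refined_oa(inst, refine(inst$seed_pm, inst$features,
                                    refine_params(beta = 0),
                                    dims = c(30, 30)))
    if (oa_b >= oa_0) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.75 * n_runs))
})
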