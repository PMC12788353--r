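test_that("band exclusion removes the union of ranges and singletons", {
  cube224 <- hyper_cube(array(runif(2 * 2 * 224), c(2, 2, 224)))
  out <- exclude_bands(cube224, band_exclusion_preset("salinas"), quiet = TRUE)
  expect_equal(attr(out, "n_removed"), 20L)
  expect_equal(length(out$band_ids), 204L)
  expect_false(any(c(108:112, 154:167, 224) %in% out$band_ids))

  # empty exclusion is the identity
  same <- exclude_bands(cube224, band_exclusion(), quiet = TRUE)
  expect_identical(same$values, cube224$values)
  expect_equal(attr(same, "n_removed"), 0L)

  # overlapping ranges collapse to a union, computed here by brute force
  cube10 <- hyper_cube(array(runif(2 * 2 * 10), c(2, 2, 10)))
  union_ids <- unique(c(1:3, 2:5))
  out10 <- exclude_bands(cube10, band_exclusion(list(c(1, 3), c(2, 5))),
                         quiet = TRUE)
  expect_equal(attr(out10, "n_removed"), length(union_ids))  # 5, not 7
  expect_equal(out10$band_ids, setdiff(1:10, union_ids))

  expect_error(exclude_bands(cube10, band_exclusion(singletons = 11L)),
               "outside")
  expect_error(band_exclusion(list(c(5, 3))), "lo <= hi")
})

test_that("band exclusions with disjoint lists commute", {
  cube <- hyper_cube(array(runif(2 * 2 * 30), c(2, 2, 30)))
  a <- band_exclusion(list(c(3, 7)))
  b <- band_exclusion(singletons = c(12L, 20L))
  ab <- exclude_bands(exclude_bands(cube, a, quiet = TRUE), b, quiet = TRUE)
  ba <- exclude_bands(exclude_bands(cube, b, quiet = TRUE), a, quiet = TRUE)
  expect_identical(ab$band_ids, ba$band_ids)
  expect_identical(ab$values, ba$values)
})

test_that("min-max normalization maps each band to [0, 1]", {
  v <- array(0, c(1, 3, 2))
  v[1, , 1] <- c(2, 4, 6)
  v[1, , 2] <- c(5, 5, 5)
  out <- minmax_normalize(hyper_cube(v))
  expect_equal(as.vector(out$values[1, , 1]), c(0, 0.5, 1))
  expect_equal(as.vector(out$values[1, , 2]), c(0, 0, 0))  # constant band

  set.seed(42)
  cube <- minmax_normalize(hyper_cube(array(rnorm(4 * 4 * 3), c(4, 4, 3))))
  for (b in 1:3) {
    expect_equal(min(cube$values[, , b]), 0)
    expect_equal(max(cube$values[, , b]), 1)
  }
})

test_that("mask_background keeps labeled pixels in raster order", {
  cube <- hyper_cube(array(seq_len(2 * 2 * 3), c(2, 2, 3)))
  empty <- mask_background(cube, label_map(matrix(0L, 2, 2)))
  expect_equal(nrow(empty$features), 0L)

  lab <- matrix(c(0L, 2L, 1L, 0L), 2, 2)     # (1,1)=0 (2,1)=2 (1,2)=1 (2,2)=0
  tab <- mask_background(cube, label_map(lab))
  expect_equal(nrow(tab$features), 2L)
  # raster order: row 1 first -> (1,2) label 1 before (2,1) label 2
  expect_equal(tab$coords, cbind(row = c(1L, 2L), col = c(2L, 1L)))
  expect_equal(tab$labels, c(1L, 2L))
  expect_equal(tab$features[1, ], as.vector(cube$values[1, 2, ]))

  sc <- make_scene(scene_spec(M = 30, N = 30, background_fraction = 0.37,
                              seed = 5))
  tab2 <- mask_background(sc$cube, sc$labels)
  expect_equal(nrow(tab2$features), sum(sc$labels$labels > 0))
  expect_equal(nrow(tab2$features) + sum(sc$labels$labels == 0), 30 * 30)

  bad <- label_map(matrix(1L, 3, 3))
  expect_error(mask_background(cube, bad), "shapes differ")
})

test_that("mirror padding reflects symmetrically with edge duplication", {
  # column edge [a, b, c] with r = 2 -> [b, a, a, b, c, c, b]
  v <- array(0, c(3, 3, 1))
  v[1, , 1] <- c(10, 20, 30)                 # a, b, c along columns of row 1
  pad <- mirror_pad(hyper_cube(v), 2L)
  expect_equal(as.vector(pad$values[3, , 1]), c(20, 10, 10, 20, 30, 30, 20))

  set.seed(7)
  cube <- hyper_cube(array(rnorm(5 * 5 * 2), c(5, 5, 2)))
  for (r in 1:4) {
    p <- mirror_pad(cube, r)
    expect_equal(dim(p$values), c(5 + 2 * r, 5 + 2 * r, 2))
    # interior identity
    expect_identical(p$values[(r + 1):(r + 5), (r + 1):(r + 5), ],
                     cube$values)
  }
  # full equality with the loop-based reflection oracle at r = 2
  r <- 2
  p <- mirror_pad(cube, r)$values
  for (i in seq_len(5 + 2 * r)) for (j in seq_len(5 + 2 * r)) {
    oi <- oracle_reflect(i - r, 5); oj <- oracle_reflect(j - r, 5)
    expect_identical(p[i, j, ], cube$values[oi, oj, ])
  }
  expect_error(mirror_pad(cube, 5), "min\\(M, N\\)")
})

test_that("ENVI write/read round trips all interleaves bit-identically", {
  set.seed(1)
  cube <- hyper_cube(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                     wavelengths = seq(400, 800, 100))
  for (il in c("bsq", "bil", "bip")) {
    path <- file.path(tempdir(), paste0("envi_", il))
    write_cube_envi(cube, path, interleave = il)
    back <- read_cube(path, format = "envi")
    expect_identical(back$values, cube$values)
    expect_equal(back$wavelengths, cube$wavelengths)
    expect_equal(back$band_ids, cube$band_ids)
  }
  expect_error(read_cube(file.path(tempdir(), "nope.dat")), "not found")
  # header/data mismatch: truncate the binary
  path <- file.path(tempdir(), "envi_bad")
  write_cube_envi(cube, path)
  writeBin(raw(8), path)
  expect_error(read_cube(path, format = "envi"), "does not match")
})

test_that("label maps round trip through integer ENVI rasters", {
  lab <- label_map(matrix(sample(0:4, 30, replace = TRUE), 5, 6))
  path <- file.path(tempdir(), "labels.dat")
  write_label_map(lab, path)
  expect_identical(read_label_map(path)$labels, lab$labels)
})

test_that("MAT containers round trip and accept the benchmark layout", {
  set.seed(2)
  a <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  path <- file.path(tempdir(), "small.mat")
  write_mat(list(cube = a, gt = matrix(as.double(0:8), 3, 3)), path)
  back <- read_mat(path)
  expect_identical(back$cube, a)
  expect_identical(back$gt, array(as.double(0:8), c(3, 3)))

  # benchmark-sized container written in the distribution layout
  big <- array(runif(145 * 145 * 220), c(145, 145, 220))
  bp <- file.path(tempdir(), "pines_like_synthetic.mat")
  write_mat(list(scene_corrected = big), bp)
  cube <- read_cube(bp)
  expect_equal(dim(cube$values), c(145L, 145L, 220L))
  expect_equal(cube$band_ids, 1:220)
  expect_identical(cube$values[17, 3, 100], big[17, 3, 100])
  unlink(bp)
})

test_that("archive round trip preserves the cube exactly", {
  cube <- hyper_cube(array(rnorm(24), c(2, 3, 4)), band_ids = c(2L, 5L, 7L, 9L))
  path <- file.path(tempdir(), "cube.rds")
  write_cube(cube, path)
  expect_identical(read_cube(path), cube)
})

test_that("container constructors enforce their invariants", {
  expect_error(hyper_cube(matrix(1, 2, 2)), "3-d")
  expect_error(hyper_cube(array(1, c(2, 2, 3)), band_ids = c(3L, 2L, 5L)),
               "increasing")
  v <- array(1, c(2, 2, 2)); v[1, 1, 1] <- NA
  expect_error(hyper_cube(v), "finite")
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_silent(hyper_cube(v, nodata_mask = mask))  # NA only under the mask
  expect_error(label_map(matrix(-1L, 2, 2)), "non-negative")
})
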