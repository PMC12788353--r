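#' Hyperspectral reflectance cube
#'
#' A `HyperCube` is an `M x N x D` array of reflectance values in
#' `(row, col, band)` order together with the 1-based original band indices
#' (`band_ids`), optional per-band center wavelengths in nanometres, and an
#' optional `M x N` logical nodata mask. Band indices are kept 1-based
#' throughout so that published water-absorption band lists can be applied
#' verbatim.
#'
#' @param values numeric `M x N x D` array, `(row, col, band)` order.
#' @param band_ids integer vector of length `D`, strictly increasing 1-based
#'   original band numbers. Defaults to `1:D`.
#' @param wavelengths optional numeric vector of length `D` (nm).
#' @param nodata_mask optional `M x N` logical matrix, `TRUE` where the pixel
#'   carries no data.
#' @return an object of class `HyperCube`.
#' @export
hyper_cube <- function(values, band_ids = NULL, wavelengths = NULL,
                       nodata_mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array in (row, col, band) order")
  dm <- dim(values)
  if (any(dm < 1L)) stop("all cube dimensions must be >= 1")
  D <- dm[3L]
  if (is.null(band_ids)) band_ids <- seq_len(D)
  band_ids <- as.integer(band_ids)
  if (length(band_ids) != D) stop("length(band_ids) must equal the band count")
  if (D > 1L && any(diff(band_ids) <= 0L))
    stop("band_ids must be strictly increasing")
  if (!is.null(wavelengths) && length(wavelengths) != D)
    stop("wavelengths must have one entry per band")
  if (!is.null(nodata_mask)) {
    if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dm[1:2]))
      stop("nodata_mask must be a logical M x N matrix")
  }
  valid <- if (is.null(nodata_mask)) TRUE else !as.vector(nodata_mask)
  if (!all(is.finite(values[rep(valid, times = D)])))
    stop("cube values must be finite outside the nodata mask")
  structure(list(values = values, band_ids = band_ids,
                 wavelengths = wavelengths, nodata_mask = nodata_mask),
            class = "HyperCube")
}

#' @export
print.HyperCube <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("HyperCube: %d x %d pixels, %d bands (ids %d..%d)\n",
              dm[1], dm[2], dm[3], min(x$band_ids), max(x$band_ids)))
  if (!is.null(x$wavelengths))
    cat(sprintf("  wavelengths %.1f-%.1f nm\n",
                min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$nodata_mask))
    cat(sprintf("  nodata pixels: %d\n", sum(x$nodata_mask)))
  invisible(x)
}

#' @export
dim.HyperCube <- function(x) dim(x$values)

#' Integer class-label raster
#'
#' Labels are integers in `0..K`; 0 is reserved for background/unlabeled
#' pixels and never acts as a training or evaluation class.
#'
#' @param labels integer `M x N` matrix.
#' @param class_names optional named character vector mapping label to name.
#' @return an object of class `LabelMap`.
#' @export
label_map <- function(labels, class_names = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be an M x N matrix")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers (0 = background)")
  structure(list(labels = labels, class_names = class_names),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0L])
  cat(sprintf("LabelMap: %d x %d, %d classes, %d background pixels\n",
              nrow(x$labels), ncol(x$labels), length(tab),
              sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.LabelMap <- function(x) dim(x$labels)

#' Band exclusion list
#'
#' The union of inclusive 1-based index ranges and singleton indices, as
#' printed in published water-absorption band lists. Duplicate coverage
#' collapses (the excluded set is a union, not a sum).
#'
#' @param ranges list of length-2 vectors `c(lo, hi)` of inclusive 1-based
#'   band numbers.
#' @param singletons integer vector of single 1-based band numbers.
#' @return an object of class `BandExclusion`.
#' @export
band_exclusion <- function(ranges = list(), singletons = integer()) {
  if (length(ranges) && !is.list(ranges)) ranges <- list(ranges)
  for (rg in ranges) {
    if (length(rg) != 2L || rg[1] < 1L || rg[1] > rg[2])
      stop("each range must be c(lo, hi) with 1 <= lo <= hi")
  }
  ids <- sort(unique(c(unlist(lapply(ranges, function(rg)
    seq.int(rg[1], rg[2]))), as.integer(singletons))))
  structure(list(ranges = ranges, singletons = as.integer(singletons),
                 band_ids = as.integer(ids)),
            class = "BandExclusion")
}

#' Named water-absorption band exclusion presets
#'
#' `"salinas"` removes the twenty AVIRIS water-absorption bands
#' 108-112, 154-167 and 224. `"indian_pines"` carries the printed list
#' 104-108, 150-163 and 200 (also twenty bands); the conventional full
#' AVIRIS list that leaves 200 of 224 bands is available as
#' `"indian_pines_full"` (104-108, 150-163, 220-224). `"none"` excludes
#' nothing. Callers should inspect the reported retained count rather than
#' assume a total.
#'
#' @param name preset name.
#' @return a [band_exclusion()] object.
#' @export
band_exclusion_preset <- function(name = c("salinas", "indian_pines",
                                           "indian_pines_full", "none")) {
  name <- match.arg(name)
  switch(name,
    salinas = band_exclusion(list(c(108, 112), c(154, 167)), 224L),
    indian_pines = band_exclusion(list(c(104, 108), c(150, 163)), 200L),
    indian_pines_full = band_exclusion(list(c(104, 108), c(150, 163),
                                            c(220, 224))),
    none = band_exclusion())
}

#' Remove excluded bands from a cube
#'
#' Drops every band whose original band id falls in the exclusion set and
#' keeps the surviving `band_ids` so later exclusions still refer to the
#' original numbering. The number of removed bands is attached as attribute
#' `"n_removed"` and reported via `message()`.
#'
#' @param cube a [hyper_cube()].
#' @param excl a [band_exclusion()].
#' @param quiet suppress the removal message.
#' @return the filtered `HyperCube` with attribute `n_removed`.
#' @export
exclude_bands <- function(cube, excl, quiet = FALSE) {
  stopifnot(inherits(cube, "HyperCube"), inherits(excl, "BandExclusion"))
  if (length(excl$band_ids) &&
      (min(excl$band_ids) < min(cube$band_ids) ||
       max(excl$band_ids) > max(cube$band_ids)))
    stop("exclusion index outside the cube's band id range")
  keep <- !(cube$band_ids %in% excl$band_ids)
  n_removed <- sum(!keep)
  if (all(keep)) {
    out <- cube
  } else {
    if (!any(keep)) stop("exclusion removes every band")
    out <- hyper_cube(cube$values[, , keep, drop = FALSE],
                      band_ids = cube$band_ids[keep],
                      wavelengths = cube$wavelengths[keep],
                      nodata_mask = cube$nodata_mask)
  }
  attr(out, "n_removed") <- n_removed
  if (!quiet)
    message(sprintf("excluded %d band(s), %d retained", n_removed,
                    sum(keep)))
  out
}

#' Per-band min-max normalization
#'
#' Maps each band independently onto `[0, 1]` using the minimum and maximum
#' over valid (non-nodata) pixels; constant bands map to 0. Keeping the
#' rescaling per band leaves all bands on a common scale so that a single
#' Gaussian kernel width is meaningful across the spectrum.
#'
#' @param cube a [hyper_cube()].
#' @return the normalized `HyperCube`.
#' @export
minmax_normalize <- function(cube) {
  stopifnot(inherits(cube, "HyperCube"))
  v <- cube$values
  D <- dim(v)[3L]
  valid <- if (is.null(cube$nodata_mask)) NULL else !cube$nodata_mask
  for (b in seq_len(D)) {
    band <- v[, , b]
    vals <- if (is.null(valid)) band else band[valid]
    if (!length(vals) || all(!is.finite(vals)))
      stop(sprintf("band %d has no valid data", b))
    lo <- min(vals); hi <- max(vals)
    v[, , b] <- if (hi > lo) (band - lo) / (hi - lo) else band * 0
  }
  hyper_cube(v, band_ids = cube$band_ids, wavelengths = cube$wavelengths,
             nodata_mask = cube$nodata_mask)
}

#' Extract labeled pixels into a flat table
#'
#' Drops all background pixels (label 0, plus any nodata pixels) and returns
#' the remaining pixels in raster (row-major) order: a `PixelTable` with
#' 1-based `(row, col)` coordinates, a `P' x D` feature matrix, and the
#' class vector.
#'
#' @param cube a [hyper_cube()].
#' @param labels a [label_map()] with matching spatial shape.
#' @return an object of class `PixelTable` with fields `coords`, `features`,
#'   `labels`.
#' @export
mask_background <- function(cube, labels) {
  stopifnot(inherits(cube, "HyperCube"), inherits(labels, "LabelMap"))
  dmc <- dim(cube$values)[1:2]
  if (!identical(dmc, dim(labels$labels)))
    stop("cube and label map shapes differ")
  lab <- labels$labels
  keep <- lab > 0L
  if (!is.null(cube$nodata_mask)) keep <- keep & !cube$nodata_mask
  # raster order: all columns of row 1, then row 2, ...
  idx <- which(t(keep))                      # row-major scan
  rows <- (idx - 1L) %/% ncol(lab) + 1L
  cols <- (idx - 1L) %% ncol(lab) + 1L
  D <- dim(cube$values)[3L]
  flat <- matrix(cube$values, nrow = prod(dmc), ncol = D)  # column-major pixels
  lin <- rows + (cols - 1L) * dmc[1L]
  structure(list(coords = cbind(row = rows, col = cols),
                 features = flat[lin, , drop = FALSE],
                 labels = lab[lin]),
            class = "PixelTable")
}

#' @export
print.PixelTable <- function(x, ...) {
  cat(sprintf("PixelTable: %d labeled pixels, %d features, %d classes\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$labels))))
  invisible(x)
}

# Symmetric (edge-duplicating) reflection of 1-based indices into [1, n].
reflect_index <- function(i, n) {
  while (any(i < 1L | i > n)) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
  }
  i
}

# Pad a 3-d array by symmetric reflection (edge pixel included).
pad_array <- function(a, r) {
  dm <- dim(a)
  ri <- reflect_index(seq.int(1L - r, dm[1L] + r), dm[1L])
  ci <- reflect_index(seq.int(1L - r, dm[2L] + r), dm[2L])
  a[ri, ci, , drop = FALSE]
}

#' Mirror-pad a cube
#'
#' Extends the cube by `r` pixels on every side using symmetric reflection
#' that duplicates the edge pixel (a 1-d edge `[a, b, c]` padded by 2
#' becomes `[b, a, a, b, c, c, b]`), so every original pixel has a complete
#' `(2r+1)^2` spatial neighborhood.
#'
#' @param cube a [hyper_cube()].
#' @param r neighborhood radius in pixels, `1 <= r < min(M, N)`.
#' @return the padded `HyperCube` of shape `(M+2r) x (N+2r) x D`.
#' @export
mirror_pad <- function(cube, r) {
  stopifnot(inherits(cube, "HyperCube"))
  dm <- dim(cube$values)
  if (r < 1L || r >= min(dm[1:2]))
    stop("r must satisfy 1 <= r < min(M, N)")
  mask <- cube$nodata_mask
  if (!is.null(mask)) {
    ri <- reflect_index(seq.int(1L - r, dm[1L] + r), dm[1L])
    ci <- reflect_index(seq.int(1L - r, dm[2L] + r), dm[2L])
    mask <- mask[ri, ci, drop = FALSE]
  }
  hyper_cube(pad_array(cube$values, as.integer(r)),
             band_ids = cube$band_ids, wavelengths = cube$wavelengths,
             nodata_mask = mask)
}
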