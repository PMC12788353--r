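### Raster I/O: ENVI (flat binary + text header), MAT v5 containers as
### distributed for the classic airborne benchmarks, and an RDS-based
### portable archive. No raster package ships with the runtime, so the two
### binary formats are parsed directly; both are simple enough that the
### round-trip tests below fully pin the behavior.

# ---------------------------------------------------------------- ENVI ----

.envi_types <- data.frame(
  code = c(1L, 2L, 3L, 4L, 5L, 12L),
  what = c("integer", "integer", "integer", "double", "double", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE)

envi_header_path <- function(path) paste0(path, ".hdr")

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[[1]]))
    stop("not an ENVI header: ", hdr_path)
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  # "key = value" entries; brace-delimited values may span lines
  rx <- gregexpr("(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                 txt, perl = TRUE)[[1]]
  starts <- rx
  lens <- attr(rx, "match.length")
  for (m in seq_along(starts)) {
    piece <- substr(txt, starts[m], starts[m] + lens[m] - 1L)
    key <- tolower(trimws(sub("=.*$", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    val <- gsub("^\\{|\\}$", "", val)
    out[[gsub("\\s+", " ", key)]] <- trimws(val)
  }
  out
}

num_list <- function(x) {
  if (is.null(x)) return(NULL)
  as.numeric(strsplit(x, ",")[[1]])
}

#' Write a cube as an ENVI raster
#'
#' Writes the flat binary file at `path` and a companion text header at
#' `path.hdr`. Values are stored as 64-bit floats by default so that a
#' write/read round trip is bit-identical; pass `data_type = 4` for 32-bit
#' storage.
#'
#' @param cube a [hyper_cube()].
#' @param path output path of the binary file.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code (2, 3, 4, 5 or 12).
#' @return `path`, invisibly.
#' @export
write_cube_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                            data_type = 5L) {
  stopifnot(inherits(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  ti <- .envi_types[.envi_types$code == data_type, ]
  if (!nrow(ti)) stop("unsupported ENVI data type ", data_type)
  dm <- dim(cube$values)
  v <- cube$values                           # (row, col, band)
  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),        # sample fastest, line, band
                 bil = c(2L, 3L, 1L),        # sample, band, line
                 bip = c(3L, 2L, 1L))        # band, sample, line
  flat <- as.vector(aperm(v, perm))
  if (ti$what == "integer") flat <- as.integer(round(flat))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(flat, con, size = ti$size, endian = "little")
  hdr <- c("ENVI",
           "description = {hsirefine export}",
           sprintf("samples = %d", dm[2L]),
           sprintf("lines = %d", dm[1L]),
           sprintf("bands = %d", dm[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("band names = {%s}",
                   paste(sprintf("band %d", cube$band_ids), collapse = ", ")))
  if (!is.null(cube$wavelengths))
    hdr <- c(hdr, sprintf("wavelength = {%s}",
                          paste(cube$wavelengths, collapse = ", ")))
  writeLines(hdr, envi_header_path(path))
  invisible(path)
}

read_cube_envi <- function(path) {
  hdr_path <- envi_header_path(path)
  if (!file.exists(hdr_path)) {
    alt <- sub("\\.[^.]*$", ".hdr", path)
    if (file.exists(alt)) hdr_path <- alt else
      stop("companion ENVI header not found for ", path)
  }
  h <- parse_envi_header(hdr_path)
  M <- as.integer(h$lines); N <- as.integer(h$samples)
  D <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  ti <- .envi_types[.envi_types$code == dtype, ]
  if (!nrow(ti)) stop("unsupported ENVI data type ", dtype)
  interleave <- tolower(h$interleave %||% "bsq")
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  n <- as.numeric(M) * N * D
  expect_bytes <- n * ti$size + as.numeric(h[["header offset"]] %||% 0)
  if (file.info(path)$size != expect_bytes)
    stop("ENVI data size does not match header dimensions")
  con <- file(path, "rb")
  on.exit(close(con))
  off <- as.integer(h[["header offset"]] %||% "0")
  if (off > 0) readBin(con, "raw", n = off)
  flat <- readBin(con, ti$what, n = n, size = ti$size, signed = ti$signed,
                  endian = endian)
  arr <- switch(interleave,
    bsq = aperm(array(flat, dim = c(N, M, D)), c(2L, 1L, 3L)),
    bil = aperm(array(flat, dim = c(N, D, M)), c(3L, 1L, 2L)),
    bip = aperm(array(flat, dim = c(D, N, M)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", interleave))
  band_ids <- NULL
  if (!is.null(h[["band names"]])) {
    ids <- suppressWarnings(as.integer(gsub("[^0-9]", "",
                                            strsplit(h[["band names"]], ",")[[1]])))
    if (!anyNA(ids) && length(ids) == D && all(diff(ids) > 0)) band_ids <- ids
  }
  hyper_cube(arr, band_ids = band_ids, wavelengths = num_list(h$wavelength))
}

#' Write a label raster as a single-band integer ENVI map
#' @param labels a [label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "LabelMap"))
  cube <- hyper_cube(array(as.numeric(labels$labels),
                           dim = c(dim(labels$labels), 1L)))
  write_cube_envi(cube, path, data_type = 3L)
}

#' Read a single-band integer ENVI map as a label raster
#' @param path path of the binary file (companion `.hdr` required).
#' @return a [label_map()].
#' @export
read_label_map <- function(path) {
  cube <- read_cube_envi(path)
  if (dim(cube$values)[3L] != 1L) stop("label raster must be single band")
  label_map(matrix(as.integer(round(cube$values[, , 1L])),
                   nrow = dim(cube$values)[1L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------- MAT v5 ----
# Minimal MAT-file (level 5) support for numeric arrays, the layout used to
# distribute the airborne benchmark cubes and their ground truth. The writer
# emits uncompressed elements; the reader additionally inflates
# zlib-compressed (miCOMPRESSED) elements when the zlib stream is readable.

.mat_mi <- c(miINT8 = 1L, miUINT8 = 2L, miINT16 = 3L, miUINT16 = 4L,
             miINT32 = 5L, miUINT32 = 6L, miSINGLE = 7L, miDOUBLE = 9L,
             miMATRIX = 14L, miCOMPRESSED = 15L)

pad8 <- function(n) (8L - n %% 8L) %% 8L

#' Write named numeric arrays to a MAT v5 container
#'
#' Supports 2-d and 3-d double arrays (class `mxDOUBLE`), uncompressed.
#' Intended for fixtures and interchange with the benchmark distribution
#' layout (`indian_pines_corrected`, `indian_pines_gt`, ...).
#'
#' @param vars named list of numeric arrays/matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by hsirefine")
  head <- charToRaw(desc)
  head <- c(head, raw(124L - length(head)))
  writeBin(head, con)
  writeBin(c(0L, 1L), con, size = 1L)                   # version 0x0100 LE
  writeBin(charToRaw("IM"), con)                        # endianness marker
  for (nm in names(vars)) {
    a <- vars[[nm]]
    if (is.matrix(a) || is.vector(a)) a <- as.array(a)
    dm <- dim(a); if (is.null(dm)) dm <- c(length(a), 1L)
    name_raw <- charToRaw(nm)
    n_data <- length(a) * 8L
    sz <- 16L +                                          # array flags
      8L + 4L * length(dm) + pad8(4L * length(dm)) +     # dimensions
      8L + length(name_raw) + pad8(length(name_raw)) +   # name
      8L + n_data + pad8(n_data)                         # real data
    writeBin(c(.mat_mi[["miMATRIX"]], as.integer(sz)), con, size = 4L)
    writeBin(c(.mat_mi[["miUINT32"]], 8L), con, size = 4L)
    writeBin(c(6L, 0L), con, size = 4L)                  # mxDOUBLE, no flags
    writeBin(c(.mat_mi[["miINT32"]], 4L * length(dm)), con, size = 4L)
    writeBin(as.integer(dm), con, size = 4L)
    writeBin(raw(pad8(4L * length(dm))), con)
    writeBin(c(.mat_mi[["miINT8"]], length(name_raw)), con, size = 4L)
    writeBin(name_raw, con)
    writeBin(raw(pad8(length(name_raw))), con)
    writeBin(c(.mat_mi[["miDOUBLE"]], n_data), con, size = 4L)
    writeBin(as.vector(a, mode = "double"), con, size = 8L)
    writeBin(raw(pad8(n_data)), con)
  }
  invisible(path)
}

read_u32 <- function(raw, at, endian) {
  readBin(raw[at + 0:3], "integer", size = 4L, endian = endian)
}

mat_read_numeric <- function(raw, type, endian) {
  switch(as.character(type),
    `1` = readBin(raw, "integer", n = length(raw), size = 1L, signed = TRUE, endian = endian),
    `2` = readBin(raw, "integer", n = length(raw), size = 1L, signed = FALSE, endian = endian),
    `3` = readBin(raw, "integer", n = length(raw) / 2L, size = 2L, signed = TRUE, endian = endian),
    `4` = readBin(raw, "integer", n = length(raw) / 2L, size = 2L, signed = FALSE, endian = endian),
    `5` = readBin(raw, "integer", n = length(raw) / 4L, size = 4L, endian = endian),
    `7` = readBin(raw, "numeric", n = length(raw) / 4L, size = 4L, endian = endian),
    `9` = readBin(raw, "numeric", n = length(raw) / 8L, size = 8L, endian = endian),
    stop("unsupported MAT numeric type ", type))
}

mat_parse_element <- function(body, endian) {
  # body: raw payload of one miMATRIX element; returns list(name=, value=)
  pos <- 1L
  read_tag <- function() {
    t <- read_u32(body, pos, endian)
    if (bitwAnd(t, -65536L) != 0L) {       # small data element
      type <- bitwAnd(t, 65535L)
      nbytes <- bitwShiftR(bitwAnd(t, -65536L), 16L)
      dat <- body[pos + 4L + seq_len(nbytes) - 1L]
      pos <<- pos + 8L
      list(type = type, data = dat)
    } else {
      nbytes <- read_u32(body, pos + 4L, endian)
      dat <- if (nbytes > 0L) body[pos + 8L + seq_len(nbytes) - 1L] else raw()
      pos <<- pos + 8L + nbytes + pad8(nbytes)
      list(type = t, data = dat)
    }
  }
  flags <- read_tag()
  cls <- as.integer(flags$data[1L])
  dims_el <- read_tag()
  dm <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4L,
                size = 4L, endian = endian)
  name_el <- read_tag()
  nm <- rawToChar(name_el$data)
  data_el <- read_tag()
  vals <- mat_read_numeric(data_el$data, data_el$type, endian)
  if (length(vals) != prod(dm))
    stop("MAT array '", nm, "': data length does not match dimensions")
  list(name = nm, value = array(vals, dim = dm), class = cls)
}

#' Read numeric arrays from a MAT v5 container
#'
#' Parses real numeric arrays (double, single and integer classes) from an
#' uncompressed MAT v5 file; zlib-compressed elements are inflated through
#' `memDecompress` where the platform zlib accepts the stream. Cell arrays,
#' structs, sparse and complex data are out of scope.
#'
#' @param path path to the `.mat` file.
#' @return named list of arrays.
#' @export
read_mat <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file: ", path)
  marker <- rawToChar(raw[127:128])
  endian <- if (marker == "IM") "little" else if (marker == "MI") "big" else
    stop("not a MAT v5 file (bad endian marker)")
  out <- list()
  pos <- 129L
  while (pos + 8L <= length(raw) + 1L) {
    type <- read_u32(raw, pos, endian)
    nbytes <- read_u32(raw, pos + 4L, endian)
    body <- raw[pos + 8L + seq_len(nbytes) - 1L]
    pos <- pos + 8L + nbytes + pad8(nbytes)
    if (type == .mat_mi[["miCOMPRESSED"]]) {
      inflated <- tryCatch(memDecompress(body, type = "gzip"),
                           error = function(e) NULL)
      if (is.null(inflated))
        stop("cannot inflate compressed MAT element (zlib stream)")
      type <- read_u32(inflated, 1L, endian)
      body <- inflated[8L + seq_len(read_u32(inflated, 5L, endian))]
    }
    if (type != .mat_mi[["miMATRIX"]]) next
    el <- mat_parse_element(body, endian)
    out[[el$name]] <- el$value
  }
  out
}

# ---------------------------------------------------------------- facade ----

#' Read a hyperspectral cube from disk
#'
#' @param path input path. ENVI rasters need a companion `.hdr`; MAT
#'   containers should hold one `M x N x D` numeric array (the first 3-d
#'   array is taken, or name it with `var`); archives are RDS files written
#'   by [write_cube()].
#' @param format `"auto"` (by extension), `"envi"`, `"mat"` or `"archive"`.
#' @param var optional variable name inside a MAT container.
#' @return a [hyper_cube()].
#' @export
read_cube <- function(path, format = c("auto", "envi", "mat", "archive"),
                      var = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mat = "mat", rds = "archive", "envi")
  }
  switch(format,
    envi = read_cube_envi(path),
    archive = {
      obj <- readRDS(path)
      if (!inherits(obj, "HyperCube")) stop("archive does not hold a HyperCube")
      obj
    },
    mat = {
      vars <- read_mat(path)
      if (!is.null(var)) {
        if (is.null(vars[[var]])) stop("variable '", var, "' not in ", path)
        a <- vars[[var]]
      } else {
        is3d <- vapply(vars, function(v) length(dim(v)) == 3L, logical(1))
        if (!any(is3d)) stop("no 3-d array found in ", path)
        a <- vars[[which(is3d)[1L]]]
      }
      hyper_cube(a * 1.0)
    })
}

#' Write a hyperspectral cube to disk
#'
#' @param cube a [hyper_cube()].
#' @param path output path.
#' @param format `"envi"`, `"mat"` or `"archive"`; `"auto"` picks from the
#'   extension (`.mat`, `.rds`, otherwise ENVI).
#' @param ... passed to [write_cube_envi()] for ENVI output.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "mat", "archive"),
                       ...) {
  stopifnot(inherits(cube, "HyperCube"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mat = "mat", rds = "archive", "envi")
  }
  switch(format,
    envi = write_cube_envi(cube, path, ...),
    mat = write_mat(list(cube = cube$values), path),
    archive = { saveRDS(cube, path); invisible(path) })
}
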