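#' @title Volumetric image and label I/O
#'
#' @description Readers and writers for single-channel 3D volumes in
#' multi-page TIFF and HDF5 form, using the `(Z, Y, X)` axis convention
#' (page = Z slice). Label volumes hold non-negative integers with 0 reserved
#' for background; in TIFF form they are stored as 16-bit unsigned samples
#' when the maximum label fits, and otherwise as 32-bit float samples scaled
#' by `2^24` (exact for labels below 2^24). HDF5 labels are stored as uint32.
#'
#' @name volume_io
NULL

.is_h5 <- function(path) grepl("\\.(h5|hdf5|he5)$", path, ignore.case = TRUE)

# read TIFF pages; 8/16-bit pages are integer samples and are returned at
# their raw values, 32-bit pages are returned as stored (floating point)
.read_tiff_pages <- function(path) {
  meta <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                   error = function(e) stop("unreadable format: ", path, " (",
                                            conditionMessage(e), ")",
                                            call. = FALSE))
  if (!is.list(meta)) meta <- list(meta)
  bits <- attr(meta[[1]], "bits.per.sample")
  if (!is.null(bits) && bits <= 16)
    meta <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(meta)) meta <- list(meta)
  attr(meta, "bits.per.sample") <- bits
  meta
}

.check_vol3d <- function(a, what = "volume") {
  if (is.null(dim(a)) || length(dim(a)) != 3L)
    stop("non-3D data: ", what, " must be a 3D array (Z, Y, X)", call. = FALSE)
  invisible(a)
}

#' Read a 3D intensity volume
#'
#' @param path Path to a multi-page TIFF (`.tif`/`.tiff`) or HDF5
#'   (`.h5`/`.hdf5`) file.
#' @param dataset_key Dataset name inside an HDF5 file; required for HDF5,
#'   ignored for TIFF.
#' @return A numeric 3D array with dim `(Z, Y, X)`. Integer-typed storage is
#'   mapped to reals without rescaling.
#' @export
read_intensity_volume <- function(path, dataset_key = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  if (.is_h5(path)) {
    if (is.null(dataset_key))
      stop("dataset_key is required for HDF5 input", call. = FALSE)
    r <- cpp_h5_read(path, dataset_key)
    # HDF5 stores row-major (d1 slowest); undo to get dim (d1,d2,d3) col-major
    a <- array(r$data, dim = rev(r$dims))
    return(aperm(a, 3:1))
  }
  pages <- .read_tiff_pages(path)
  if (length(pages) < 2L && length(dim(pages[[1]])) != 2L)
    stop("non-3D data: expected grayscale pages in ", path, call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("non-3D data: multi-channel TIFF pages are not supported", call. = FALSE)
  if (length(pages) == 1L)
    stop("non-3D data: single-page 2D TIFF", call. = FALSE)
  a <- aperm(simplify2array(pages), c(3L, 1L, 2L))  # (Z, Y, X)
  storage.mode(a) <- "double"
  a
}

#' Write a 3D intensity volume
#'
#' @param volume Numeric 3D array `(Z, Y, X)` of finite intensities.
#' @param path Output path; `.tif`/`.tiff` writes 32-bit float pages
#'   (values clamped to `[0, 1]`), `.h5` writes a float64 dataset.
#' @param dataset_key HDF5 dataset name (default `"volume"`).
#' @export
write_intensity_volume <- function(volume, path, dataset_key = "volume") {
  .check_vol3d(volume)
  stopifnot(all(is.finite(volume)))
  if (.is_h5(path)) {
    # HDF5 is row-major: flatten so the last stored axis (X) varies fastest
    cpp_h5_write(path, dataset_key, as.numeric(aperm(volume, 3:1)),
                 dim(volume), FALSE, TRUE)
    return(invisible(path))
  }
  v <- pmin(pmax(volume, 0), 1)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                 error = function(e) stop("unwritable path: ", path,
                                          call. = FALSE))
  invisible(path)
}

#' Write an instance label volume
#'
#' The integer width is chosen from the maximum label: TIFF files use 16-bit
#' unsigned samples up to 65535 and 32-bit float samples (scaled by `2^24`,
#' exact below 2^24) beyond; HDF5 stores uint32. A round-trip through
#' [read_label_volume()] returns identical values.
#'
#' @param labels Integer-valued 3D array `(Z, Y, X)`, 0 = background.
#' @param path Output path (`.tif`/`.tiff` or `.h5`).
#' @param dataset_key HDF5 dataset name (default `"labels"`).
#' @export
write_label_volume <- function(labels, path, dataset_key = "labels") {
  .check_vol3d(labels, "labels")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  mx <- max(labels)
  if (.is_h5(path)) {
    cpp_h5_write(path, dataset_key, as.numeric(aperm(labels, 3:1)),
                 dim(labels), TRUE, TRUE)
    return(invisible(path))
  }
  if (mx >= 2^24)
    stop("TIFF label storage supports labels below 2^24; use HDF5",
         call. = FALSE)
  if (mx <= 65535) {
    pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
    bits <- 16L
  } else {
    pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 2^24)
    bits <- 32L
  }
  tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
           error = function(e) stop("unwritable path: ", path, call. = FALSE))
  invisible(path)
}

#' Read an instance label volume written by [write_label_volume()]
#'
#' @inheritParams read_intensity_volume
#' @return Integer 3D array `(Z, Y, X)`.
#' @export
read_label_volume <- function(path, dataset_key = "labels") {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  if (.is_h5(path)) {
    r <- cpp_h5_read(path, dataset_key)
    a <- array(as.integer(round(r$data)), dim = rev(r$dims))
    return(aperm(a, 3:1))
  }
  pages <- .read_tiff_pages(path)
  bits <- attr(pages, "bits.per.sample")
  a <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  if (!is.null(bits) && bits > 16) a <- round(a * 2^24)  # label / 2^24 pages
  storage.mode(a) <- "integer"
  a
}

#' Plan an overlapping tiling of a volume
#'
#' Splits a volume into tiles of at most `tile_extent` voxels per axis with
#' the given overlap. Each tile owns a disjoint core region; the core regions
#' exactly partition the volume, and boundary tiles are shifted inward so
#' every tile lies inside the volume. Tiles larger than the volume are
#' clamped to the volume extent.
#'
#' @param extent Integer vector of 3 volume extents `(Z, Y, X)`.
#' @param tile_extent Integer vector of 3 tile extents.
#' @param overlap Integer vector of 3 overlaps (each `< tile_extent`).
#' @return A `tile_layout` object: list with `extent`, `tile_extent`,
#'   `overlap` and `tiles`, a list of `list(origin=, tile=, core=)` entries
#'   (1-based inclusive index ranges per axis).
#' @export
plan_tiles <- function(extent, tile_extent, overlap = c(0L, 0L, 0L)) {
  extent <- as.integer(extent); tile_extent <- as.integer(tile_extent)
  overlap <- as.integer(overlap)
  stopifnot(length(extent) == 3L, length(tile_extent) == 3L,
            length(overlap) == 3L, all(extent >= 1L), all(tile_extent >= 1L),
            all(overlap >= 0L), all(overlap < tile_extent))
  tile_extent <- pmin(tile_extent, extent)
  axes <- lapply(1:3, function(a) {
    te <- tile_extent[a]; ov <- overlap[a]; n <- extent[a]
    if (te >= n) {
      starts <- 1L
    } else {
      step <- max(te - ov, 1L)
      starts <- seq.int(1L, n - te + 1L, by = step)
      if (starts[length(starts)] + te - 1L < n)
        starts <- c(starts, n - te + 1L)  # final tile shifted inward
      starts <- unique(starts)
    }
    # core boundaries at the midpoints of consecutive tile overlaps
    k <- length(starts)
    core_lo <- integer(k); core_hi <- integer(k)
    for (i in seq_len(k)) {
      core_lo[i] <- if (i == 1L) 1L else core_hi[i - 1L] + 1L
      core_hi[i] <- if (i == k) n else
        (starts[i] + te - 1L + starts[i + 1L]) %/% 2L
    }
    list(starts = starts, core_lo = core_lo, core_hi = core_hi, te = te)
  })
  tiles <- list()
  for (ix in seq_along(axes[[3]]$starts))
    for (iy in seq_along(axes[[2]]$starts))
      for (iz in seq_along(axes[[1]]$starts)) {
        ii <- c(iz, iy, ix)
        origin <- vapply(1:3, function(a) axes[[a]]$starts[ii[a]], integer(1))
        te <- vapply(1:3, function(a) axes[[a]]$te, integer(1))
        core_lo <- vapply(1:3, function(a) axes[[a]]$core_lo[ii[a]], integer(1))
        core_hi <- vapply(1:3, function(a) axes[[a]]$core_hi[ii[a]], integer(1))
        tiles[[length(tiles) + 1L]] <- list(
          origin = origin,
          tile = cbind(lo = origin, hi = origin + te - 1L),
          core = cbind(lo = core_lo, hi = core_hi))
      }
  structure(list(extent = extent, tile_extent = tile_extent, overlap = overlap,
                 tiles = tiles),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat("tile_layout:", length(x$tiles), "tiles over volume",
      paste(x$extent, collapse = "x"), "\n")
  invisible(x)
}

#' Stitch per-tile class probability volumes
#'
#' Reassembles a full-volume probability field from per-tile predictions by
#' copying each tile's core region only; overlap margins are discarded, which
#' removes seam effects at tile borders.
#'
#' @param layout A [plan_tiles()] layout.
#' @param tiles List of 4D arrays `(z, y, x, class)` matching the layout's
#'   tile extents, in layout order.
#' @return 4D array `(Z, Y, X, n_class)` covering the full volume.
#' @export
stitch_probability_tiles <- function(layout, tiles) {
  stopifnot(inherits(layout, "tile_layout"),
            length(tiles) == length(layout$tiles))
  nc <- dim(tiles[[1]])[4]
  out <- array(NA_real_, c(layout$extent, nc))
  for (i in seq_along(tiles)) {
    tl <- layout$tiles[[i]]
    ext <- tl$tile[, "hi"] - tl$tile[, "lo"] + 1L
    if (!all(dim(tiles[[i]])[1:3] == ext))
      stop("tile ", i, " shape mismatch: expected ",
           paste(ext, collapse = "x"), call. = FALSE)
    lo <- tl$core[, "lo"]; hi <- tl$core[, "hi"]
    loc_lo <- lo - tl$origin + 1L; loc_hi <- hi - tl$origin + 1L
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], ] <-
      tiles[[i]][loc_lo[1]:loc_hi[1], loc_lo[2]:loc_hi[2],
                 loc_lo[3]:loc_hi[3], , drop = FALSE]
  }
  stopifnot(!anyNA(out))
  out
}
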