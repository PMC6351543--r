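#' Binary mask raster
#'
#' A single-channel binary raster tied to a pyramid scale: `scale = s` means
#' the raster side is the level-0 side divided by `s` (ceiling). Semantics:
#' `1` = tumor (or tissue foreground), `0` = normal (or background).
#'
#' @param data numeric/integer/logical matrix with values in `{0, 1}`.
#' @param scale power-of-two scale denominator (1, 8, 32 and 128 are the
#'   scales used by the pipeline).
#' @return object of class `mask_raster` with fields `data` (integer matrix)
#'   and `scale`.
#' @export
mask_raster <- function(data, scale) {
  if (is.logical(data)) data <- data * 1L
  if (!is.matrix(data) || nrow(data) < 1L || ncol(data) < 1L) stop("mask must be a non-empty matrix")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  scale <- assert_pow2_scale(scale, "mask scale")
  storage.mode(data) <- "integer"
  structure(list(data = data, scale = scale), class = "mask_raster")
}

#' @export
print.mask_raster <- function(x, ...) {
  cat(sprintf("<mask_raster> %d x %d at scale 1/%d, foreground %.1f%%\n",
              ncol(x$data), nrow(x$data), x$scale, 100 * mean(x$data)))
  invisible(x)
}

#' Probability heatmap
#'
#' A float raster of tumor probabilities in `[0, 1]` at a stated scale
#' (`8` = dense, `128` = rough), with an optional provenance raster `counts`
#' giving the number of predictions averaged into each cell (cells with
#' `counts = 0` carry the fill value 0).
#'
#' @param data numeric matrix in `[0, 1]`.
#' @param scale power-of-two scale denominator.
#' @param counts optional integer matrix of contributing-prediction counts.
#' @return object of class `prob_heatmap`.
#' @export
prob_heatmap <- function(data, scale, counts = NULL) {
  if (!is.matrix(data) || nrow(data) < 1L || ncol(data) < 1L) stop("heatmap must be a non-empty matrix")
  if (anyNA(data) || any(data < 0) || any(data > 1)) stop("heatmap values must be in [0, 1]")
  scale <- assert_pow2_scale(scale, "heatmap scale")
  if (!is.null(counts)) {
    stopifnot(is.matrix(counts), all(dim(counts) == dim(data)), all(counts >= 0))
    storage.mode(counts) <- "integer"
  }
  structure(list(data = data, scale = scale, counts = counts), class = "prob_heatmap")
}

#' @export
print.prob_heatmap <- function(x, ...) {
  cat(sprintf("<prob_heatmap> %d x %d at scale 1/%d, range [%.3f, %.3f]\n",
              ncol(x$data), nrow(x$data), x$scale, min(x$data), max(x$data)))
  invisible(x)
}

# Minimal uncompressed single-strip float32 TIFF (SampleFormat = IEEEFP),
# little-endian, with the description tag carrying metadata. Written by hand
# because the available TIFF bindings only write integer sample formats;
# reading goes through libtiff (tiff::readTIFF), which handles float TIFFs.
write_f32_tiff <- function(data, path, desc) {
  h <- nrow(data); w <- ncol(data)
  descb <- c(charToRaw(desc), as.raw(0))
  desc_n <- length(descb)
  if (desc_n %% 2 == 1L) descb <- c(descb, as.raw(0))
  nbytes <- 4 * h * w
  data_off <- 8L
  desc_off <- data_off + nbytes
  ifd_off <- desc_off + length(descb)
  con <- file(path, "wb"); on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42); w32(ifd_off)
  writeBin(as.numeric(t(data)), con, size = 4, endian = "little")  # row-major float32
  writeBin(descb, con)
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3 && count == 1) { w16(value); w16(0) } else w32(value)
  }
  w16(11)  # IFD entry count; tags in ascending order
  entry(256, 4, 1, w)          # ImageWidth
  entry(257, 4, 1, h)          # ImageLength
  entry(258, 3, 1, 32)         # BitsPerSample
  entry(259, 3, 1, 1)          # Compression = none
  entry(262, 3, 1, 1)          # Photometric = BlackIsZero
  entry(270, 2, desc_n, desc_off)  # ImageDescription
  entry(273, 4, 1, data_off)   # StripOffsets
  entry(277, 3, 1, 1)          # SamplesPerPixel
  entry(278, 4, 1, h)          # RowsPerStrip
  entry(279, 4, 1, nbytes)     # StripByteCounts
  entry(339, 3, 1, 3)          # SampleFormat = IEEE float
  w32(0)                       # no next IFD
  invisible(path)
}

#' Heatmap file I/O
#'
#' Heatmaps are stored as single-channel IEEE float32 TIFFs with the scale
#' recorded in the description tag; the round trip is bit-exact at float32
#' precision (write quantizes doubles to float32; write/read is idempotent).
#' The provenance count raster is not persisted (`read_heatmap` returns
#' `counts = NULL`).
#'
#' @param hm a [prob_heatmap()].
#' @param path file path.
#' @rdname heatmap_io
#' @export
write_heatmap <- function(hm, path) {
  stopifnot(inherits(hm, "prob_heatmap"))
  write_f32_tiff(hm$data, path, sprintf("wsicascade-heatmap;scale=%d", hm$scale))
  invisible(path)
}

#' @param scale scale override for files without the description tag.
#' @rdname heatmap_io
#' @export
read_heatmap <- function(path, scale = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  r <- tiff::readTIFF(path, info = TRUE)
  if (is.null(scale)) {
    desc <- attr(r, "description")
    m <- if (is.null(desc)) character(0) else
      regmatches(desc, regexec("scale=([0-9]+)", desc))[[1]]
    if (length(m) < 2L) stop("heatmap file carries no scale tag; pass `scale`")
    scale <- as.integer(m[2])
  }
  d <- matrix(as.numeric(r), nrow(r))
  prob_heatmap(d, scale)
}

#' Mask file I/O
#'
#' Masks are stored as single-channel 8-bit PNGs (0 = background,
#' 255 = foreground) with the scale in a PNG text chunk; the round trip is
#' exact.
#'
#' @param mask a [mask_raster()].
#' @param path file path.
#' @rdname mask_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_raster"))
  png::writePNG(mask$data + 0.0, path, text = c(scale = as.character(mask$scale)))
  invisible(path)
}

#' @param scale scale override when the file carries no text chunk.
#' @rdname mask_io
#' @export
read_mask <- function(path, scale = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  r <- png::readPNG(path, info = TRUE)
  if (length(dim(r)) == 3L) r <- r[, , 1]
  if (!all(r %in% c(0, 1))) stop("mask file values must be 0 or 255")
  if (is.null(scale)) {
    txt <- attr(r, "info")$text
    if (is.null(txt) || is.na(txt["scale"])) stop("mask file carries no scale chunk; pass `scale`")
    scale <- as.integer(txt[["scale"]])
  }
  d <- unclass(r); attributes(d) <- list(dim = dim(r))
  mask_raster(d, scale)
}

#' Sample a level-0 mask at the stride-s lattice
#'
#' Takes the value at lattice points `(s*x, s*y)` (0-based; nearest, no
#' averaging) — the same convention the pixel loss and the dense-heatmap
#' ground truth use. The result has ceiling-division dimensions, matching
#' heatmaps at the same scale.
#'
#' @param mask a [mask_raster()] at scale 1.
#' @param s target scale (default 8).
#' @return a [mask_raster()] at scale `s`.
#' @export
lattice_mask <- function(mask, s = 8L) {
  stopifnot(inherits(mask, "mask_raster"))
  if (mask$scale != 1L) stop("lattice_mask expects a level-0 (scale 1) mask")
  s <- assert_pow2_scale(s, "s")
  d <- mask$data[seq(1L, nrow(mask$data), s), seq(1L, ncol(mask$data), s), drop = FALSE]
  mask_raster(d, s)
}
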