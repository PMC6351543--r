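#' Multi-resolution slide pyramid
#'
#' A `slide_pyramid` holds an ordered list of RGB rasters where page/level
#' `k` is the level-0 image downsampled by `2^k`. Level 0 is the full-resolution
#' scan (40x magnification by convention); level `k` is at `40 / 2^k` x.
#' All window coordinates in this package are 0-based level-0 pixel
#' coordinates, `(x = column, y = row)`, and windows are half-open:
#' a window at `(x, y)` with side `size` covers `[x, x + size) x [y, y + size)`.
#'
#' @param levels list of numeric arrays `h x w x 3` with values in `[0, 255]`,
#'   ordered from level 0 (largest) upward.
#' @param tol maximum allowed deviation (pixels) of each level's dimensions
#'   from `ceiling(dim0 / 2^k)`, to tolerate scanner rounding. Default 1.
#' @return object of class `slide_pyramid` with fields `levels`, `width0`,
#'   `height0`.
#' @export
slide_pyramid <- function(levels, tol = 1L) {
  if (!is.list(levels) || length(levels) < 1L) stop("levels must be a non-empty list")
  for (k in seq_along(levels)) {
    d <- dim(levels[[k]])
    if (length(d) != 3L || d[3] != 3L) stop("each level must be an h x w x 3 RGB array")
    if (d[1] < 1L || d[2] < 1L) stop("empty level raster")
  }
  d0 <- dim(levels[[1]])
  for (k in seq_along(levels)) {
    want <- ceiling(d0[1:2] / 2^(k - 1))
    got <- dim(levels[[k]])[1:2]
    if (any(abs(got - want) > tol)) {
      stop(sprintf("malformed pyramid: level %d is %dx%d, expected %dx%d (2^k rule)",
                   k - 1L, got[2], got[1], want[2], want[1]))
    }
  }
  structure(list(levels = levels, width0 = d0[2], height0 = d0[1]),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("<slide_pyramid> %d x %d px at level 0 (40x), %d level(s)\n",
              x$width0, x$height0, length(x$levels)))
  for (k in seq_along(x$levels)) {
    d <- dim(x$levels[[k]])
    cat(sprintf("  level %d: %5d x %5d  (%gx)\n", k - 1L, d[2], d[1], 40 / 2^(k - 1)))
  }
  invisible(x)
}

n_levels <- function(slide) length(slide$levels)

#' Read a pyramidal slide from a multipage TIFF
#'
#' Page `k` of the file is level `k`; pages must follow the `2^k` dimension
#' rule (within one pixel of ceiling division). 8-bit RGB.
#'
#' @param path path to a multipage TIFF.
#' @return a [slide_pyramid()].
#' @export
read_pyramid <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  levels <- lapply(pages, function(p) {
    d <- dim(p)
    if (length(d) == 2L) stop("malformed pyramid: page is not RGB")
    if (d[3] > 3L) p <- p[, , 1:3, drop = FALSE]  # drop alpha
    p * 255
  })
  slide_pyramid(levels)
}

#' Write a slide pyramid as a multipage 8-bit RGB TIFF
#'
#' @param slide a [slide_pyramid()].
#' @param path output path.
#' @export
write_pyramid <- function(slide, path) {
  stopifnot(inherits(slide, "slide_pyramid"))
  pages <- lapply(slide$levels, function(l) clip01(round(l) / 255))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Map coordinates between pyramid scales
#'
#' Converts 0-based coordinates from a raster at scale `from_scale`
#' (side = level-0 side / from_scale) to one at `to_scale`, using
#' `floor(p * from_scale / to_scale)`. Exact whenever `to_scale` divides
#' `from_scale * p`; the round trip `map_coords(map_coords(p, 1, s), s, 1)`
#' is within `s - 1` pixels of `p` (quantization bound).
#'
#' @param p numeric vector (or matrix) of 0-based coordinates.
#' @param from_scale,to_scale powers of two.
#' @return mapped coordinates, same shape as `p`.
#' @export
map_coords <- function(p, from_scale, to_scale) {
  assert_pow2_scale(from_scale, "from_scale")
  assert_pow2_scale(to_scale, "to_scale")
  floor(p * from_scale / to_scale)
}

#' Read a square window from a slide level
#'
#' The window is given in level-0 coordinates; the returned raster has side
#' `size / 2^level`. Area outside the slide is filled with white
#' `(255, 255, 255)` — slide background is white glass, and this makes
#' border patches well-defined.
#'
#' @param slide a [slide_pyramid()].
#' @param x,y 0-based level-0 top-left coordinates (may be negative for
#'   windows overhanging the top/left edge).
#' @param size window side in level-0 pixels; must be divisible by `2^level`.
#' @param level pyramid level to read from.
#' @return numeric array `(size/2^level) x (size/2^level) x 3` in `[0, 255]`.
#' @export
read_window <- function(slide, x, y, size, level = 0L) {
  stopifnot(inherits(slide, "slide_pyramid"))
  f <- 2^level
  if (level < 0L || level >= n_levels(slide)) stop("no such level")
  if (size %% f != 0) stop("window size must be divisible by 2^level")
  if (x >= slide$width0 || y >= slide$height0 || x + size <= 0 || y + size <= 0)
    stop("window entirely outside slide")
  side <- size %/% f
  lv <- slide$levels[[level + 1L]]
  sx <- floor(x / f); sy <- floor(y / f)
  out <- array(255, c(side, side, 3L))
  # overlap in level-k pixel indices (0-based)
  x0 <- max(0L, sx); x1 <- min(ncol(lv), sx + side)
  y0 <- max(0L, sy); y1 <- min(nrow(lv), sy + side)
  if (x1 > x0 && y1 > y0) {
    out[(y0 - sy + 1L):(y1 - sy), (x0 - sx + 1L):(x1 - sx), ] <-
      lv[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  }
  out
}

# RGB image of the slide at side = level-0 side / s; uses the stored level
# when present, otherwise mean-pools the deepest available level further.
image_at_scale <- function(slide, s) {
  assert_pow2_scale(s, "scale")
  k <- as.integer(log2(s))
  if (k < n_levels(slide)) return(slide$levels[[k + 1L]])
  img <- slide$levels[[n_levels(slide)]]
  for (i in seq_len(k - n_levels(slide) + 1L)) img <- pool2_rgb(img)
  img
}
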