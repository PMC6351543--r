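#' Tile plans
#'
#' A tile plan is a row-major ordered grid of square windows in level-0
#' coordinates, stored as a data frame with columns `x`, `y` plus attributes
#' `size`, `stride` and `purpose` (`"rough"`, `"dense"` or `"train"`).
#'
#' @param xy data frame with 0-based `x`, `y` columns.
#' @param size window side (level-0 px).
#' @param stride grid step (level-0 px).
#' @param purpose plan purpose.
#' @return object of class `tile_plan`.
#' @export
tile_plan <- function(xy, size, stride, purpose = c("rough", "dense", "train")) {
  purpose <- match.arg(purpose)
  stopifnot(is.data.frame(xy), all(c("x", "y") %in% names(xy)))
  structure(xy[c("x", "y")], size = as.integer(size), stride = as.integer(stride),
            purpose = purpose, class = c("tile_plan", "data.frame"))
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d window(s) of %d px, stride %d, purpose '%s'\n",
              nrow(x), attr(x, "size"), attr(x, "stride"), attr(x, "purpose")))
  invisible(x)
}

# 1-D grid of window origins: multiples of `stride` from 0; when the extent
# minus size is not on the grid, a final origin is added flush with the edge
# (flush = TRUE, rough/training plans) or the grid is extended past the edge
# to the next stride multiple (flush = FALSE, dense plans, keeping origins
# divisible by the stride and hence by 8).
grid_origins <- function(extent, size, stride, flush = TRUE) {
  if (extent <= size) return(0L)
  last <- extent - size
  xs <- seq(0L, last, by = stride)
  if (last %% stride != 0L) {
    xs <- if (flush) c(xs, last) else seq(0L, by = stride, length.out = length(xs) + 1L)
  }
  as.integer(xs)
}

#' Plan the rough classification tiling
#'
#' Grid of 299 x 299 level-0 windows at stride 128 (the rough-heatmap
#' geometry) over the slide extent; a final window is added flush with each
#' edge so no tissue is missed. Windows whose footprint, mapped to the 1.25x
#' tissue mask, contains no foreground are dropped.
#'
#' @param mask tissue [mask_raster()] at scale 32.
#' @param slide_dims `c(width0, height0)` in level-0 px.
#' @param size,stride window side and grid step (level-0 px).
#' @return a [tile_plan()] with purpose `"rough"`, in row-major order.
#' @export
plan_rough_tiles <- function(mask, slide_dims, size = 299L, stride = 128L) {
  stopifnot(inherits(mask, "mask_raster"))
  if (!any(mask$data == 1L)) {
    warning("empty tissue mask: rough plan has no windows")
    return(tile_plan(data.frame(x = integer(0), y = integer(0)), size, stride, "rough"))
  }
  W <- as.integer(slide_dims[1]); H <- as.integer(slide_dims[2])
  xs <- grid_origins(W, size, stride, flush = TRUE)
  ys <- grid_origins(H, size, stride, flush = TRUE)
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # x fastest: row-major
  s <- mask$scale
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    cx0 <- max(0L, grid$x[i] %/% s); cx1 <- min(ncol(mask$data) - 1L, (grid$x[i] + size - 1L) %/% s)
    cy0 <- max(0L, grid$y[i] %/% s); cy1 <- min(nrow(mask$data) - 1L, (grid$y[i] + size - 1L) %/% s)
    if (cx1 < cx0 || cy1 < cy0) return(FALSE)
    any(mask$data[(cy0 + 1L):(cy1 + 1L), (cx0 + 1L):(cx1 + 1L)] == 1L)
  }, logical(1))
  tile_plan(grid[keep, , drop = FALSE], size, stride, "rough")
}

#' Label training patches against the ground truth
#'
#' A patch located in a tumor region is a tumor patch: label `g = 1` iff the
#' window contains at least one ground-truth tumor pixel (configurable to
#' the stricter center-pixel rule).
#'
#' @param plan a [tile_plan()].
#' @param gt ground-truth [mask_raster()] at scale 1.
#' @param rule `"any"` (default, >= 1 tumor pixel) or `"center"`.
#' @return data frame `x`, `y`, `label`.
#' @export
label_patches <- function(plan, gt, rule = c("any", "center")) {
  rule <- match.arg(rule)
  stopifnot(inherits(plan, "tile_plan"), inherits(gt, "mask_raster"), gt$scale == 1L)
  size <- attr(plan, "size")
  H <- nrow(gt$data); W <- ncol(gt$data)
  lab <- vapply(seq_len(nrow(plan)), function(i) {
    x <- plan$x[i]; y <- plan$y[i]
    if (rule == "center") {
      cx <- x + size %/% 2L; cy <- y + size %/% 2L
      if (cx < 0L || cy < 0L || cx >= W || cy >= H) return(0L)
      return(gt$data[cy + 1L, cx + 1L])
    }
    x0 <- max(0L, x); x1 <- min(W - 1L, x + size - 1L)
    y0 <- max(0L, y); y1 <- min(H - 1L, y + size - 1L)
    if (x1 < x0 || y1 < y0) return(0L)
    as.integer(any(gt$data[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] == 1L))
  }, integer(1))
  data.frame(x = plan$x, y = plan$y, label = lab)
}

#' Balance training patches 1:1
#'
#' Keeps all tumor patches and subsamples normal patches without replacement
#' down to the tumor count (seeded). When there are fewer normals than
#' tumors, all normals are kept with a warning — upsampling is not performed.
#'
#' @param patches data frame with a `label` column (from [label_patches()]).
#' @param seed RNG seed for the subsample.
#' @return the balanced subset, tumor rows first, original row order within
#'   each class.
#' @export
balance_1to1 <- function(patches, seed = 1L) {
  stopifnot("label" %in% names(patches))
  tum <- which(patches$label == 1L)
  nor <- which(patches$label == 0L)
  if (length(nor) < length(tum)) {
    warning("fewer normal than tumor patches; keeping all normals")
    sel <- nor
  } else {
    sel <- with_local_seed(seed, sort(sample(nor, length(tum))))
  }
  patches[c(tum, sel), , drop = FALSE]
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_d4 <- function(m, flip, rot) {
  if (flip == "h") m <- m[, ncol(m):1, drop = FALSE]
  if (flip == "v") m <- m[nrow(m):1, , drop = FALSE]
  for (i in seq_len(rot %/% 90L)) m <- rot90cw(m)
  m
}

#' Augment a training patch (and its mask) geometrically and in color
#'
#' Random pick from the d4 subgroup {identity, horizontal flip, vertical
#' flip} x {0, 90, 180, 270 degrees}, applied identically to image and mask,
#' plus mild color jitter (brightness and saturation scales drawn from
#' `jitter_range`) applied to the image only. Seeded and reproducible.
#'
#' @param img numeric array `h x w x 3` in `[0, 255]`.
#' @param mask optional binary matrix of the same height/width.
#' @param seed RNG seed.
#' @param jitter_range range of the brightness/saturation scale factors.
#' @return list `img`, `mask` (NULL when no mask given), `transform`.
#' @export
augment_patch <- function(img, mask = NULL, seed = 1L, jitter_range = c(0.9, 1.1)) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  tr <- with_local_seed(seed, list(
    flip = sample(c("none", "h", "v"), 1L),
    rot = sample(c(0L, 90L, 180L, 270L), 1L),
    brightness = runif(1, jitter_range[1], jitter_range[2]),
    saturation = runif(1, jitter_range[1], jitter_range[2])
  ))
  out <- NULL
  for (c in 1:3) {
    p <- apply_d4(img[, , c], tr$flip, tr$rot)
    if (is.null(out)) out <- array(0, c(nrow(p), ncol(p), 3L))
    out[, , c] <- p
  }
  gray <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3
  for (c in 1:3) out[, , c] <- pmin(255, pmax(0, (gray + tr$saturation * (out[, , c] - gray)) * tr$brightness))
  if (!is.null(mask)) mask <- apply_d4(mask, tr$flip, tr$rot)
  list(img = out, mask = mask, transform = tr)
}
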