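#' Heatmap accumulator
#'
#' Accumulates per-patch predictions into a whole-slide heatmap: the value
#' at a heatmap coordinate is the average of all predictions contributing
#' there, tracked as a running sum raster plus an integer count raster.
#' Cells never predicted finalize to the fill value 0.
#'
#' @param width0,height0 slide dimensions in level-0 px.
#' @param scale heatmap scale: 8 (dense) or 128 (rough).
#' @return object of class `heatmap_accumulator`.
#' @export
heatmap_accumulator <- function(width0, height0, scale) {
  scale <- assert_pow2_scale(scale, "scale")
  h <- ceiling(height0 / scale); w <- ceiling(width0 / scale)
  structure(list(sum = matrix(0, h, w), counts = matrix(0L, h, w), scale = scale),
            class = "heatmap_accumulator")
}

#' Accumulate a dense tile prediction
#'
#' The prediction raster of a tile whose level-0 top-left is `(x, y)` lands
#' at `(x/8, y/8)` in the scale-8 heatmap; overlapping predictions are
#' summed and counted for averaging. Tile origins must be divisible by 8
#' (the tile planners guarantee this); parts of the prediction falling
#' outside the heatmap (overhanging tiles) are ignored.
#'
#' @param acc a scale-8 [heatmap_accumulator()].
#' @param x,y level-0 tile origin, divisible by 8.
#' @param pred `(size/8) x (size/8)` probability matrix.
#' @return the updated accumulator.
#' @export
accumulate_dense <- function(acc, x, y, pred) {
  stopifnot(inherits(acc, "heatmap_accumulator"), is.matrix(pred))
  if (x %% 8L != 0L || y %% 8L != 0L) stop("tile origin must be divisible by 8")
  ox <- x %/% 8L; oy <- y %/% 8L
  h <- nrow(acc$sum); w <- ncol(acc$sum)
  if (ox >= w || oy >= h || ox + ncol(pred) <= 0L || oy + nrow(pred) <= 0L)
    stop("prediction offset out of heatmap bounds")
  rx <- max(0L, ox):(min(w, ox + ncol(pred)) - 1L)
  ry <- max(0L, oy):(min(h, oy + nrow(pred)) - 1L)
  acc$sum[ry + 1L, rx + 1L] <- acc$sum[ry + 1L, rx + 1L] +
    pred[ry - oy + 1L, rx - ox + 1L, drop = FALSE]
  acc$counts[ry + 1L, rx + 1L] <- acc$counts[ry + 1L, rx + 1L] + 1L
  acc
}

#' Accumulate a rough (classifier) prediction
#'
#' A 299 x 299 window at stride 128 contributes one scalar to the scale-128
#' rough heatmap, written at cell `(floor(x/128), floor(y/128))` — one cell
#' per stride-128 window, which yields the 1/128-side rough map; duplicate
#' contributions to a cell are averaged by the same rule as dense stitching.
#'
#' @param acc a scale-128 [heatmap_accumulator()].
#' @param x,y level-0 window origin.
#' @param p scalar probability.
#' @return the updated accumulator.
#' @export
accumulate_rough <- function(acc, x, y, p) {
  stopifnot(inherits(acc, "heatmap_accumulator"), length(p) == 1L, p >= 0, p <= 1)
  cx <- x %/% acc$scale; cy <- y %/% acc$scale
  if (cx < 0L || cy < 0L || cx >= ncol(acc$sum) || cy >= nrow(acc$sum))
    stop("window cell out of heatmap bounds")
  acc$sum[cy + 1L, cx + 1L] <- acc$sum[cy + 1L, cx + 1L] + p
  acc$counts[cy + 1L, cx + 1L] <- acc$counts[cy + 1L, cx + 1L] + 1L
  acc
}

#' Finalize an accumulator into a heatmap
#'
#' Element-wise `sum / n`; cells with `n = 0` get 0. The count raster is
#' retained as provenance.
#'
#' @param acc a [heatmap_accumulator()].
#' @return a [prob_heatmap()].
#' @export
finalize_heatmap <- function(acc) {
  stopifnot(inherits(acc, "heatmap_accumulator"))
  d <- acc$sum / pmax(acc$counts, 1L)
  prob_heatmap(d, acc$scale, acc$counts)
}

#' Ensemble-average heatmaps
#'
#' Element-wise arithmetic mean of heatmaps at the same scale and shape
#' (model ensembling); provenance counts are summed.
#'
#' @param maps list of [prob_heatmap()] objects.
#' @return a [prob_heatmap()].
#' @export
ensemble_average <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  s <- maps[[1]]$scale; d <- dim(maps[[1]]$data)
  for (m in maps) {
    stopifnot(inherits(m, "prob_heatmap"))
    if (m$scale != s || !all(dim(m$data) == d)) stop("heatmaps differ in scale or shape")
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
  cnts <- lapply(maps, `[[`, "counts")
  counts <- if (all(!vapply(cnts, is.null, logical(1)))) Reduce(`+`, cnts) else NULL
  prob_heatmap(avg, s, counts)
}
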