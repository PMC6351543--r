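#' Rough classification pass
#'
#' Runs the classifier over the tissue-restricted 299/128 grid and stitches
#' the scalar predictions into the 1/128-side rough heatmap. Windows are
#' visited in sorted row-major order so results are bit-reproducible.
#'
#' @param slide a [slide_pyramid()].
#' @param tissue tissue [mask_raster()] at scale 32 (see
#'   [compute_tissue_mask()]).
#' @param model a classifier model.
#' @param size,stride rough tiling geometry (level-0 px).
#' @return a [prob_heatmap()] at scale 128.
#' @export
rough_pass <- function(slide, tissue, model, size = 299L, stride = 128L) {
  plan <- plan_rough_tiles(tissue, c(slide$width0, slide$height0), size, stride)
  acc <- heatmap_accumulator(slide$width0, slide$height0, 128L)
  if (nrow(plan)) {
    ord <- order(plan$y, plan$x)
    for (i in ord) {
      p <- predict_rough(model, slide, plan$x[i], plan$y[i], size)
      acc <- accumulate_rough(acc, plan$x[i], plan$y[i], p)
    }
  }
  finalize_heatmap(acc)
}

#' Select candidate tumor regions from the rough heatmap
#'
#' Thresholds the rough heatmap at `thr` (strictly greater; cells exactly at
#' the threshold are excluded).
#'
#' @param rough a scale-128 [prob_heatmap()].
#' @param thr probability threshold (default 0.5).
#' @return a [mask_raster()] at the rough scale (1 = candidate).
#' @export
select_candidates <- function(rough, thr = 0.5) {
  stopifnot(inherits(rough, "prob_heatmap"))
  if (thr < 0 || thr > 1) stop("threshold must be in [0, 1]")
  mask_raster(rough$data > thr, rough$scale)
}

#' Plan the dense segmentation tiling over candidate regions
#'
#' Large test tiles (default 2560 px) on an aligned half-overlap grid
#' (stride = size/2): origins are multiples of the stride starting at 0, and
#' the grid extends to the first origin at or past `extent - size`, so every
#' pixel — and hence every candidate cell — is covered and edge tiles may
#' overhang (read with white fill). Only tiles whose footprint contains at
#' least one candidate cell are kept. Origins are multiples of the stride
#' and therefore of 8, as stitching requires.
#'
#' @param cand candidate [mask_raster()] (scale 128 from
#'   [select_candidates()], or any power-of-two scale).
#' @param slide_dims `c(width0, height0)` in level-0 px.
#' @param size tile side in level-0 px (divisible by 16 so the stride is
#'   divisible by 8).
#' @param stride grid step; default half overlap (`size / 2`).
#' @return a [tile_plan()] with purpose `"dense"`, row-major order.
#' @export
plan_dense_tiles <- function(cand, slide_dims, size = 2560L, stride = size %/% 2L) {
  stopifnot(inherits(cand, "mask_raster"))
  size <- as.integer(size); stride <- as.integer(stride)
  if (stride %% 8L != 0L) stop("dense tile stride must be divisible by 8")
  W <- as.integer(slide_dims[1]); H <- as.integer(slide_dims[2])
  xs <- grid_origins(W, size, stride, flush = FALSE)
  ys <- grid_origins(H, size, stride, flush = FALSE)
  cells <- which(cand$data == 1L, arr.ind = TRUE)
  if (!nrow(cells))
    return(tile_plan(data.frame(x = integer(0), y = integer(0)), size, stride, "dense"))
  cs <- cand$scale
  keep <- matrix(FALSE, length(ys), length(xs))
  # origin o covers cell c iff o <= (c+1)*cs - 1 and o + size > c*cs
  cover_range <- function(c0, origins) {
    lo <- findInterval(c0 * cs - size, origins) + 1L          # first origin > c*cs - size
    hi <- findInterval((c0 + 1L) * cs - 1L, origins)          # last origin <= (c+1)*cs - 1
    c(lo, hi)
  }
  for (i in seq_len(nrow(cells))) {
    rx <- cover_range(cells[i, 2] - 1L, xs)
    ry <- cover_range(cells[i, 1] - 1L, ys)
    if (rx[1] <= rx[2] && ry[1] <= ry[2]) keep[ry[1]:ry[2], rx[1]:rx[2]] <- TRUE
  }
  idx <- which(keep, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])  # row-major
  tile_plan(data.frame(x = xs[idx[ord, 2]], y = ys[idx[ord, 1]]), size, stride, "dense")
}

#' Dense segmentation pass
#'
#' Runs the segmenter(s) over a dense tile plan and stitches the 1/8-scale
#' tile predictions into the 1/8-side whole-slide heatmap by overlap
#' averaging. With several models, per-tile predictions are
#' ensemble-averaged before stitching. Regions never segmented keep 0.
#'
#' @param slide a [slide_pyramid()].
#' @param plan a dense [tile_plan()] (from [plan_dense_tiles()]).
#' @param models a segmenter model or list of segmenter models.
#' @return a [prob_heatmap()] at scale 8.
#' @export
dense_pass <- function(slide, plan, models) {
  stopifnot(inherits(plan, "tile_plan"))
  if (!is.list(models) || inherits(models, "wsi_segmenter")) models <- list(models)
  size <- attr(plan, "size")
  acc <- heatmap_accumulator(slide$width0, slide$height0, 8L)
  if (nrow(plan)) {
    ord <- order(plan$y, plan$x)
    for (i in ord) {
      preds <- lapply(models, predict_dense, slide = slide,
                      x = plan$x[i], y = plan$y[i], size = size)
      pred <- Reduce(`+`, preds) / length(preds)
      acc <- accumulate_dense(acc, plan$x[i], plan$y[i], pred)
    }
  }
  finalize_heatmap(acc)
}

#' Run the full cascade on one slide
#'
#' Tissue mask -> rough classifier heatmap -> candidate selection at `thr`
#' -> dense tiling with half overlap over candidates -> dense segmentation
#' heatmap. Returns all intermediate artifacts plus tiling statistics
#' (including the tile-reduction ratio versus segmenting everywhere, the
#' cascade's efficiency rationale).
#'
#' @param slide a [slide_pyramid()].
#' @param classifier a classifier model.
#' @param segmenters a segmenter model or list of them (ensembled).
#' @param thr candidate threshold on the rough heatmap.
#' @param tile,stride dense tile side and grid step (level-0 px).
#' @param tissue optional precomputed tissue mask.
#' @param verbose log tile counts, reduction ratio and timing.
#' @return list with `tissue`, `rough`, `candidates`, `plan`, `dense`,
#'   `stats`.
#' @export
cascade_segment <- function(slide, classifier, segmenters, thr = 0.5,
                            tile = 2560L, stride = tile %/% 2L,
                            tissue = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(tissue)) tissue <- compute_tissue_mask(slide)
  rough <- rough_pass(slide, tissue, classifier)
  cand <- select_candidates(rough, thr)
  plan <- plan_dense_tiles(cand, c(slide$width0, slide$height0), tile, stride)
  full <- plan_dense_tiles(mask_raster(matrix(1L, nrow(cand$data), ncol(cand$data)),
                                       cand$scale),
                           c(slide$width0, slide$height0), tile, stride)
  dense <- dense_pass(slide, plan, segmenters)
  stats <- list(n_rough = sum(rough$counts > 0), n_dense = nrow(plan),
                n_full = nrow(full),
                reduction = if (nrow(full)) nrow(plan) / nrow(full) else NA_real_,
                elapsed_s = proc.time()[["elapsed"]] - t0)
  if (verbose)
    log_info("cascade: %d rough windows, %d/%d dense tiles (%.1f%% of full grid), %.1f s",
             stats$n_rough, stats$n_dense, stats$n_full, 100 * stats$reduction,
             stats$elapsed_s)
  list(tissue = tissue, rough = rough, candidates = cand, plan = plan,
       dense = dense, stats = stats)
}
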