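#' Pixel confusion counts
#'
#' Two-class (normal = 0, tumor = 1) confusion counts between a predicted
#' and a ground-truth binary raster of the same shape: `counts[i+1, j+1]` is
#' the number of pixels with ground truth `i` and prediction `j`.
#'
#' @param pred,gt binary matrices (or [mask_raster()]s) of equal shape.
#' @return 2 x 2 numeric matrix of counts.
#' @export
confusion_counts <- function(pred, gt) {
  if (inherits(pred, "mask_raster")) pred <- pred$data
  if (inherits(gt, "mask_raster")) gt <- gt$data
  stopifnot(all(dim(pred) == dim(gt)), all(pred %in% c(0, 1)), all(gt %in% c(0, 1)))
  counts <- matrix(0, 2, 2, dimnames = list(gt = c(0, 1), pred = c(0, 1)))
  counts[1, 1] <- sum(gt == 0 & pred == 0)
  counts[1, 2] <- sum(gt == 0 & pred == 1)
  counts[2, 1] <- sum(gt == 1 & pred == 0)
  counts[2, 2] <- sum(gt == 1 & pred == 1)
  counts
}

iou_per_class <- function(counts) {
  vapply(1:2, function(c) {
    denom <- sum(counts[c, ]) + sum(counts[, c]) - counts[c, c]
    if (denom == 0) 1.0 else counts[c, c] / denom  # class absent everywhere: IoU := 1
  }, numeric(1))
}

#' Mean intersection-over-union
#'
#' `IoU_c = p_cc / (sum_j p_cj + sum_j p_jc - p_cc)`; `miou()` averages the
#' normal and tumor IoUs, `tumor_iou()` returns the tumor-class IoU. A class
#' absent from both prediction and truth scores IoU 1, so a normal slide
#' predicted all-normal has mIoU 1.
#'
#' @param counts 2 x 2 confusion matrix from [confusion_counts()].
#' @return scalar in `[0, 1]`.
#' @rdname miou
#' @export
miou <- function(counts) mean(iou_per_class(counts))

#' @rdname miou
#' @export
tumor_iou <- function(counts) iou_per_class(counts)[2]

#' Slide-level ROC AUC
#'
#' AUC of per-slide scores (the maximum heatmap probability in each slide)
#' against slide labels, computed as the Mann-Whitney statistic with
#' midranks for ties (equivalent to the trapezoidal ROC area).
#'
#' @param scores numeric per-slide scores.
#' @param labels 0/1 per-slide labels (1 = tumor).
#' @return AUC in `[0, 1]`.
#' @export
slide_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both tumor and normal slides")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Extract point detections from a heatmap
#'
#' Connected components (8-connected) of `heatmap > thr`; each component
#' yields one detection at its maximum-probability pixel, scored by that
#' maximum — the per-lesion max-probability convention used for FROC.
#'
#' @param hm a [prob_heatmap()].
#' @param thr detection threshold.
#' @return data frame with 0-based heatmap coordinates `x`, `y` and `prob`.
#' @export
heatmap_to_detections <- function(hm, thr = 0.5) {
  stopifnot(inherits(hm, "prob_heatmap"))
  lab <- label_components(hm$data > thr)
  n <- attr(lab, "n")
  if (n == 0L) return(data.frame(x = integer(0), y = integer(0), prob = numeric(0)))
  out <- lapply(seq_len(n), function(k) {
    idx <- which(lab == k)
    best <- idx[which.max(hm$data[idx])]
    h <- nrow(hm$data)
    data.frame(x = (best - 1L) %/% h, y = (best - 1L) %% h, prob = max(hm$data[idx]))
  })
  do.call(rbind, out)
}

#' Lesion-level FROC score
#'
#' Free-response ROC over a cohort: lesions are the 8-connected components
#' of each slide's ground-truth tumor mask at heatmap scale; a lesion counts
#' as detected at threshold `t` when at least one detection with probability
#' `>= t` falls inside it, and detections inside no lesion are false
#' positives. Sweeping all distinct detection scores gives the
#' sensitivity vs. average-FP-per-slide curve; the FROC score is the mean
#' sensitivity at the stated FP rates (Camelyon convention
#' `{0.25, 0.5, 1, 2, 4, 8}`), linearly interpolating the curve and clamping
#' beyond its ends.
#'
#' @param per_slide list of slides; each a list with `gt` (binary lesion
#'   mask at heatmap scale, matrix or [mask_raster()]) and `detections`
#'   (data frame `x`, `y`, `prob` at the same scale). Normal slides have an
#'   all-zero `gt`.
#' @param fp_rates average false positives per slide at which sensitivity
#'   is read off.
#' @return list with `score`, `sensitivities` at `fp_rates`, and the full
#'   `curve` (data frame `threshold`, `fp_per_slide`, `sensitivity`).
#' @export
froc <- function(per_slide, fp_rates = c(0.25, 0.5, 1, 2, 4, 8)) {
  stopifnot(is.list(per_slide), length(per_slide) >= 1L)
  n_slides <- length(per_slide)
  lesion_scores <- numeric(0)   # best detection prob per lesion (-Inf = missed)
  fp_scores <- numeric(0)       # probs of detections inside no lesion
  for (sl in per_slide) {
    g <- if (inherits(sl$gt, "mask_raster")) sl$gt$data else sl$gt
    lab <- label_components(g)
    nles <- attr(lab, "n")
    det <- sl$detections
    hit <- if (nrow(det)) lab[cbind(det$y + 1L, det$x + 1L)] else integer(0)
    if (nles > 0L) {
      best <- rep(-Inf, nles)
      for (i in seq_along(hit)) if (hit[i] > 0L) best[hit[i]] <- max(best[hit[i]], det$prob[i])
      lesion_scores <- c(lesion_scores, best)
    }
    fp_scores <- c(fp_scores, det$prob[hit == 0L])
  }
  if (!length(lesion_scores)) stop("FROC undefined: cohort contains no lesions")
  thr <- sort(unique(c(lesion_scores[is.finite(lesion_scores)], fp_scores)),
              decreasing = TRUE)
  if (!length(thr)) thr <- 1  # no detections at all
  sens <- vapply(thr, function(t) mean(lesion_scores >= t), numeric(1))
  fps <- vapply(thr, function(t) sum(fp_scores >= t) / n_slides, numeric(1))
  s_at <- if (length(unique(fps)) < 2L) {
    rep(max(sens), length(fp_rates))  # vertical curve (e.g. zero FPs throughout)
  } else {
    stats::approx(x = fps, y = sens, xout = fp_rates, method = "linear",
                  rule = 2, ties = max)$y
  }
  list(score = mean(s_at), sensitivities = stats::setNames(s_at, fp_rates),
       curve = data.frame(threshold = thr, fp_per_slide = fps, sensitivity = sens))
}

#' Bootstrap percentile confidence interval over slides
#'
#' Resamples slides with replacement (same size as the original cohort),
#' recomputes the metric on each resample, and reports the 2.5% and 97.5%
#' percentiles over `B` replicates (seeded).
#'
#' @param metric_fn function taking a list of slide-level records and
#'   returning a scalar.
#' @param data list of slide-level records.
#' @param B number of bootstrap replicates (2000 by convention).
#' @param seed RNG seed.
#' @param probs percentiles to report.
#' @return named numeric vector of percentiles, with attribute `replicates`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 2000L, seed = 1L,
                         probs = c(0.025, 0.975)) {
  stopifnot(is.function(metric_fn), is.list(data), length(data) >= 1L)
  n <- length(data)
  reps <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      # a resample can be degenerate for some metrics (e.g. one-class AUC)
      tryCatch(as.numeric(metric_fn(data[idx])), error = function(e) NA_real_)
    }, numeric(1))
  })
  ci <- stats::quantile(reps, probs, na.rm = TRUE)
  attr(ci, "replicates") <- reps
  ci
}

#' Evaluate a cohort of heatmaps against ground truth
#'
#' Computes the four headline metrics of the pipeline: slide-level AUC from
#' per-slide maximum heatmap probability, lesion-level FROC from per-lesion
#' maximum probabilities, and mIoU / Tumor-mIoU from the heatmap binarized
#' at `thr` against the ground truth at heatmap scale. mIoU is the mean of
#' per-slide mIoU over all slides; Tumor-mIoU is the mean tumor-class IoU
#' over tumor slides.
#'
#' @param slides list of records, each with `heatmap` (a [prob_heatmap()]),
#'   `gt` (binary mask at heatmap scale), and `label` (1 = tumor slide).
#' @param thr binarization / detection threshold.
#' @param fp_rates FROC FP rates.
#' @return list with `auc`, `froc`, `miou`, `tumor_miou`, and a per-slide
#'   data frame `per_slide`.
#' @export
evaluate_cohort <- function(slides, thr = 0.5, fp_rates = c(0.25, 0.5, 1, 2, 4, 8)) {
  stopifnot(is.list(slides), length(slides) >= 1L)
  rows <- lapply(seq_along(slides), function(i) {
    sl <- slides[[i]]
    g <- if (inherits(sl$gt, "mask_raster")) sl$gt$data else sl$gt
    cc <- confusion_counts(sl$heatmap$data > thr, g)
    data.frame(slide = i, label = sl$label, score = max(sl$heatmap$data),
               miou = miou(cc), tumor_iou = tumor_iou(cc))
  })
  tab <- do.call(rbind, rows)
  froc_in <- lapply(slides, function(sl) list(
    gt = if (inherits(sl$gt, "mask_raster")) sl$gt$data else sl$gt,
    detections = heatmap_to_detections(sl$heatmap, thr)))
  # AUC is undefined for one-class cohorts and FROC for lesion-free cohorts;
  # report NA (with a warning) rather than failing the whole evaluation
  soft <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })
  list(auc = soft(slide_auc(tab$score, tab$label)),
       froc = soft(froc(froc_in, fp_rates)$score),
       miou = mean(tab$miou),
       tumor_miou = mean(tab$tumor_iou[tab$label == 1]),
       per_slide = tab)
}
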