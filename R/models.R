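#' Model contracts
#'
#' The cascade is model-agnostic. A *classifier* maps a 299 x 299 RGB patch
#' to a single tumor probability; a *segmenter* maps an `L x L` patch
#' (`L` divisible by 8) to an `(L/8) x (L/8)` probability raster — the
#' dense model's output is downsampled with a 1/8 sampling rate. Any
#' function with that signature can be wrapped; trained deep networks are
#' deliberately out of scope, and seeded oracle models backed by the ground
#' truth make every stage testable.
#'
#' `predict_rough()` / `predict_dense()` run one model on one window;
#' models that declare `needs_pixels = FALSE` (the oracles) are scored from
#' the window coordinates alone and skip the pixel read.
#'
#' @param fn prediction function: `function(patch)` returning a probability
#'   (classifier) or a probability raster of side `L/8` (segmenter), where
#'   `patch` is an `L x L x 3` array in `[0, 255]`.
#' @return a model object usable by [rough_pass()] / [dense_pass()].
#' @rdname model_contract
#' @export
classifier_model <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, needs_pixels = TRUE),
            class = c("fn_classifier", "wsi_classifier"))
}

#' @rdname model_contract
#' @export
segmenter_model <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, needs_pixels = TRUE),
            class = c("fn_segmenter", "wsi_segmenter"))
}

needs_pixels <- function(model) isTRUE(model$needs_pixels)

#' Oracle models backed by the ground truth
#'
#' Test doubles that satisfy the model contracts from the level-0 ground
#' truth instead of pixels. The oracle classifier scores a window as
#' `clip01(I[window contains a tumor pixel] + N(0, noise_sd))`; with
#' `noise_sd = 0` it reproduces [label_patches()] labels exactly. The oracle
#' segmenter samples the ground truth at the window's stride-8 lattice,
#' flips each lattice value independently with probability `flip_rate`, and
#' maps the result to probabilities (`prob_neg = 0.1`, `prob_pos = 0.9`), so
#' the zero-flip oracle reproduces the lattice-sampled ground truth exactly
#' after binarization at 0.5. Noise is keyed on (seed, window), so
#' predictions are deterministic and independent of evaluation order.
#'
#' @param gt ground-truth [mask_raster()] at scale 1.
#' @param noise_sd standard deviation of additive Gaussian score noise.
#' @param flip_rate per-lattice-pixel label flip probability.
#' @param seed base RNG seed.
#' @param prob_pos,prob_neg probabilities emitted for (possibly flipped)
#'   tumor / normal lattice pixels.
#' @rdname oracle_models
#' @export
oracle_classifier <- function(gt, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(gt, "mask_raster"), gt$scale == 1L, noise_sd >= 0)
  structure(list(gt = gt, noise_sd = noise_sd, seed = as.integer(seed),
                 needs_pixels = FALSE),
            class = c("oracle_classifier", "wsi_classifier"))
}

#' @rdname oracle_models
#' @export
oracle_segmenter <- function(gt, flip_rate = 0, seed = 1L,
                             prob_pos = 0.9, prob_neg = 0.1) {
  stopifnot(inherits(gt, "mask_raster"), gt$scale == 1L,
            flip_rate >= 0, flip_rate <= 1)
  structure(list(gt = gt, flip_rate = flip_rate, seed = as.integer(seed),
                 prob_pos = prob_pos, prob_neg = prob_neg, needs_pixels = FALSE),
            class = c("oracle_segmenter", "wsi_segmenter"))
}

# any ground-truth tumor pixel inside the (clipped) window?
window_has_tumor <- function(gt, x, y, size) {
  H <- nrow(gt$data); W <- ncol(gt$data)
  x0 <- max(0L, x); x1 <- min(W - 1L, x + size - 1L)
  y0 <- max(0L, y); y1 <- min(H - 1L, y + size - 1L)
  if (x1 < x0 || y1 < y0) return(FALSE)
  any(gt$data[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] == 1L)
}

# gt values at the window's stride-8 lattice (0 outside the slide)
gt_lattice <- function(gt, x, y, size) {
  side <- size %/% 8L
  H <- nrow(gt$data); W <- ncol(gt$data)
  xs <- x + 8L * (0:(side - 1L)); ys <- y + 8L * (0:(side - 1L))
  vx <- xs >= 0L & xs < W; vy <- ys >= 0L & ys < H
  out <- matrix(0L, side, side)
  if (any(vx) && any(vy)) out[vy, vx] <- gt$data[ys[vy] + 1L, xs[vx] + 1L, drop = FALSE]
  out
}

#' Run a classifier on one window
#'
#' @param model a classifier model.
#' @param slide a [slide_pyramid()] (pixels are read only for models that
#'   need them).
#' @param x,y,size window in level-0 coordinates.
#' @return tumor probability in `[0, 1]`.
#' @export
predict_rough <- function(model, slide, x, y, size = 299L) {
  UseMethod("predict_rough")
}

#' @export
predict_rough.fn_classifier <- function(model, slide, x, y, size = 299L) {
  p <- model$fn(read_window(slide, x, y, size))
  stopifnot(length(p) == 1L, p >= 0, p <= 1)
  as.numeric(p)
}

#' @export
predict_rough.oracle_classifier <- function(model, slide, x, y, size = 299L) {
  ind <- as.numeric(window_has_tumor(model$gt, x, y, size))
  if (model$noise_sd == 0) return(ind)
  with_local_seed(window_seed(model$seed, x, y),
                  clip01(ind + stats::rnorm(1, 0, model$noise_sd)))
}

#' Run a segmenter on one window
#'
#' @inheritParams predict_rough
#' @param size window side, divisible by 8.
#' @return `(size/8) x (size/8)` probability raster.
#' @export
predict_dense <- function(model, slide, x, y, size) {
  UseMethod("predict_dense")
}

#' @export
predict_dense.fn_segmenter <- function(model, slide, x, y, size) {
  if (size %% 8L != 0L) stop("segmenter input side must be divisible by 8")
  p <- model$fn(read_window(slide, x, y, size))
  stopifnot(is.matrix(p), all(dim(p) == size %/% 8L), all(p >= 0), all(p <= 1))
  p
}

#' @export
predict_dense.oracle_segmenter <- function(model, slide, x, y, size) {
  if (size %% 8L != 0L) stop("segmenter input side must be divisible by 8")
  g <- gt_lattice(model$gt, x, y, size)
  if (model$flip_rate > 0) {
    flip <- with_local_seed(window_seed(model$seed, x, y),
                            matrix(stats::runif(length(g)) < model$flip_rate, nrow(g)))
    g <- ifelse(flip, 1L - g, g)
  }
  ifelse(g == 1L, model$prob_pos, model$prob_neg)
}

#' Training losses
#'
#' `pixel_loss()` is the dense model's training loss: binary cross-entropy
#' between the `(L/8) x (L/8)` predicted probabilities and the level-0
#' binary mask sampled at the stride-8 lattice (`m(8x, 8y)`, nearest value,
#' no averaging), normalized by the number of output pixels `(L/8)^2`.
#' `patch_loss()` is the classifier's loss: mean binary cross-entropy of
#' patch probabilities against patch labels. Probabilities are clipped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param p predicted probabilities: an `(L/8) x (L/8)` matrix
#'   (`pixel_loss`) or a vector (`patch_loss`).
#' @param m level-0 binary mask, `L x L` (tumor = 1).
#' @param g patch labels in `{0, 1}`.
#' @param eps clipping constant.
#' @return non-negative scalar loss.
#' @rdname losses
#' @export
pixel_loss <- function(p, m, eps = 1e-7) {
  stopifnot(is.matrix(p), is.matrix(m))
  L <- nrow(m)
  if (ncol(m) != L) stop("mask must be square")
  if (L %% 8L != 0L) stop("patch side L must be divisible by 8")
  if (!all(dim(p) == L %/% 8L)) stop("prediction must be (L/8) x (L/8)")
  if (!all(m %in% c(0, 1))) stop("mask values must be 0 or 1")
  ms <- m[seq(1L, L, 8L), seq(1L, L, 8L), drop = FALSE]
  pc <- pmin(1 - eps, pmax(eps, p))
  -mean(ms * log(pc) + (1 - ms) * log(1 - pc))
}

#' @rdname losses
#' @export
patch_loss <- function(p, g, eps = 1e-7) {
  stopifnot(length(p) == length(g), length(p) >= 1L, all(g %in% c(0, 1)))
  pc <- pmin(1 - eps, pmax(eps, p))
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}
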