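#' Specification for a synthetic pyramidal slide
#'
#' The generator emulates the structure the pipeline relies on in real
#' scans: white glass background, colored (high-saturation) tissue regions
#' separable on the HSV S channel, and smooth tumor blobs inside tissue
#' with a level-0 ground-truth mask. Tissue is a union of random ellipses
#' hitting a target area fraction; tumor blobs are harmonically perturbed
#' disks (smooth closed shapes) clipped to tissue. The pyramid is built by
#' exact 2x mean pooling down to a side of at least 64 px.
#'
#' @param width0,height0 level-0 dimensions (px).
#' @param tissue_fraction target tissue area fraction (matched within
#'   0.03).
#' @param n_tumor_blobs number of tumor blobs (0 for a normal slide).
#' @param blob_radius range of blob base radii (level-0 px).
#' @param n_tissue_regions number of tissue ellipses.
#' @param seed RNG seed; the slide and mask are bit-reproducible from it.
#' @param noise_sd per-channel Gaussian color noise (8-bit units).
#' @param colors list with `background`, `tissue`, `tumor` RGB triplets in
#'   `[0, 255]`; defaults are white glass, saturated pink tissue and
#'   purple tumor (hematoxylin-eosin-like).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(width0 = 4096L, height0 = 4096L, tissue_fraction = 0.25,
                       n_tumor_blobs = 2L, blob_radius = c(150, 400),
                       n_tissue_regions = 2L, seed = 1L, noise_sd = 6,
                       colors = list(background = c(250, 250, 250),
                                     tissue = c(232, 150, 183),
                                     tumor = c(148, 94, 172))) {
  stopifnot(width0 >= 64, height0 >= 64,
            tissue_fraction > 0, tissue_fraction <= 0.9,
            n_tumor_blobs >= 0, length(blob_radius) == 2L,
            blob_radius[1] <= blob_radius[2], n_tissue_regions >= 1L)
  if (n_tumor_blobs > 0 && 2 * blob_radius[2] > min(width0, height0))
    stop("infeasible spec: tumor blob diameter exceeds the slide")
  structure(list(width0 = as.integer(width0), height0 = as.integer(height0),
                 tissue_fraction = tissue_fraction,
                 n_tumor_blobs = as.integer(n_tumor_blobs),
                 blob_radius = blob_radius,
                 n_tissue_regions = as.integer(n_tissue_regions),
                 seed = as.integer(seed), noise_sd = noise_sd, colors = colors),
            class = "synth_spec")
}

# paint an ellipse (center cx,cy, semi-axes a,b, angle th) into logical matrix m
paint_ellipse <- function(m, cx, cy, a, b, th) {
  H <- nrow(m); W <- ncol(m)
  r <- max(a, b)
  x0 <- max(0L, floor(cx - r)); x1 <- min(W - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(H - 1L, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(m)
  xs <- x0:x1; ys <- y0:y1
  dx <- xs - cx; dy <- ys - cy
  ct <- cos(th); st <- sin(th)
  u <- outer(dy * st, dx * ct, "+") / a   # rows = y, cols = x
  v <- outer(dy * ct, -dx * st, "+") / b
  m[ys + 1L, xs + 1L] <- m[ys + 1L, xs + 1L] | (u^2 + v^2 <= 1)
  m
}

# smooth blob: polar radius r0 * (1 + sum_k a_k cos(k t + ph_k)), k = 2..4
paint_blob <- function(m, cx, cy, r0, amp, ph) {
  H <- nrow(m); W <- ncol(m)
  rmax <- r0 * (1 + sum(abs(amp)))
  x0 <- max(0L, floor(cx - rmax)); x1 <- min(W - 1L, ceiling(cx + rmax))
  y0 <- max(0L, floor(cy - rmax)); y1 <- min(H - 1L, ceiling(cy + rmax))
  if (x1 < x0 || y1 < y0) return(m)
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, length(ys), length(xs))
  d <- sqrt(dx^2 + dy^2)
  t <- atan2(dy, dx)
  rb <- r0 * (1 + amp[1] * cos(2 * t + ph[1]) + amp[2] * cos(3 * t + ph[2]) +
                amp[3] * cos(4 * t + ph[3]))
  m[ys + 1L, xs + 1L] <- m[ys + 1L, xs + 1L] | (d <= rb)
  m
}

#' Generate a synthetic pyramidal slide with ground truth
#'
#' Draws the tissue and tumor geometry from the seeded spec, renders the
#' level-0 RGB image (region colors plus Gaussian color noise, clipped to
#' 8-bit), and builds the pyramid by exact 2x mean pooling. The achieved
#' tissue fraction is matched to the target within 0.03 by rescaling the
#' ellipses; tumor blobs are clipped to tissue so the ground truth is
#' always inside tissue.
#'
#' @param spec a [synth_spec()].
#' @return list with `slide` ([slide_pyramid()]), `gt` (level-0
#'   [mask_raster()], tumor = 1) and `meta` (achieved tissue/tumor
#'   fractions, blob centers and radii, seed).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  W <- spec$width0; H <- spec$height0
  with_local_seed(spec$seed, {
    k <- spec$n_tissue_regions
    target <- spec$tissue_fraction
    area_each <- target * W * H / k
    centers <- cbind(stats::runif(k, 0.25 * W, 0.75 * W),
                     stats::runif(k, 0.25 * H, 0.75 * H))
    ratio <- stats::runif(k, 0.6, 1)
    angle <- stats::runif(k, 0, pi)
    a <- sqrt(area_each / (pi * ratio))   # semi-axes: pi * a * b = area_each
    b <- a * ratio
    tissue <- NULL
    for (it in 1:8) {
      tissue <- matrix(FALSE, H, W)
      for (i in seq_len(k))
        tissue <- paint_ellipse(tissue, centers[i, 1], centers[i, 2], a[i], b[i], angle[i])
      got <- mean(tissue)
      if (abs(got - target) <= 0.025) break
      adj <- sqrt(target / max(got, 1e-6))
      a <- a * adj; b <- b * adj
    }
    # tumor blobs: centers at tissue pixels (coarse grid sample), clipped to tissue
    gt <- matrix(FALSE, H, W)
    blobs <- NULL
    if (spec$n_tumor_blobs > 0L) {
      step <- 16L
      ty <- seq(1L, H, step); tx <- seq(1L, W, step)
      sub <- tissue[ty, tx, drop = FALSE]
      cand <- which(sub, arr.ind = TRUE)
      if (!nrow(cand)) stop("infeasible spec: no tissue to place tumor blobs in")
      pick <- cand[sample.int(nrow(cand), spec$n_tumor_blobs,
                              replace = nrow(cand) < spec$n_tumor_blobs), , drop = FALSE]
      r0 <- stats::runif(spec$n_tumor_blobs, spec$blob_radius[1], spec$blob_radius[2])
      blobs <- data.frame(cx = tx[pick[, 2]] - 1L, cy = ty[pick[, 1]] - 1L, r = r0)
      for (i in seq_len(spec$n_tumor_blobs)) {
        amp <- stats::runif(3, 0, 0.15) / (1:3)
        ph <- stats::runif(3, 0, 2 * pi)
        gt <- paint_blob(gt, blobs$cx[i], blobs$cy[i], blobs$r[i], amp, ph)
      }
      gt <- gt & tissue
      if (!any(gt)) stop("infeasible spec: tumor blobs fell outside tissue")
    }
    # render level 0
    img <- array(0, c(H, W, 3L))
    for (c in 1:3) {
      ch <- matrix(spec$colors$background[c], H, W)
      ch[tissue] <- spec$colors$tissue[c]
      ch[gt] <- spec$colors$tumor[c]
      if (spec$noise_sd > 0) ch <- ch + stats::rnorm(H * W, 0, spec$noise_sd)
      img[, , c] <- round(pmin(255, pmax(0, ch)))
    }
    levels <- list(img)
    while (min(dim(levels[[length(levels)]])[1:2]) >= 128)
      levels[[length(levels) + 1L]] <- pool2_rgb(levels[[length(levels)]])
    list(slide = slide_pyramid(levels),
         gt = mask_raster(gt, 1L),
         meta = list(tissue_fraction = mean(tissue), tumor_fraction = mean(gt),
                     blobs = blobs, seed = spec$seed))
  })
}

#' Generate a seeded cohort of synthetic slides
#'
#' Emulates a test cohort of tumor and normal slides. Per-slide specs carry
#' disjoint seeds derived from the cohort seed, so slides are reproducible
#' and independent; slides are *not* generated here — call
#' [generate_slide()] per entry to keep memory bounded.
#'
#' @param n_tumor,n_normal cohort composition.
#' @param template a [synth_spec()] used for every slide (normal slides get
#'   `n_tumor_blobs = 0`).
#' @param seed cohort seed.
#' @return data frame with columns `id`, `label` (1 = tumor), `seed`, and a
#'   list-column `spec` of per-slide [synth_spec()]s.
#' @export
make_cohort <- function(n_tumor, n_normal, template = synth_spec(), seed = 1L) {
  stopifnot(inherits(template, "synth_spec"), n_tumor + n_normal >= 1L)
  n <- n_tumor + n_normal
  seeds <- with_local_seed(seed, sample.int(2147483646L, n))
  labels <- rep(c(1L, 0L), c(n_tumor, n_normal))
  specs <- lapply(seq_len(n), function(i) {
    sp <- template
    sp$seed <- seeds[i]
    if (labels[i] == 0L) sp$n_tumor_blobs <- 0L
    sp
  })
  out <- data.frame(id = seq_len(n), label = labels, seed = seeds)
  out$spec <- specs
  out
}
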