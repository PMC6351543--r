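# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (explicit loops, no shared code paths).

# Otsu: explicit loop over all 256 thresholds, smallest maximizer wins.
brute_otsu <- function(hist) {
  n <- sum(hist)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    w0 <- sum(hist[1:(t + 1)])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(hist[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(hist[(t + 2):256] * ((t + 1):255)) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# losses: explicit double loops
brute_pixel_loss <- function(p, m, eps = 1e-7) {
  L <- nrow(m); s <- L / 8
  total <- 0
  for (x in 0:(s - 1)) for (y in 0:(s - 1)) {
    pv <- min(1 - eps, max(eps, p[y + 1, x + 1]))
    mv <- m[8 * y + 1, 8 * x + 1]
    total <- total + mv * log(pv) + (1 - mv) * log(1 - pv)
  }
  -total / s^2
}

brute_patch_loss <- function(p, g, eps = 1e-7) {
  total <- 0
  for (i in seq_along(p)) {
    pv <- min(1 - eps, max(eps, p[i]))
    total <- total + g[i] * log(pv) + (1 - g[i]) * log(1 - pv)
  }
  -total / length(p)
}

# stitching: for every heatmap pixel, enumerate all covering patches and average
brute_stitch <- function(xs, ys, preds, W, H) {
  hw <- ceiling(W / 8); hh <- ceiling(H / 8)
  out <- matrix(0, hh, hw)
  for (py in 0:(hh - 1)) for (px in 0:(hw - 1)) {
    vals <- c()
    for (i in seq_along(xs)) {
      ox <- xs[i] / 8; oy <- ys[i] / 8
      side <- nrow(preds[[i]])
      if (px >= ox && px < ox + side && py >= oy && py < oy + side)
        vals <- c(vals, preds[[i]][py - oy + 1, px - ox + 1])
    }
    if (length(vals)) {
      s <- 0
      for (v in vals) s <- s + v  # plain double accumulation, patch order
      out[py + 1, px + 1] <- s / length(vals)
    }
  }
  out
}

# connected components by BFS
bfs_components <- function(bin, conn = 8) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  nb <- if (conn == 8) expand.grid(dy = -1:1, dx = -1:1) else data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
  k <- 0L
  for (col in 1:w) for (row in 1:h) {
    if (bin[row, col] != 0 && lab[row, col] == 0L) {
      k <- k + 1L
      queue <- list(c(row, col)); lab[row, col] <- k
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (j in seq_len(nrow(nb))) {
          r <- cur[1] + nb$dy[j]; c2 <- cur[2] + nb$dx[j]
          if (r >= 1 && r <= h && c2 >= 1 && c2 <= w && bin[r, c2] != 0 && lab[r, c2] == 0L) {
            lab[r, c2] <- k
            queue[[length(queue) + 1]] <- c(r, c2)
          }
        }
      }
    }
  }
  attr(lab, "n") <- k
  lab
}

# per-pixel IoU counting oracle
brute_miou <- function(pred, gt) {
  ious <- c()
  for (cls in 0:1) {
    inter <- 0; uni <- 0
    for (i in seq_along(pred)) {
      p <- pred[i] == cls; g <- gt[i] == cls
      if (p && g) inter <- inter + 1
      if (p || g) uni <- uni + 1
    }
    ious <- c(ious, if (uni == 0) 1 else inter / uni)
  }
  mean(ious)
}

# FROC oracle: explicit sweep over all distinct detection scores
brute_froc <- function(per_slide, fp_rates = c(0.25, 0.5, 1, 2, 4, 8)) {
  n_slides <- length(per_slide)
  all_scores <- c()
  recs <- list()
  n_lesions <- 0
  for (sl in per_slide) {
    lab <- bfs_components(sl$gt)
    n_lesions <- n_lesions + attr(lab, "n")
    det <- sl$detections
    inside <- integer(nrow(det))
    for (i in seq_len(nrow(det))) inside[i] <- lab[det$y[i] + 1, det$x[i] + 1]
    recs[[length(recs) + 1]] <- list(lab = lab, det = det, inside = inside,
                                     nles = attr(lab, "n"))
    all_scores <- c(all_scores, det$prob)
  }
  thr <- sort(unique(all_scores), decreasing = TRUE)
  if (!length(thr)) thr <- 1
  sens <- fps <- numeric(length(thr))
  for (ti in seq_along(thr)) {
    t <- thr[ti]; hit <- 0; fp <- 0
    for (r in recs) {
      det_ok <- which(r$det$prob >= t)
      for (k in seq_len(r$nles)) {
        if (any(r$inside[det_ok] == k)) hit <- hit + 1
      }
      fp <- fp + sum(r$inside[det_ok] == 0)
    }
    sens[ti] <- hit / n_lesions
    fps[ti] <- fp / n_slides
  }
  s_at <- numeric(length(fp_rates))
  for (i in seq_along(fp_rates)) {
    xo <- fp_rates[i]
    if (length(unique(fps)) < 2) { s_at[i] <- max(sens); next }
    if (xo <= min(fps)) { s_at[i] <- max(sens[fps == min(fps)]); next }
    if (xo >= max(fps)) { s_at[i] <- max(sens[fps == max(fps)]); next }
    lo <- max(which(fps <= xo)); hi <- min(which(fps >= xo))
    x1 <- fps[lo]; x2 <- fps[hi]
    y1 <- max(sens[fps == x1]); y2 <- max(sens[fps == x2])
    s_at[i] <- if (x1 == x2) y2 else y1 + (y2 - y1) * (xo - x1) / (x2 - x1)
  }
  list(score = mean(s_at), sensitivities = s_at,
       curve = data.frame(threshold = thr, fp_per_slide = fps, sensitivity = sens))
}

# small random fixtures
random_mask <- function(h, w, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(as.integer(runif(h * w) < p), h, w)
}

# tiny test pyramid from a level-0 RGB array via exact 2x mean pooling
tiny_pyramid <- function(img, n_levels = 3) {
  levels <- list(img)
  for (k in seq_len(n_levels - 1)) {
    prev <- levels[[k]]
    h <- dim(prev)[1]; w <- dim(prev)[2]
    h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
    nxt <- array(0, c(h2, w2, 3))
    for (c in 1:3) for (i in 1:h2) for (j in 1:w2) {
      rows <- (2 * i - 1):min(2 * i, h); cols <- (2 * j - 1):min(2 * j, w)
      nxt[i, j, c] <- mean(prev[rows, cols, c])
    }
    levels[[k + 1]] <- nxt
  }
  slide_pyramid(levels)
}
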