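#' Convert an RGB raster to 8-bit HSV channels
#'
#' Tissue preselection thresholds the saturation channel, so the conversion
#' keeps an exact 256-bin integerization: `S = round(255 * (max - min) / max)`
#' with `S = 0` where `max = 0` (and for any gray pixel, `R = G = B`),
#' `V = max`, and hue scaled from degrees to `round(255 * h / 360)`.
#'
#' @param img numeric array `h x w x 3` with values in `[0, 255]`.
#' @return list of integer matrices `H`, `S`, `V`, each in `[0, 255]`.
#' @export
rgb_to_hsv_channels <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- matrix(img[, , 1], h, w); g <- matrix(img[, , 2], h, w)
  b <- matrix(img[, , 3], h, w)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  S <- matrix(0L, nrow(mx), ncol(mx))
  nz <- mx > 0
  S[nz] <- as.integer(round(255 * d[nz] / mx[nz]))
  V <- matrix(as.integer(round(mx)), nrow(mx))
  # hue in degrees, 0 where d == 0
  h <- matrix(0, nrow(mx), ncol(mx))
  i <- d > 0 & mx == r
  h[i] <- (60 * ((g[i] - b[i]) / d[i])) %% 360
  i <- d > 0 & mx == g & mx != r
  h[i] <- 60 * ((b[i] - r[i]) / d[i]) + 120
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * ((r[i] - g[i]) / d[i]) + 240
  H <- matrix(as.integer(round(255 * h / 360)), nrow(mx))
  list(H = H, S = S, V = V)
}

#' Otsu threshold of a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance
#' `sigma_b^2(t) = w0 * w1 * (mu0 - mu1)^2` over all candidate thresholds,
#' where class 0 is bins `<= t`. Ties are broken by the smallest `t`
#' (determinism).
#'
#' @param hist numeric vector of 256 non-negative bin counts (bin `i`
#'   corresponds to value `i - 1`).
#' @return list with `threshold` (integer in `[0, 255]`) and
#'   `between_class_variance`.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(length(hist) == 256L, all(hist >= 0))
  n <- sum(hist)
  if (n <= 0) stop("degenerate histogram: empty")
  if (sum(hist > 0) < 2L) stop("degenerate histogram: all mass in one bin")
  v <- 0:255
  w0 <- cumsum(hist)                # count in class 0 for t = 0..255
  s0 <- cumsum(hist * v)            # value sum in class 0
  w1 <- n - w0
  s1 <- sum(hist * v) - s0
  ok <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, 256)
  sb[ok] <- (w0[ok] / n) * (w1[ok] / n) * (s0[ok] / w0[ok] - s1[ok] / w1[ok])^2
  t <- which.max(sb) - 1L           # which.max takes the first (smallest t) on ties
  list(threshold = t, between_class_variance = sb[t + 1L])
}

value_histogram <- function(values256) {
  tabulate(as.integer(values256) + 1L, nbins = 256L)
}

#' Compute the tissue foreground mask at 1.25x
#'
#' Reads the slide at 1.25x magnification (level-0 side / 32; level 5 when
#' the pyramid stores it, otherwise the deepest stored level mean-pooled
#' down), converts to HSV, Otsu-thresholds the saturation channel, and marks
#' pixels with `S > t` as tissue foreground. Tissue is colored (high
#' saturation) while glass background is near-gray, so foreground is the
#' high-S side. Foreground positions map back to level 0 via
#' `map_coords(p, 32, 1)` for patch extraction.
#'
#' @param slide a [slide_pyramid()].
#' @param channel HSV channel to threshold; the pipeline uses `"S"`, which
#'   separates tissue best, but `"H"` and `"V"` share the same Otsu core for
#'   comparison.
#' @return a [mask_raster()] at scale 32 (foreground = 1).
#' @export
compute_tissue_mask <- function(slide, channel = c("S", "H", "V")) {
  channel <- match.arg(channel)
  img <- image_at_scale(slide, 32L)
  ch <- rgb_to_hsv_channels(round(img))[[channel]]
  ot <- otsu_threshold(value_histogram(ch))
  mask_raster(ch > ot$threshold, 32L)
}
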