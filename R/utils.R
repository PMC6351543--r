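# internal helpers shared across modules

is_pow2 <- function(x) {
  length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x) &&
    bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

assert_pow2_scale <- function(x, what = "scale") {
  if (!is_pow2(x)) stop(sprintf("%s must be a power of two, got %s", what, format(x)), call. = FALSE)
  invisible(as.integer(x))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  code
}

# Deterministic per-window seed so oracle-model noise depends only on (model seed, window),
# never on prediction order. Kept below 2^31 - 1.
window_seed <- function(seed, x, y) {
  as.integer((as.numeric(seed) %% 2147483587 + (x + 1) * 48271 + (y + 1) * 16807) %% 2147483587)
}

# clamp to [0, 1] preserving dim attributes (pmin/pmax would drop them)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Exact 2x mean pooling with ceiling dimensions (odd trailing row/col averages itself).
pool2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
  ro <- seq(1L, h, 2L); re <- seq(2L, h, 2L)
  s <- m[ro, , drop = FALSE]
  cnt_r <- rep(2, h2)
  if (length(re)) s[seq_along(re), ] <- s[seq_along(re), , drop = FALSE] + m[re, , drop = FALSE]
  if (h %% 2 == 1L) cnt_r[h2] <- 1
  co <- seq(1L, w, 2L); ce <- seq(2L, w, 2L)
  s2 <- s[, co, drop = FALSE]
  cnt_c <- rep(2, w2)
  if (length(ce)) s2[, seq_along(ce)] <- s2[, seq_along(ce), drop = FALSE] + s[, ce, drop = FALSE]
  if (w %% 2 == 1L) cnt_c[w2] <- 1
  sweep(sweep(s2, 1, cnt_r, "/"), 2, cnt_c, "/")
}

pool2_rgb <- function(img) {
  out <- NULL
  for (c in 1:3) {
    p <- pool2(img[, , c])
    if (is.null(out)) out <- array(0, c(nrow(p), ncol(p), 3L))
    out[, , c] <- p
  }
  out
}

log_info <- function(fmt, ...) {
  message(sprintf("[%s] INFO %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}
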