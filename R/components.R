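#' Label connected components of a binary raster
#'
#' 8-connected components (the convention used for lesion regions and
#' heatmap detections), labeled in raster-scan order of each component's
#' first pixel so labels are deterministic.
#'
#' @param bin logical or 0/1 numeric matrix.
#' @return integer matrix of the same shape: 0 = background, `1..K` =
#'   component ids; attribute `n` gives `K`.
#' @export
label_components <- function(bin) {
  stopifnot(is.matrix(bin))
  m <- bin != 0
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  fg <- which(m)                      # column-major linear indices
  if (!length(fg)) { attr(lab, "n") <- 0L; return(lab) }
  id <- integer(h * w); id[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {  # S, E, SE, NE
    r2 <- rows + off[1]; c2 <- cols + off[2]
    keep <- r2 >= 1L & r2 <= h & c2 <= w
    nb <- (c2[keep] - 1L) * h + r2[keep]
    src <- fg[keep]
    hit <- m[nb]
    if (any(hit)) edges <- c(edges, rbind(id[src[hit]], id[nb[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel by first occurrence in raster-scan (row-major: by y then x) order
  scan_order <- order(rows, cols)
  first <- !duplicated(comp[scan_order])
  relab <- integer(max(comp))
  relab[comp[scan_order][first]] <- seq_len(sum(first))
  lab[fg] <- relab[comp]
  attr(lab, "n") <- as.integer(sum(first))
  lab
}
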