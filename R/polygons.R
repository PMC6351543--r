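#' Binarize a heatmap
#'
#' `1` where the probability is strictly greater than `thr` (values exactly
#' at the threshold are excluded).
#'
#' @param hm a [prob_heatmap()].
#' @param thr threshold in `[0, 1]`.
#' @return a [mask_raster()] at the heatmap scale.
#' @export
binarize_heatmap <- function(hm, thr = 0.5) {
  stopifnot(inherits(hm, "prob_heatmap"))
  if (thr < 0 || thr > 1) stop("threshold must be in [0, 1]")
  mask_raster(hm$data > thr, hm$scale)
}

# Moore boundary tracing of one 8-connected component (values of `lab` == k).
# Returns 0-based (x, y) boundary pixel coordinates in tracing order.
trace_boundary <- function(lab, k) {
  idx <- which(lab == k, arr.ind = TRUE)
  # start at topmost, then leftmost pixel
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  sy <- start[1]; sx <- start[2]
  # clockwise Moore neighborhood, starting west
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  h <- nrow(lab); w <- ncol(lab)
  inside <- function(y, x) y >= 1L && y <= h && x >= 1L && x <= w && lab[y, x] == k
  if (sum(lab == k) == 1L) return(cbind(x = sx - 1L, y = sy - 1L))
  pts <- matrix(integer(0), 0, 2)
  cy <- sy; cx <- sx
  dir <- 1L  # backtrack points west of the start pixel (nothing above the start row)
  first_dir <- NA_integer_
  repeat {
    pts <- rbind(pts, c(cx - 1L, cy - 1L))
    found <- FALSE
    for (i in 0:7) {
      d <- (dir + i) %% 8L
      ny <- cy + dy[d + 1L]; nx <- cx + dx[d + 1L]
      if (inside(ny, nx)) {
        if (cy == sy && cx == sx) {
          if (is.na(first_dir)) first_dir <- d
          else if (d == first_dir && nrow(pts) > 1L) return(pts[-nrow(pts), , drop = FALSE])
        }
        cy <- ny; cx <- nx
        dir <- (d + 6L) %% 8L  # turn back two steps clockwise
        found <- TRUE
        break
      }
    }
    if (!found) return(pts)                       # isolated pixel (shouldn't happen here)
    if (cy == sy && cx == sx && nrow(pts) > 4L * sum(lab == k) + 8L) return(pts)
  }
}

#' Extract external tumor polygons from a binary mask
#'
#' Border-following (Moore tracing) on the 8-connected components of the
#' mask yields one closed outer contour per component; holes are ignored —
#' only external polygons are exported. Vertices are boundary pixel centers
#' scaled by the mask scale into level-0 coordinates. Components smaller
#' than `min_area` mask pixels are dropped to suppress single-pixel noise,
#' as are degenerate contours with fewer than 3 vertices.
#'
#' @param mask a [mask_raster()] (typically scale 8, from
#'   [binarize_heatmap()]).
#' @param min_area minimum component area in mask pixels.
#' @return list of polygons; each a numeric matrix with columns `x`, `y`
#'   (level-0 px, first vertex not repeated — the polygon is implicitly
#'   closed).
#' @export
extract_polygons <- function(mask, min_area = 4L) {
  stopifnot(inherits(mask, "mask_raster"))
  lab <- label_components(mask$data)
  n <- attr(lab, "n")
  polys <- list()
  for (k in seq_len(n)) {
    if (sum(lab == k) < min_area) next
    b <- trace_boundary(lab, k)
    if (nrow(b) < 3L) next
    p <- b * mask$scale
    colnames(p) <- c("x", "y")
    polys[[length(polys) + 1L]] <- p
  }
  polys
}

#' Rasterize a polygon back onto a mask grid
#'
#' Even-odd scanline fill over mask-pixel centers, united with the polygon's
#' own vertex pixels (consecutive contour vertices are 8-adjacent, so the
#' contour is covered). Used to verify that extracted polygons reproduce
#' their source components.
#'
#' @param poly polygon matrix (`x`, `y` in level-0 px) as returned by
#'   [extract_polygons()].
#' @param scale mask scale the polygon is rasterized onto.
#' @param dims mask dimensions `c(nrow, ncol)`.
#' @return binary matrix of shape `dims`.
#' @export
rasterize_polygon <- function(poly, scale, dims) {
  px <- poly[, "x"] / scale; py <- poly[, "y"] / scale
  out <- matrix(0L, dims[1], dims[2])
  nv <- length(px)
  xs <- 0:(dims[2] - 1L)
  for (row in seq_len(dims[1])) {
    yc <- row - 1L
    crossings <- rep(0L, dims[2])
    j <- nv
    for (i in seq_len(nv)) {
      y1 <- py[i]; y2 <- py[j]
      if ((y1 > yc) != (y2 > yc)) {
        xint <- (px[j] - px[i]) * (yc - y1) / (y2 - y1) + px[i]
        crossings <- crossings + (xs < xint)
      }
      j <- i
    }
    out[row, crossings %% 2L == 1L] <- 1L
  }
  vx <- round(px); vy <- round(py)
  ok <- vx >= 0 & vx < dims[2] & vy >= 0 & vy < dims[1]
  out[cbind(vy[ok] + 1L, vx[ok] + 1L)] <- 1L
  out
}

#' ASAP XML annotation I/O
#'
#' Writes polygons in the ASAP annotation schema
#' (`ASAP_Annotations/Annotations/Annotation[@Type="Polygon"]/Coordinates/
#' Coordinate[@Order, @X, @Y]`, level-0 pixel units) so segmentation results
#' can be loaded, checked and edited in the ASAP slide viewer.
#' `read_asap_xml()` inverts it; the round trip is exact to float precision
#' and preserves coordinate order.
#'
#' @param polygons list of polygon matrices (`x`, `y` columns, level-0 px).
#' @param path output / input file path.
#' @param group annotation group name.
#' @param color polygon display color.
#' @rdname asap_xml
#' @export
write_asap_xml <- function(polygons, path, group = "tumor", color = "#F4FA58") {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    ann <- xml2::xml_add_child(anns, "Annotation",
                               Name = sprintf("Annotation %d", i - 1L),
                               Type = "Polygon", PartOfGroup = group, Color = color)
    coords <- xml2::xml_add_child(ann, "Coordinates")
    for (j in seq_len(nrow(p))) {
      xml2::xml_add_child(coords, "Coordinate", Order = as.character(j - 1L),
                          X = format(p[j, "x"], digits = 17),
                          Y = format(p[j, "y"], digits = 17))
    }
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  xml2::xml_add_child(groups, "Group", Name = group, PartOfGroup = "None",
                      Color = color)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname asap_xml
#' @export
read_asap_xml <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation[@Type='Polygon']")
  lapply(anns, function(a) {
    cs <- xml2::xml_find_all(a, ".//Coordinate")
    ord <- order(as.integer(xml2::xml_attr(cs, "Order")))
    p <- cbind(x = as.numeric(xml2::xml_attr(cs, "X"))[ord],
               y = as.numeric(xml2::xml_attr(cs, "Y"))[ord])
    p
  })
}
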