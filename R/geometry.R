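#' Polygon utilities
#'
#' Polygons are numeric matrices with columns `x`, `y` in pixel coordinates
#' (see the package help page for the coordinate convention). The first vertex
#' is not repeated at the end.
#'
#' @param poly numeric matrix or data frame with columns `x` and `y`.
#' @return `polygon_area()` returns the signed shoelace area (positive for
#'   counter-clockwise winding in the stored axis order).
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  i2 <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly[, c("x", "y"), drop = FALSE])
  storage.mode(poly) <- "double"
  if (nrow(poly) >= 2L && all(poly[1L, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L) stop("a polygon needs at least 3 distinct vertices")
  poly
}

#' @rdname polygon_area
#' @return `normalize_winding()` returns the polygon with positive signed
#'   area (vertices reversed if needed).
#' @export
normalize_winding <- function(poly) {
  poly <- as_polygon(poly)
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  colnames(poly) <- c("x", "y")
  poly
}

# proper/improper intersection of segments p1-p2 and p3-p4
segments_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    o(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) || on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

#' @rdname polygon_area
#' @return `is_simple_polygon()` returns `TRUE` when no two non-adjacent
#'   edges intersect (and adjacent edges meet only at their shared vertex).
#' @export
is_simple_polygon <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  edge <- function(i) list(a = poly[i, ], b = poly[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1L)) {
    ei <- edge(i)
    for (j in seq((i + 1L), n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      ej <- edge(j)
      if (adjacent) {
        # edges share one vertex s; with the other endpoints u and v, the
        # polygon self-touches only when one of u, v lies on the other edge
        if (j == i + 1L) {
          s <- poly[j, ]; u <- ei$a; v <- ej$b
        } else {
          s <- poly[1L, ]; u <- ei$b; v <- ej$a
        }
        if (all(u == v)) return(FALSE) # degenerate spike
        if (point_on_segment(v, s, u) || point_on_segment(u, s, v))
          return(FALSE)
      } else if (segments_intersect(ei$a, ei$b, ej$a, ej$b)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

point_on_segment <- function(p, a, b) {
  cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (abs(cr) > 1e-12 * (abs(b[1] - a[1]) + abs(b[2] - a[2]) + 1)) return(FALSE)
  min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
}

#' Even-odd point-in-polygon test
#'
#' @param px,py numeric vectors of point coordinates (pixel space).
#' @param poly polygon (matrix with columns `x`, `y`).
#' @return logical vector, `TRUE` where the point is inside under the even-odd
#'   rule with half-open edge handling.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  x <- poly[, 1L]; y <- poly[, 2L]
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  for (k in seq_len(n)) {
    crosses <- (y[k] <= py) != (yj[k] <= py)
    if (any(crosses)) {
      xc <- x[k] + (py[crosses] - y[k]) * (xj[k] - x[k]) / (yj[k] - y[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xc)
    }
  }
  inside
}

#' Rasterize polygons onto a pixel grid
#'
#' Scanline even-odd fill: a pixel is set when its center `(ix + 0.5,
#' iy + 0.5)` lies inside the polygon. `rasterize_polygons()` returns the
#' union of several polygons.
#'
#' @param poly polygon in pixel coordinates.
#' @param height,width raster dimensions in pixels.
#' @return logical matrix `height x width`.
#' @export
rasterize_polygon <- function(poly, height, width) {
  poly <- as_polygon(poly)
  out <- matrix(FALSE, height, width)
  n <- nrow(poly)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  ylo <- max(0L, floor(min(y1)))
  yhi <- min(height - 1L, ceiling(max(y1)))
  if (ylo > yhi) return(out)
  for (iy in ylo:yhi) {
    yc <- iy + 0.5
    cross <- (y1 <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xc <- sort(x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) / (y2[cross] - y1[cross]))
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      # centers in [xc_k, xc_{k+1}): ix + 0.5 >= lo and < hi
      lo <- ceiling(xc[k] - 0.5 + 1e-12)
      hi <- ceiling(xc[k + 1L] - 0.5 - 1e-12) - 1L
      lo <- max(lo, 0L); hi <- min(hi, width - 1L)
      if (lo <= hi) out[iy + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  out
}

#' @rdname rasterize_polygon
#' @param polys list of polygons.
#' @export
rasterize_polygons <- function(polys, height, width) {
  out <- matrix(FALSE, height, width)
  for (p in polys) out <- out | rasterize_polygon(p, height, width)
  out
}

#' Douglas-Peucker polygon simplification
#'
#' Used to suppress the rasterization staircase of traced boundaries before
#' measuring perimeter. Closed polygons are split at the vertex farthest from
#' the first vertex and each chain simplified independently.
#'
#' @param poly polygon (matrix with columns `x`, `y`), treated as closed.
#' @param tol maximum allowed deviation (same units as the coordinates).
#' @return the simplified polygon.
#' @export
simplify_polygon <- function(poly, tol = 1) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n <= 4L) return(poly)
  d1 <- sqrt((poly[, 1L] - poly[1L, 1L])^2 + (poly[, 2L] - poly[1L, 2L])^2)
  i1 <- which.max(d1)
  keep1 <- dp_chain(poly[1:i1, , drop = FALSE], tol)
  keep2 <- dp_chain(poly[c(i1:n, 1L), , drop = FALSE], tol)
  idx <- c(seq(1L, i1)[keep1], c(i1:n, 1L)[keep2])
  idx <- idx[!duplicated(idx)]
  idx <- sort(idx[idx <= n])
  poly[idx, , drop = FALSE]
}

# logical keep-vector for an open chain of points
dp_chain <- function(pts, tol) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  if (n <= 2L) return(keep)
  stack <- list(c(1L, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rg[1L]; j <- rg[2L]
    if (j - i < 2L) next
    d <- point_segment_distance(pts[(i + 1L):(j - 1L), , drop = FALSE],
                                pts[i, ], pts[j, ])
    k <- which.max(d)
    if (d[k] > tol) {
      k <- i + k
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  keep
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1L] - a[1L])^2 + (p[, 2L] - a[2L])^2))
  t <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((p[, 1L] - (a[1L] + t * ab[1L]))^2 + (p[, 2L] - (a[2L] + t * ab[2L]))^2)
}

#' Trace the boundary polygon of a binary mask
#'
#' Marching-squares isoline at level 0.5 on the zero-padded mask. When the
#' mask contains several boundary loops (holes, multiple components) the
#' loop enclosing the largest absolute area is returned.
#'
#' @param mask logical or 0/1 matrix.
#' @return polygon in pixel coordinates (vertices at half-pixel positions).
#' @export
boundary_polygon <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask has no boundary")
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # rows carry y, columns carry x; padded index i maps to coordinate i - 1.5
  cl <- grDevices::contourLines(x = seq_len(nr + 2L) - 1.5,
                                y = seq_len(nc + 2L) - 1.5,
                                z = pad, levels = 0.5)
  polys <- lapply(cl, function(co) cbind(x = co$y, y = co$x))
  areas <- vapply(polys, function(p) abs(polygon_area(p)), numeric(1))
  normalize_winding(polys[[which.max(areas)]])
}

#' Boundary pixel centers of a mask
#'
#' Foreground pixels with at least one 4-neighbour outside the mask, returned
#' as their centers in pixel coordinates.
#'
#' @param mask logical or 0/1 matrix.
#' @return two-column matrix (`x`, `y`) of pixel centers.
#' @export
boundary_pixels <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  inner <- mask
  inner[] <- FALSE
  if (nr > 2L && nc > 2L) {
    core <- mask[2:(nr - 1L), 2:(nc - 1L)] &
      mask[1:(nr - 2L), 2:(nc - 1L)] & mask[3:nr, 2:(nc - 1L)] &
      mask[2:(nr - 1L), 1:(nc - 2L)] & mask[2:(nr - 1L), 3:nc]
    inner[2:(nr - 1L), 2:(nc - 1L)] <- core
  }
  b <- which(mask & !inner, arr.ind = TRUE)
  cbind(x = b[, 2L] - 0.5, y = b[, 1L] - 0.5)
}

#' Feret (maximum caliper) diameter of a point set
#'
#' The longest straight-line distance between any two points, computed by
#' reducing the set to its convex hull and taking the maximum pairwise
#' distance over hull vertices.
#'
#' @param points two-column matrix of coordinates (any planar unit).
#' @return the maximum pairwise Euclidean distance (0 for a single point).
#' @export
feret_diameter <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("feret_diameter() needs at least one point")
  if (nrow(points) == 1L) return(0)
  pts <- unique(points)
  if (nrow(pts) == 1L) return(0)
  if (nrow(pts) >= 3L) {
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
  }
  max(stats::dist(pts))
}
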