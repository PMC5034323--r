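#' 8-connected component labeling
#'
#' `EBImage::bwlabel()` labels 4-connected components; diagonal-only contacts
#' are merged afterwards with a union-find pass so that components are
#' 8-connected. Labels are renumbered 1..N in raster-scan order (left to
#' right, top to bottom) of each component's first pixel, which makes the
#' numbering deterministic.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  nl <- max(lab)
  if (nl > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
      cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))
    pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                     pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(nl)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(nl), find, integer(1))
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  relabel_rasterscan(lab)
}

# per-label bounding boxes and centroids in one pass over the raster;
# returns a list with n, area_px, r0/r1/c0/c1, cx/cy (pixel-center means)
label_stats <- function(labels) {
  sel <- which(labels > 0)
  v <- labels[sel]
  n <- if (length(v)) max(v) else 0L
  nr <- nrow(labels)
  r <- (sel - 1L) %% nr + 1L
  c <- (sel - 1L) %/% nr + 1L
  f <- factor(v, levels = seq_len(n))
  list(n = n,
       area_px = tabulate(v, nbins = n),
       r0 = as.integer(tapply(r, f, min)), r1 = as.integer(tapply(r, f, max)),
       c0 = as.integer(tapply(c, f, min)), c1 = as.integer(tapply(c, f, max)),
       cx = as.numeric(tapply(c - 0.5, f, mean)),
       cy = as.numeric(tapply(r - 0.5, f, mean)))
}

# renumber labels 1..N by raster-scan (row-major) order of first pixel
relabel_rasterscan <- function(lab) {
  sel <- lab > 0
  if (!any(sel)) return(matrix(0L, nrow(lab), ncol(lab)))
  rm_index <- (row(lab)[sel] - 1L) * ncol(lab) + col(lab)[sel]
  vals <- lab[sel]
  first <- tapply(rm_index, vals, min)
  old <- as.integer(names(first))
  new <- integer(max(old))
  new[old[order(first)]] <- seq_along(old)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[sel] <- new[vals]
  out
}

#' Pixel-wise union of hormone masks
#'
#' The total endocrine cell mask is the OR of all thresholded hormone
#' channels.
#'
#' @param hormone_masks non-empty list of logical matrices of equal shape.
#' @return logical matrix with semantic `"endocrine"`.
#' @export
composite_endocrine_mask <- function(hormone_masks) {
  if (!is.list(hormone_masks) || length(hormone_masks) == 0L)
    stop("need at least one hormone mask")
  d <- dim(hormone_masks[[1L]])
  for (m in hormone_masks)
    if (!all(dim(m) == d)) stop("hormone mask shape mismatch")
  binary_mask(Reduce(`|`, lapply(hormone_masks, function(m) m != 0)),
              "endocrine")
}

#' Segment endocrine structures into islets
#'
#' Morphological closing with a disc of `close_radius_um` merges endocrine
#' cells separated by small gaps into one structure; holes (unstained
#' intra-islet fractions such as capillaries) are then filled, and 8-connected
#' components of the filled mask with filled area >= `min_area_um2` become
#' islet records numbered in raster-scan order. Every record carries both the
#' stained (`endocrine_area_um2`) and the filled (`total_islet_area_um2`)
#' area, plus centroid, perimeter, circularity and Feret diameter.
#'
#' @param endocrine logical matrix (composite endocrine mask).
#' @param pixel_size micrometers per pixel.
#' @param close_radius_um closing disc radius, micrometers (default 5).
#' @param min_area_um2 smallest filled area kept; the default 0 keeps single
#'   endocrine cells.
#' @return list with `labels` (integer matrix over the filled structures) and
#'   `islets` (data frame, one row per islet).
#' @export
segment_islets <- function(endocrine, pixel_size, close_radius_um = 5,
                           min_area_um2 = 0) {
  if (close_radius_um < 0) stop("'close_radius_um' must be >= 0")
  endocrine <- endocrine != 0
  r_px <- round(close_radius_um / pixel_size)
  closed <- if (r_px >= 1L) {
    EBImage::imageData(EBImage::closing(endocrine * 1,
                                        EBImage::makeBrush(2L * r_px + 1L, "disc"))) != 0
  } else endocrine
  filled <- EBImage::imageData(EBImage::fillHull(closed * 1)) != 0
  labels <- label_components(filled)
  n <- max(labels)
  if (n == 0L)
    return(list(labels = labels, islets = empty_islet_table()))
  px2 <- pixel_size^2
  filled_px <- tabulate(labels[labels > 0], nbins = n)
  keep <- which(filled_px * px2 >= min_area_um2)
  if (length(keep) < n) {
    drop <- labels > 0 & !(labels %in% keep)
    labels[drop] <- 0L
    labels <- relabel_rasterscan(labels)
    n <- max(labels)
    filled_px <- tabulate(labels[labels > 0], nbins = n)
  }
  stained_px <- tabulate(labels[endocrine & labels > 0], nbins = n)
  st <- label_stats(labels)
  met <- lapply(seq_len(n), function(id)
    component_shape(labels, id, st, pixel_size))
  islets <- data.frame(
    islet_id = seq_len(n),
    endocrine_area_um2 = stained_px * px2,
    total_islet_area_um2 = filled_px * px2,
    centroid_x_um = st$cx * pixel_size,
    centroid_y_um = st$cy * pixel_size,
    perimeter_um = vapply(met, `[[`, numeric(1), "perimeter_um"),
    circularity = vapply(met, `[[`, numeric(1), "circularity"),
    feret_um = vapply(met, `[[`, numeric(1), "feret_um"))
  list(labels = labels, islets = islets)
}

empty_islet_table <- function() {
  data.frame(islet_id = integer(0), endocrine_area_um2 = numeric(0),
             total_islet_area_um2 = numeric(0), centroid_x_um = numeric(0),
             centroid_y_um = numeric(0), perimeter_um = numeric(0),
             circularity = numeric(0), feret_um = numeric(0))
}

#' Shape metrics of one labeled structure
#'
#' Centroid (mean of member pixel centers), perimeter (length of the traced
#' boundary polygon after 1 px Douglas-Peucker simplification, which removes
#' the rasterization staircase), circularity `4*pi*area/perimeter^2` clipped
#' at 1, and Feret diameter (maximum pairwise distance between boundary pixel
#' centers plus one pixel for the pixel extent).
#'
#' @param labels integer label matrix.
#' @param islet_id label to measure.
#' @param pixel_size micrometers per pixel.
#' @return list with `centroid_x_um`, `centroid_y_um`, `perimeter_um`,
#'   `circularity`, `feret_um`, `area_um2`.
#' @export
islet_metrics <- function(labels, islet_id, pixel_size) {
  if (!any(labels == islet_id))
    stop("label ", islet_id, " absent from the raster")
  st <- label_stats(labels)
  shape <- component_shape(labels, islet_id, st, pixel_size)
  c(list(centroid_x_um = st$cx[islet_id] * pixel_size,
         centroid_y_um = st$cy[islet_id] * pixel_size,
         area_um2 = st$area_px[islet_id] * pixel_size^2),
    shape)
}

# perimeter / circularity / feret of one labeled component, using the
# precomputed label_stats bounding box to crop before tracing
component_shape <- function(labels, id, st, pixel_size) {
  r0 <- st$r0[id]; r1 <- st$r1[id]; c0 <- st$c0[id]; c1 <- st$c1[id]
  sub <- labels[r0:r1, c0:c1, drop = FALSE] == id
  area_um2 <- st$area_px[id] * pixel_size^2
  poly <- boundary_polygon(sub)
  perim <- poly_length(simplify_polygon(poly, tol = 1)) * pixel_size
  circ <- if (perim > 0) min(1, 4 * pi * area_um2 / perim^2) else 1
  bp <- boundary_pixels(sub)
  bp[, 1L] <- (bp[, 1L] + (c0 - 1L)) * pixel_size
  bp[, 2L] <- (bp[, 2L] + (r0 - 1L)) * pixel_size
  list(perimeter_um = perim, circularity = circ,
       feret_um = feret_diameter(bp) + pixel_size)
}

# length of a closed polygon
poly_length <- function(poly) {
  n <- nrow(poly)
  i2 <- c(seq_len(n)[-1L], 1L)
  sum(sqrt((poly[i2, 1L] - poly[, 1L])^2 + (poly[i2, 2L] - poly[, 2L])^2))
}

#' Percent area
#'
#' `100 * component_area / pancreas_area`, the normalization used for all
#' endocrine mass estimates.
#'
#' @param component_area area of the structure of interest (um^2).
#' @param pancreas_area tissue area used for normalization (um^2, > 0).
#' @return percentage.
#' @export
percent_area <- function(component_area, pancreas_area) {
  if (any(pancreas_area <= 0)) stop("'pancreas_area' must be positive")
  100 * component_area / pancreas_area
}

#' Section-level summary
#'
#' @param tissue a [tissue_mask].
#' @param hormone_masks named list of binarized hormone masks.
#' @param segmentation result of [segment_islets()].
#' @param pixel_size micrometers per pixel.
#' @return object of class `section_summary`: pancreas area, per-hormone and
#'   total endocrine stained areas, total (filled) islet area, percent
#'   endocrine area, islet count and the islet table.
#' @export
section_summary <- function(tissue, hormone_masks, segmentation, pixel_size) {
  px2 <- pixel_size^2
  hormone_area <- vapply(hormone_masks, function(m) sum(m != 0) * px2,
                         numeric(1))
  endocrine_area <- sum(composite_endocrine_mask(hormone_masks)) * px2
  structure(list(
    pancreas_area_um2 = tissue$pancreas_area_um2,
    hormone_area_um2 = hormone_area,
    endocrine_area_um2 = endocrine_area,
    total_islet_area_um2 = sum(segmentation$islets$total_islet_area_um2),
    percent_endocrine = percent_area(endocrine_area, tissue$pancreas_area_um2),
    islet_count = nrow(segmentation$islets),
    islets = segmentation$islets), class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("section_summary: %d islets, %.4g um^2 pancreas, %.4g%% endocrine\n",
              x$islet_count, x$pancreas_area_um2, x$percent_endocrine))
  invisible(x)
}
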