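#' Calibrated multi-channel section image
#'
#' A `section_image` holds one 2-D intensity raster per channel role. Exactly
#' one channel must have the role `"nuclei"`; the remaining 1-3 channels are
#' hormone channels with free-text names (e.g. `"insulin"`, `"glucagon"`,
#' `"somatostatin"`, `"pp"`). All rasters share the same `height x width` and
#' one physical pixel edge length in micrometers.
#'
#' @param channels named list of numeric matrices (`[row, col]`), one per
#'   channel role; must contain the name `"nuclei"`.
#' @param pixel_size physical edge length of one pixel, micrometers (> 0).
#' @return an object of class `section_image` with elements `channels`,
#'   `pixel_size`, `height`, `width`, `hormones` (hormone role names).
#' @export
section_image <- function(channels, pixel_size) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a named list of matrices")
  if (sum(names(channels) == "nuclei") != 1L)
    stop("exactly one channel must have the role 'nuclei'")
  hormones <- setdiff(names(channels), "nuclei")
  if (length(hormones) < 1L || length(hormones) > 3L)
    stop("need 1-3 hormone channels besides 'nuclei'")
  if (anyDuplicated(names(channels)))
    stop("duplicated channel roles")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all channel rasters must share the same height x width")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (micrometers)")
  channels <- lapply(channels, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  structure(list(channels = channels, pixel_size = pixel_size,
                 height = dims[1L, 1L], width = dims[2L, 1L],
                 hormones = hormones),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image: %d x %d px, %.4g um/px\n", x$height, x$width,
              x$pixel_size))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Pancreas and exclusion contours
#'
#' @param pancreas_outline list of simple polygons (pixel coordinates)
#'   outlining the tissue to which endocrine mass is normalized.
#' @param exclusions list of simple polygons marking regions without endocrine
#'   or exocrine tissue (large vessels, ducts, fat, inter-lobe space).
#' @return an object of class `contour_set`; polygon winding is normalized.
#' @export
contour_set <- function(pancreas_outline, exclusions = list()) {
  if (is.matrix(pancreas_outline) || is.data.frame(pancreas_outline))
    pancreas_outline <- list(pancreas_outline)
  if (is.matrix(exclusions) || is.data.frame(exclusions))
    exclusions <- list(exclusions)
  if (length(pancreas_outline) == 0L)
    stop("'pancreas_outline' must contain at least one polygon")
  check <- function(p, what) {
    p <- as_polygon(p)
    if (!is_simple_polygon(p))
      stop("self-intersecting ", what, " polygon")
    normalize_winding(p)
  }
  structure(list(
    pancreas_outline = lapply(pancreas_outline, check, what = "pancreas outline"),
    exclusions = lapply(exclusions, check, what = "exclusion")
  ), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d outline polygon(s), %d exclusion(s)\n",
              length(x$pancreas_outline), length(x$exclusions)))
  invisible(x)
}

#' Binary mask constructor
#'
#' Masks are plain logical matrices; this helper validates shape against a
#' parent raster and attaches a semantic label.
#'
#' @param values logical or 0/1 matrix.
#' @param semantic label such as `"tissue"`, `"endocrine"`, a hormone name,
#'   `"nuclei"` or `"islet"`.
#' @param parent optional `section_image` whose dimensions the mask must match.
#' @return logical matrix with attribute `semantic`.
#' @export
binary_mask <- function(values, semantic = "mask", parent = NULL) {
  m <- as.matrix(values)
  if (!all(m %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be 0/1")
  m <- m != 0
  if (!is.null(parent) && (nrow(m) != parent$height || ncol(m) != parent$width))
    stop("mask shape does not match the parent image")
  attr(m, "semantic") <- semantic
  m
}
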