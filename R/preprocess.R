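#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background of a fluorescence channel as the grayscale
#' morphological opening with a disc structuring element of the given radius
#' and subtracts it. Applied to the full raster with no regional selection;
#' the result is never negative and never exceeds the input.
#'
#' @param channel numeric intensity matrix.
#' @param radius structuring element radius in pixels (>= 1). The radius
#'   should exceed the largest genuine structure (nucleus/cell) so that
#'   foreground is preserved while slow background gradients are removed.
#' @return matrix of the same shape, `channel - opening(channel)`.
#' @export
subtract_background <- function(channel, radius = 50) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("'radius' must be >= 1 pixel")
  channel <- as.matrix(channel)
  if (length(channel) == 0L) stop("empty channel")
  lo <- min(channel); hi <- max(channel)
  if (lo == hi) return(matrix(0, nrow(channel), ncol(channel)))
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  # grayscale opening is affine-equivariant; rescale into [0, 1] because
  # EBImage clips intensities outside that range
  scaled <- (channel - lo) / (hi - lo)
  bg <- EBImage::imageData(EBImage::opening(scaled, brush)) * (hi - lo) + lo
  out <- channel - bg
  out[out < 0] <- 0
  out
}

#' Per-channel threshold specification
#'
#' @param value threshold on the channel's intensity scale.
#' @param provenance `"manual"` (the primary mode of the workflow) or
#'   `"automatic"`.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(value, provenance = c("manual", "automatic")) {
  provenance <- match.arg(provenance)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("'value' must be a single finite number")
  structure(list(value = value, provenance = provenance),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold %.6g (%s)\n", x$value, x$provenance))
  invisible(x)
}

#' Automatic (Otsu) threshold
#'
#' Exhaustive between-class-variance-maximizing threshold over a histogram of
#' the channel's intensity range: every cut between histogram bins is scored
#' by `w1 * w2 * (mu1 - mu2)^2` and the best cut wins (exact ties average the
#' tied bin centers). With one level per gray value of integer data the
#' search is exact.
#'
#' @param channel numeric matrix with at least two distinct values.
#' @param levels histogram resolution.
#' @param range histogram range; defaults to the observed intensity range.
#'   For integer data, `c(min - 0.5, max + 0.5)` with one level per gray
#'   value makes the search exact.
#' @return a [threshold_spec] flagged `"automatic"`.
#' @export
auto_threshold <- function(channel, levels = 256, range = NULL) {
  channel <- as.matrix(channel)
  if (min(channel) == max(channel))
    stop("cannot threshold a constant channel")
  if (is.null(range)) range <- c(min(channel), max(channel))
  breaks <- seq(range[1L], range[2L], length.out = levels + 1L)
  counts <- as.double(hist(as.vector(channel), breaks = breaks,
                           plot = FALSE)$counts)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(counts)
  m1 <- cumsum(counts * mids)
  w2 <- w1[levels] - w1
  m2 <- m1[levels] - m1
  bcv <- rep(NA_real_, levels)
  ok <- w1 > 0 & w2 > 0
  bcv[ok] <- (w1 * w2 * (m1 / w1 - m2 / w2)^2)[ok]
  maxi <- which(bcv == max(bcv, na.rm = TRUE))
  value <- (mids[maxi[1L]] + mids[maxi[length(maxi)]]) / 2
  # the optimal cut leaves intensities equal to `value` in the background;
  # binarize() compares inclusively, so a threshold that coincides with an
  # observed gray value is moved into the gap just above it
  if (any(channel == value)) {
    above <- channel[channel > value]
    value <- if (length(above)) (value + min(above)) / 2 else value + 1
  }
  threshold_spec(value, provenance = "automatic")
}

#' Serialize thresholds as a key=value text file
#'
#' One `channel=value` line per channel, plus `provenance.channel=...` lines,
#' mirroring the plain-text threshold files of the imaging workflow.
#'
#' @param thresholds named list of [threshold_spec].
#' @param path output file.
#' @export
write_threshold_spec <- function(thresholds, path) {
  lines <- c(
    vapply(names(thresholds), function(nm)
      sprintf("%s=%.10g", nm, thresholds[[nm]]$value), character(1)),
    vapply(names(thresholds), function(nm)
      sprintf("provenance.%s=%s", nm, thresholds[[nm]]$provenance), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_threshold_spec
#' @return `read_threshold_spec()` returns the named list of [threshold_spec].
#' @export
read_threshold_spec <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  ch <- keys[!startsWith(keys, "provenance.")]
  out <- lapply(ch, function(nm) {
    prov <- vals[keys == paste0("provenance.", nm)]
    threshold_spec(as.numeric(vals[keys == nm]),
                   if (length(prov)) prov else "manual")
  })
  stats::setNames(out, ch)
}

#' Build the tissue (normalization) mask
#'
#' Rasterizes the manual pancreas outline and subtracts every exclusion
#' polygon whose rasterized area exceeds `exclusion_min_fraction` of the
#' outline area (strictly greater). Smaller exclusions are deliberately left
#' inside the tissue mask, so that only regions materially distorting the
#' normalization are removed.
#'
#' @param section a [section_image] (supplies shape and pixel size).
#' @param contours a [contour_set].
#' @param exclusion_min_fraction minimum exclusion area as a fraction of the
#'   outline area; the default 0.0005 is the ">0.05% of a given section" rule.
#' @return an object of class `tissue_mask`: list with `mask` (logical
#'   matrix), `pancreas_area_um2`, `excluded_area_um2`, `applied_exclusions`
#'   (indices of subtracted polygons) and `pixel_size`.
#' @export
build_tissue_mask <- function(section, contours, exclusion_min_fraction = 0.0005) {
  stopifnot(inherits(section, "section_image"), inherits(contours, "contour_set"))
  base <- rasterize_polygons(contours$pancreas_outline, section$height,
                             section$width)
  outline_px <- sum(base)
  if (outline_px == 0L)
    stop("the pancreas outline rasterizes to zero pixels")
  mask <- base
  applied <- integer(0)
  for (i in seq_along(contours$exclusions)) {
    ex <- rasterize_polygon(contours$exclusions[[i]], section$height,
                            section$width)
    if (sum(ex) > exclusion_min_fraction * outline_px) {
      mask <- mask & !ex
      applied <- c(applied, i)
    }
  }
  px2 <- section$pixel_size^2
  structure(list(mask = binary_mask(mask, "tissue"),
                 pancreas_area_um2 = sum(mask) * px2,
                 excluded_area_um2 = (outline_px - sum(mask)) * px2,
                 applied_exclusions = applied,
                 pixel_size = section$pixel_size),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask: %.4g um^2 pancreas area, %d exclusion(s) applied (%.4g um^2)\n",
              x$pancreas_area_um2, length(x$applied_exclusions),
              x$excluded_area_um2))
  invisible(x)
}

#' Binarize a channel against a threshold within the tissue mask
#'
#' `mask = (channel >= threshold) AND tissue`; pixels outside the pancreas
#' area are always 0. The comparison is inclusive (`>=`).
#'
#' @param channel numeric matrix.
#' @param thr a [threshold_spec] or a single number (treated as manual).
#' @param tissue optional [tissue_mask] (or logical matrix); when omitted the
#'   whole frame is eligible.
#' @param semantic label stored on the returned mask.
#' @return logical matrix.
#' @export
binarize <- function(channel, thr, tissue = NULL, semantic = "mask") {
  channel <- as.matrix(channel)
  if (is.numeric(thr) && !inherits(thr, "threshold_spec"))
    thr <- threshold_spec(thr, "manual")
  m <- channel >= thr$value
  if (!is.null(tissue)) {
    tm <- if (inherits(tissue, "tissue_mask")) tissue$mask else tissue != 0
    if (!all(dim(tm) == dim(m))) stop("tissue mask shape mismatch")
    m <- m & tm
  }
  binary_mask(m, semantic)
}
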