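#' Read a calibrated multi-channel section image
#'
#' Accepts either one multi-page TIFF (`image_path` of length 1, `channel_map`
#' giving the 1-based page of each role) or one single-page TIFF per channel
#' (`image_path` a vector, `channel_map` indexing into it). Stored intensities
#' are returned unscaled (`as.is`), so integer images round-trip bit-exactly.
#'
#' @param image_path path(s) to TIFF file(s).
#' @param channel_map named integer vector mapping channel roles to pages (or
#'   files); must name exactly one `"nuclei"` role and 1-3 hormone roles.
#' @param pixel_size physical pixel edge length, micrometers.
#' @return a [section_image].
#' @export
read_section <- function(image_path, channel_map, pixel_size) {
  channel_map <- unlist(channel_map)
  if (is.null(names(channel_map)))
    stop("'channel_map' must be named by channel role")
  for (p in image_path)
    if (!file.exists(p)) stop("file not found: ", p)
  if (length(image_path) == 1L) {
    pages <- tiff::readTIFF(image_path, all = TRUE, as.is = TRUE)
    if (max(channel_map) > length(pages) || min(channel_map) < 1L)
      stop("channel_map page index out of range (file has ", length(pages),
           " page(s))")
    rasters <- lapply(channel_map, function(i) pages[[i]])
  } else {
    if (max(channel_map) > length(image_path) || min(channel_map) < 1L)
      stop("channel_map file index out of range")
    rasters <- lapply(channel_map, function(i)
      tiff::readTIFF(image_path[i], as.is = TRUE))
  }
  rasters <- lapply(rasters, function(r) {
    if (length(dim(r)) == 3L) {
      if (dim(r)[3L] == 1L) r <- r[, , 1L] else
        stop("multi-sample (color) TIFF pages are not supported; supply one grayscale raster per channel")
    }
    r
  })
  names(rasters) <- names(channel_map)
  section_image(rasters, pixel_size = pixel_size)
}

#' Write a section image as a multi-page TIFF
#'
#' Integer data (the generator's native output) are stored at
#' `bits_per_sample` 8 or 16 and round-trip bit-exactly through
#' [read_section()]. `bits_per_sample = 32` stores IEEE single-precision
#' floats (doubles are narrowed).
#'
#' @param section a [section_image].
#' @param path output file.
#' @param bits_per_sample 8, 16 or 32.
#' @return invisibly, the channel order written (use it as the
#'   `channel_map`).
#' @export
write_section <- function(section, path, bits_per_sample = 16) {
  stopifnot(inherits(section, "section_image"))
  if (!bits_per_sample %in% c(8L, 16L, 32L))
    stop("bits_per_sample must be 8, 16 or 32")
  pages <- lapply(section$channels, function(m) {
    if (bits_per_sample == 32L) return(m)
    top <- 2^bits_per_sample - 1
    if (any(m != round(m)) || min(m) < 0 || max(m) > top)
      stop("integer TIFF output requires integral intensities in [0, ", top, "]")
    m / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "none", reduce = FALSE)
  invisible(stats::setNames(seq_along(section$channels), names(section$channels)))
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8,
                  compression = "none")
  invisible(path)
}

#' Write a labeled raster as a 16-bit TIFF
#'
#' @param labels integer matrix of labels (0 = background, max 65535).
#' @param path output file.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read pancreas/exclusion contours
#'
#' GeoJSON is the canonical format: a `FeatureCollection` of `Polygon`
#' features with a property `kind` of `"pancreas"` or `"exclusion"` and
#' coordinates in pixel space. ImageJ `.roi` polygon files are supported for
#' compatibility; the main file is the pancreas outline and further `.roi`
#' files may be passed as exclusions.
#'
#' @param path file to read.
#' @param format `"geojson"` or `"imagej_roi"`; guessed from the extension by
#'   default.
#' @param exclusion_paths additional `.roi` files read as exclusion polygons
#'   (ImageJ format only).
#' @return a [contour_set].
#' @export
read_contours <- function(path, format = c("auto", "geojson", "imagej_roi"),
                          exclusion_paths = character()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.roi$", path, ignore.case = TRUE)) "imagej_roi" else "geojson"
  if (format == "geojson") {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
    outline <- list(); excl <- list()
    for (f in gj$features) {
      if (!identical(f$geometry$type, "Polygon"))
        stop("only Polygon features are supported")
      ring <- f$geometry$coordinates[[1L]]
      poly <- do.call(rbind, lapply(ring, function(v) c(x = v[[1L]], y = v[[2L]])))
      kind <- f$properties$kind
      if (identical(kind, "exclusion")) excl[[length(excl) + 1L]] <- poly
      else outline[[length(outline) + 1L]] <- poly
    }
    if (length(outline) == 0L) stop("GeoJSON contains no pancreas outline")
    contour_set(outline, excl)
  } else {
    outline <- list(read_imagej_roi(path))
    excl <- lapply(exclusion_paths, read_imagej_roi)
    contour_set(outline, excl)
  }
}

#' Write contours as GeoJSON
#'
#' @param contours a [contour_set].
#' @param path output file.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  feat <- function(poly, kind) {
    ring <- rbind(poly, poly[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(kind = kind),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  }
  features <- c(lapply(contours$pancreas_outline, feat, kind = "pancreas"),
                lapply(contours$exclusions, feat, kind = "exclusion"))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ImageJ `.roi` polygon
#'
#' Minimal reader for the binary `.roi` record: polygon, freehand and traced
#' ROI types are accepted and returned as a polygon in pixel coordinates.
#'
#' @param path `.roi` file.
#' @return polygon matrix with columns `x`, `y`.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ .roi file: ", path)
  short_at <- function(off) readBin(raw[(off + 1L):(off + 2L)], "integer",
                                    size = 2L, endian = "big")
  type <- as.integer(raw[7L])
  if (!type %in% c(0L, 7L, 8L))
    stop("unsupported ROI type ", type, " (only polygon/freehand/traced)")
  top <- short_at(8L); left <- short_at(10L)
  n <- short_at(16L)
  if (n < 3L) stop("ROI has fewer than 3 vertices")
  xs <- readBin(raw[65:(64L + 2L * n)], "integer", n = n, size = 2L,
                endian = "big")
  ys <- readBin(raw[(65L + 2L * n):(64L + 4L * n)], "integer", n = n,
                size = 2L, endian = "big")
  cbind(x = xs + left, y = ys + top)
}

#' Write a polygon as an ImageJ `.roi` file
#'
#' @param poly polygon matrix with columns `x`, `y` (pixel coordinates,
#'   rounded to integers).
#' @param path output file.
#' @export
write_imagej_roi <- function(poly, path) {
  poly <- round(as_polygon(poly))
  n <- nrow(poly)
  left <- min(poly[, 1L]); top <- min(poly[, 2L])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(c(218L), con, size = 2L, endian = "big")        # version
  writeBin(as.raw(c(0L, 0L)), con)                         # type = polygon
  writeBin(as.integer(c(top, left, max(poly[, 2L]), max(poly[, 1L]), n)),
           con, size = 2L, endian = "big")
  writeBin(raw(64L - 18L), con)                            # rest of header
  writeBin(as.integer(poly[, 1L] - left), con, size = 2L, endian = "big")
  writeBin(as.integer(poly[, 2L] - top), con, size = 2L, endian = "big")
  invisible(path)
}
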