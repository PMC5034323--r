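#' Regular square point grid
#'
#' Lattice vertices at `(dx + i*s, dy + j*s)` lying inside the frame
#' (`0 <= x < w`, `0 <= y < h`), in micrometers.
#'
#' @param frame_um frame size `c(w, h)` in micrometers.
#' @param spacing_um vertex spacing (default 25 um).
#' @param offset_um grid origin offset `c(dx, dy)`.
#' @return object of class `point_grid`: data frame `vertices` (`x_um`,
#'   `y_um`), `spacing_um`, `offset_um`, `n_total`.
#' @export
make_grid <- function(frame_um, spacing_um = 25, offset_um = c(0, 0)) {
  if (spacing_um <= 0) stop("'spacing_um' must be positive")
  xs <- seq_grid(offset_um[1L], spacing_um, frame_um[1L])
  ys <- seq_grid(offset_um[2L], spacing_um, frame_um[2L])
  vertices <- expand.grid(x_um = xs, y_um = ys, KEEP.OUT.ATTRS = FALSE)
  structure(list(vertices = vertices, spacing_um = spacing_um,
                 offset_um = offset_um, n_total = nrow(vertices)),
            class = "point_grid")
}

seq_grid <- function(d0, s, lim) {
  i0 <- ceiling(-d0 / s)
  v <- numeric(0)
  i <- i0
  repeat {
    x <- d0 + i * s
    if (x >= lim) break
    if (x >= 0) v <- c(v, x)
    i <- i + 1
  }
  v
}

#' Point-counting area-fraction estimate
#'
#' A grid vertex is positive when the pixel containing it is set in the
#' target mask; the estimate is `100 * n_positive / n_total`, reported both
#' exactly and rounded half-up to two decimals.
#'
#' @param target_mask logical matrix (e.g. a thresholded beta-cell mask).
#' @param grid a [make_grid()] object; vertices must fall inside the raster.
#' @param pixel_size micrometers per pixel.
#' @return list with `n_positive`, `n_total`, `percent` (exact) and
#'   `percent_rounded` (half-up, 2 decimals).
#' @export
point_count_estimate <- function(target_mask, grid, pixel_size) {
  stopifnot(inherits(grid, "point_grid"))
  if (grid$n_total == 0L) stop("empty grid")
  ix <- floor(grid$vertices$x_um / pixel_size)
  iy <- floor(grid$vertices$y_um / pixel_size)
  if (any(ix < 0 | iy < 0 | ix >= ncol(target_mask) | iy >= nrow(target_mask)))
    stop("grid vertices fall outside the raster")
  n_pos <- sum(target_mask[cbind(iy + 1L, ix + 1L)] != 0)
  pct <- 100 * n_pos / grid$n_total
  list(n_positive = n_pos, n_total = grid$n_total, percent = pct,
       percent_rounded = round_half_up(pct, 2L))
}

# round half away from zero at `digits` decimals
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Partition a section frame into optical panels
#'
#' Non-overlapping tiling of the frame by `panel_um`-sized panels; ragged
#' right/bottom panels are kept so that every pixel lies in exactly one
#' panel. Panels are numbered in raster-scan order.
#'
#' @param frame_um frame size `c(w, h)` in micrometers.
#' @param pixel_size micrometers per pixel.
#' @param panel_um panel size `c(w, h)` in micrometers; the default
#'   868 x 662 um is a typical 10x optical field.
#' @return object of class `panel_grid`: data frame with 0-based pixel ranges
#'   `x0, x1, y0, y1` (half-open) per panel.
#' @export
make_panels <- function(frame_um, pixel_size, panel_um = c(868, 662)) {
  w_px <- round(frame_um[1L] / pixel_size)
  h_px <- round(frame_um[2L] / pixel_size)
  pw <- max(1L, round(panel_um[1L] / pixel_size))
  ph <- max(1L, round(panel_um[2L] / pixel_size))
  x0 <- seq(0L, w_px - 1L, by = pw)
  y0 <- seq(0L, h_px - 1L, by = ph)
  panels <- expand.grid(x0 = x0, y0 = y0, KEEP.OUT.ATTRS = FALSE)
  panels <- panels[order(panels$y0, panels$x0), ]
  panels$x1 <- pmin(panels$x0 + pw, w_px)
  panels$y1 <- pmin(panels$y0 + ph, h_px)
  panels$panel_id <- seq_len(nrow(panels))
  rownames(panels) <- NULL
  structure(list(panels = panels[, c("panel_id", "x0", "x1", "y0", "y1")],
                 pixel_size = pixel_size,
                 frame_px = c(w = w_px, h = h_px)),
            class = "panel_grid")
}

#' Count positive pixels of a mask within each panel
#'
#' @param panels a [make_panels()] object.
#' @param mask logical matrix matching the panel frame.
#' @return integer vector, one count per panel.
#' @export
panel_counts <- function(panels, mask) {
  p <- panels$panels
  if (nrow(mask) != panels$frame_px["h"] || ncol(mask) != panels$frame_px["w"])
    stop("mask shape does not match the panel frame")
  vapply(seq_len(nrow(p)), function(i)
    sum(mask[(p$y0[i] + 1L):p$y1[i], (p$x0[i] + 1L):p$x1[i]] != 0),
    integer(1))
}

#' Rank panels by content (islet-rich first)
#'
#' Panels sorted by descending positive-pixel count of the content mask;
#' ties broken by ascending panel index.
#'
#' @param panels a [make_panels()] object.
#' @param content_mask logical matrix (e.g. an endocrine or PP-cell mask).
#' @return integer vector of panel indices, richest first.
#' @export
rank_panels <- function(panels, content_mask) {
  counts <- panel_counts(panels, content_mask)
  order(-counts, panels$panels$panel_id)
}

#' Cumulative selection curve over ranked panels
#'
#' For each `k`, the percent endocrine area obtained when only the first `k`
#' panels of `ordering` are analyzed: `100 * endocrine pixels / tissue pixels`
#' within the selected panels. At `k = n_panels` the curve equals the
#' whole-section estimate exactly. Selections containing no tissue give `NA`
#' with `undefined = TRUE` rather than an error.
#'
#' @param panels a [make_panels()] object.
#' @param ordering panel ordering, e.g. from [rank_panels()].
#' @param endocrine_mask logical matrix (already restricted to tissue).
#' @param tissue a [tissue_mask] or logical matrix.
#' @param k_values selection sizes (default `1:n_panels`).
#' @return data frame `k`, `percent`, `undefined`, with attribute
#'   `reference` = whole-section percent.
#' @export
selection_curve <- function(panels, ordering, endocrine_mask, tissue,
                            k_values = NULL) {
  tm <- if (inherits(tissue, "tissue_mask")) tissue$mask else tissue != 0
  n <- nrow(panels$panels)
  if (is.null(k_values)) k_values <- seq_len(n)
  if (any(k_values < 1L | k_values > n)) stop("k out of range")
  e_cnt <- panel_counts(panels, endocrine_mask)[ordering]
  t_cnt <- panel_counts(panels, tm)[ordering]
  ce <- cumsum(e_cnt); ct <- cumsum(t_cnt)
  pct <- ifelse(ct[k_values] > 0, 100 * ce[k_values] / ct[k_values], NA_real_)
  out <- data.frame(k = k_values, percent = pct,
                    undefined = ct[k_values] == 0)
  attr(out, "reference") <- 100 * sum(endocrine_mask != 0) / sum(tm)
  out
}

#' Every-nth-section sampling within a tissue block
#'
#' Selects sections 1, 1+n, 1+2n, ... from an ordered block of section
#' summaries and returns their percent endocrine areas.
#'
#' @param block list of [section_summary] objects (or a numeric vector of
#'   percent endocrine areas), in cutting order.
#' @param n sampling period (default every 50th section).
#' @return list with `indices`, `percent` and `range`.
#' @export
every_nth_section <- function(block, n = 50) {
  if (n < 1L) stop("'n' must be >= 1")
  pct <- if (is.numeric(block)) block else
    vapply(block, function(s) s$percent_endocrine, numeric(1))
  if (length(pct) == 0L) stop("empty block")
  idx <- seq(1L, length(pct), by = n)
  list(indices = idx, percent = pct[idx], range = range(pct[idx]))
}

#' Whole-organ estimates under block-selection schemes
#'
#' The organ is an ordered set of tissue blocks labeled `head`, `body`,
#' `tail`. An estimate under a scheme is the area-weighted mean percent
#' endocrine area over the selected blocks (total endocrine area divided by
#' total pancreas area of the selection); the fold change compares it to the
#' all-blocks truth.
#'
#' Schemes: `"all"` (truth, fold 1), `"single_block"` (each block alone,
#' enumerated unless `block` is given), `"one_per_region"` (one block from
#' each region; all combinations enumerated unless `blocks` are given),
#' `"region_only"` (all blocks of one `region`), `"random_k"` (`k` random
#' blocks, `replicates` seeded draws).
#'
#' @param blocks data frame with columns `block`, `region` (head/body/tail),
#'   `pancreas_area_um2`, `endocrine_area_um2`.
#' @param scheme selection rule.
#' @param block single block id for `single_block`.
#' @param region region name for `region_only`.
#' @param k,replicates,seed parameters of `random_k`.
#' @return data frame with `scheme`, `selection`, `estimate` (percent) and
#'   `fold` (estimate / truth).
#' @export
block_selection_estimates <- function(blocks,
                                      scheme = c("all", "single_block",
                                                 "one_per_region",
                                                 "region_only", "random_k"),
                                      block = NULL, region = NULL, k = NULL,
                                      replicates = 5, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("block", "region", "pancreas_area_um2",
                  "endocrine_area_um2") %in% names(blocks)))
  est <- function(sel) {
    s <- blocks[blocks$block %in% sel, ]
    if (nrow(s) == 0L) stop("scheme selected zero blocks")
    100 * sum(s$endocrine_area_um2) / sum(s$pancreas_area_um2)
  }
  truth <- est(blocks$block)
  res <- switch(scheme,
    all = data.frame(selection = "all", estimate = truth),
    single_block = {
      ids <- if (is.null(block)) blocks$block else block
      data.frame(selection = as.character(ids),
                 estimate = vapply(ids, function(b) est(b), numeric(1)))
    },
    one_per_region = {
      regions <- c("head", "body", "tail")
      ids <- lapply(regions, function(r) blocks$block[blocks$region == r])
      if (any(lengths(ids) == 0L)) stop("need at least one block per region")
      combos <- expand.grid(ids[[1L]], ids[[2L]], ids[[3L]],
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      data.frame(
        selection = apply(combos, 1L, paste, collapse = "+"),
        estimate = apply(combos, 1L, function(sel) est(sel)))
    },
    region_only = {
      if (is.null(region)) stop("'region' required for region_only")
      data.frame(selection = region,
                 estimate = est(blocks$block[blocks$region == region]))
    },
    random_k = {
      if (is.null(k)) stop("'k' required for random_k")
      old <- get_rng_state()
      on.exit(restore_rng_state(old))
      set.seed(seed)
      sels <- replicate(replicates,
                        sample(blocks$block, min(k, nrow(blocks))),
                        simplify = FALSE)
      data.frame(
        selection = vapply(sels, paste, character(1), collapse = "+"),
        estimate = vapply(sels, est, numeric(1)))
    })
  res$scheme <- scheme
  res$fold <- res$estimate / truth
  res[, c("scheme", "selection", "estimate", "fold")]
}

#' Cell-type ratios from the N largest islets
#'
#' Sorts islets by total (filled) area, keeps the `min(n, N)` largest, and
#' compares pooled cell-count ratios of every hormone pair against the
#' all-islet ratios. Zero denominators are flagged `undefined` instead of
#' raising an error.
#'
#' @param islets islet table with `total_islet_area_um2` and `count_<type>`
#'   columns (see [assign_to_islets()]).
#' @param n number of largest islets to keep (default 100).
#' @param types cell types; default: all `count_` columns except
#'   `unclassified`.
#' @return data frame with `pair`, `top_ratio`, `all_ratio`, `fold`,
#'   `undefined`.
#' @export
largest_n_ratios <- function(islets, n = 100, types = NULL) {
  if (n < 1L) stop("'n' must be >= 1")
  if (is.null(types))
    types <- setdiff(sub("^count_", "", grep("^count_", names(islets),
                                             value = TRUE)), "unclassified")
  if (length(types) < 2L) stop("need at least two cell types")
  top <- islets[order(-islets$total_islet_area_um2), ]
  top <- top[seq_len(min(n, nrow(top))), ]
  pairs <- utils::combn(types, 2L)
  ratio <- function(df, a, b) {
    num <- sum(df[[paste0("count_", a)]])
    den <- sum(df[[paste0("count_", b)]])
    if (den == 0L) NA_real_ else num / den
  }
  out <- data.frame(
    pair = paste0(pairs[1L, ], "/", pairs[2L, ]),
    top_ratio = vapply(seq_len(ncol(pairs)), function(j)
      ratio(top, pairs[1L, j], pairs[2L, j]), numeric(1)),
    all_ratio = vapply(seq_len(ncol(pairs)), function(j)
      ratio(islets, pairs[1L, j], pairs[2L, j]), numeric(1)))
  out$fold <- out$top_ratio / out$all_ratio
  out$undefined <- !is.finite(out$fold)
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
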