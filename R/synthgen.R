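#' Parameters of the synthetic section generator
#'
#' The generator emulates the tissue properties the pipeline is built for:
#' scattered islets spanning single endocrine cells to large clusters
#' (log-normal cell counts), size-dependent composition (the alpha-cell
#' fraction rising with islet size), cells rendered as cytoplasm discs with
#' concentric nuclei, optional islet-rich spatial clustering, smooth
#' background gradients with Gaussian noise, and signal-free exclusion
#' regions (vessels/ducts).
#'
#' @param frame_um frame size `c(w, h)` in micrometers.
#' @param pixel_size micrometers per pixel.
#' @param n_islets target number of islets.
#' @param median_cells,sdlog log-normal islet size distribution (cells per
#'   islet; median 8 and log-sd 1.2 span singlets to hundreds of cells at
#'   the default frame).
#' @param clustering `"uniform"` or `"clustered"`.
#' @param n_clusters,cluster_sd_um islet-rich clustering: cluster count and
#'   Gaussian dispersion of islet centers around each cluster.
#' @param hormones hormone channel names; cell types carry the same names.
#' @param baseline_fractions composition at the median islet size (named,
#'   summing to 1); the default 0.8/0.15/0.05 matches beta-dominant human
#'   islets.
#' @param alpha_slope increase of the second (alpha) fraction per decade of
#'   islet size (taken from the beta fraction), reproducing the
#'   size-dependent architecture of human islets.
#' @param cell_radius_um cytoplasm disc radius; the default 7.53 um gives the
#'   178 um^2 nominal single-cell area.
#' @param nucleus_radius_um nucleus disc radius (< cell radius).
#' @param spacing_factor cell center spacing as a fraction of one cell
#'   diameter; 0.95 leaves cytoplasm discs connected, 0.9 gives ~10% overlap.
#' @param islet_gap_um minimum gap between islet boundaries (must exceed
#'   twice the islet-closing radius for count-exact recovery).
#' @param signal_level,background_level,gradient_amplitude,noise_sd intensity
#'   model (arbitrary 16-bit units): rendered signal, flat background, linear
#'   gradient amplitude, Gaussian noise sd. `noise_sd = 20` is 10% of the
#'   default signal.
#' @param exocrine_nuclei_per_mm2 density of hormone-negative nuclei outside
#'   islets.
#' @param n_exclusions,exclusion_radius_um signal-free exclusion regions
#'   (count and radius range), all large enough to trigger the exclusion
#'   rule.
#' @param margin_um inset of the pancreas outline from the frame edge.
#' @param seed RNG seed; all draws flow from it.
#' @return validated list of class `synth_params`.
#' @export
synth_params <- function(frame_um = c(2000, 2000), pixel_size = 1,
                         n_islets = 60, median_cells = 8, sdlog = 1.2,
                         clustering = c("uniform", "clustered"),
                         n_clusters = 3, cluster_sd_um = 150,
                         hormones = c("insulin", "glucagon", "somatostatin"),
                         baseline_fractions = NULL, alpha_slope = 0.08,
                         cell_radius_um = 7.53, nucleus_radius_um = 3.2,
                         spacing_factor = 0.95, islet_gap_um = 25,
                         signal_level = 200, background_level = 10,
                         gradient_amplitude = 20, noise_sd = 5,
                         exocrine_nuclei_per_mm2 = 400,
                         n_exclusions = 2, exclusion_radius_um = c(100, 200),
                         margin_um = 40, seed = 1) {
  clustering <- match.arg(clustering)
  if (is.null(baseline_fractions)) {
    baseline_fractions <- switch(as.character(length(hormones)),
      "1" = c(1), "2" = c(0.85, 0.15), "3" = c(0.8, 0.15, 0.05),
      "4" = c(0.75, 0.15, 0.05, 0.05), stop("1-4 hormones supported"))
    names(baseline_fractions) <- hormones
  }
  stopifnot(length(baseline_fractions) == length(hormones),
            all(baseline_fractions >= 0),
            abs(sum(baseline_fractions) - 1) < 1e-9,
            nucleus_radius_um < cell_radius_um,
            pixel_size > 0, all(frame_um > 0), median_cells >= 1,
            sdlog >= 0, spacing_factor > 0, noise_sd >= 0,
            signal_level > background_level)
  if (is.null(names(baseline_fractions))) names(baseline_fractions) <- hormones
  p <- list(frame_um = frame_um, pixel_size = pixel_size, n_islets = n_islets,
            median_cells = median_cells, sdlog = sdlog,
            clustering = clustering, n_clusters = n_clusters,
            cluster_sd_um = cluster_sd_um, hormones = hormones,
            baseline_fractions = baseline_fractions, alpha_slope = alpha_slope,
            cell_radius_um = cell_radius_um,
            nucleus_radius_um = nucleus_radius_um,
            spacing_factor = spacing_factor, islet_gap_um = islet_gap_um,
            signal_level = signal_level, background_level = background_level,
            gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
            exocrine_nuclei_per_mm2 = exocrine_nuclei_per_mm2,
            n_exclusions = n_exclusions,
            exclusion_radius_um = exclusion_radius_um,
            margin_um = margin_um, seed = seed)
  class(p) <- "synth_params"
  p
}

# composition fractions for islets of n cells (rows) over the hormone types
composition_fractions <- function(n_cells, params) {
  base <- params$baseline_fractions
  k <- length(base)
  f <- matrix(rep(base, each = length(n_cells)), ncol = k,
              dimnames = list(NULL, names(base)))
  if (k >= 2L && params$alpha_slope != 0) {
    shift <- params$alpha_slope * (log10(n_cells) - log10(params$median_cells))
    # alpha (second type) gains with size at the expense of beta (first type)
    shift <- pmax(pmin(shift, f[, 1L] - 0.05), -f[, 2L] + 1e-6)
    f[, 1L] <- f[, 1L] - shift
    f[, 2L] <- f[, 2L] + shift
  }
  f <- pmax(f, 0)
  f / rowSums(f)
}

#' Islet population without spatial rendering
#'
#' The statistical layer of the generator: log-normal islet sizes and
#' size-dependent per-cell type draws, without placing or rasterizing
#' anything. Useful for testing analytics and selection estimators at large
#' N cheaply.
#'
#' @param params a [synth_params()] object.
#' @param n_islets number of islets (default `params$n_islets`).
#' @return islet table with `islet_id`, `n_cells`, `count_<type>` columns and
#'   nominal `total_islet_area_um2` / `endocrine_area_um2` (cells x the
#'   single-cell disc area).
#' @export
generate_islet_population <- function(params = synth_params(),
                                      n_islets = params$n_islets) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(params$seed)
  sample_islet_population(params, n_islets)
}

sample_islet_population <- function(params, n_islets) {
  n_cells <- pmax(1L, round(stats::rlnorm(n_islets, log(params$median_cells),
                                          params$sdlog)))
  fr <- composition_fractions(n_cells, params)
  types <- params$hormones
  counts <- matrix(0L, n_islets, length(types),
                   dimnames = list(NULL, types))
  cell_types <- vector("list", n_islets)
  for (i in seq_len(n_islets)) {
    tp <- sample(types, n_cells[i], replace = TRUE, prob = fr[i, ])
    cell_types[[i]] <- tp
    tb <- table(factor(tp, levels = types))
    counts[i, ] <- as.integer(tb)
  }
  cell_area <- pi * params$cell_radius_um^2
  out <- data.frame(islet_id = seq_len(n_islets), n_cells = n_cells)
  for (tp in types) out[[paste0("count_", tp)]] <- counts[, tp]
  out$total_islet_area_um2 <- n_cells * cell_area
  out$endocrine_area_um2 <- n_cells * cell_area
  attr(out, "cell_types") <- cell_types
  out
}

# hexagonal cell-center layout: n points closest to the origin on a hex
# lattice with the given spacing
hex_layout <- function(n, spacing) {
  if (n == 1L) return(cbind(x = 0, y = 0))
  m <- ceiling(sqrt(n)) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- (ij$i + ij$j / 2) * spacing
  y <- ij$j * spacing * sqrt(3) / 2
  d <- x^2 + y^2
  ord <- order(d, x, y)[seq_len(n)]
  cbind(x = x[ord], y = y[ord])
}

#' Generate a synthetic pancreas section with full ground truth
#'
#' Deterministic given `params$seed`. Islet centers are drawn from the chosen
#' point process, cells are packed hexagonally inside each islet, each cell's
#' cytoplasm disc is rendered into its hormone channel and its nucleus into
#' the nuclei channel, a smooth background gradient and Gaussian noise are
#' added, intensities are quantized to integers, and exclusion regions are
#' blanked and reported as contour polygons.
#'
#' @param params a [synth_params()] object.
#' @return list with `section` ([section_image]), `contours` ([contour_set])
#'   and `truth` (ground-truth list: `cells`, `islets`, noise-free
#'   `signal_masks`, exact areas and percent endocrine area).
#' @export
generate_section <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(params$seed)

  px <- params$pixel_size
  w_px <- round(params$frame_um[1L] / px)
  h_px <- round(params$frame_um[2L] / px)
  W <- w_px * px; H <- h_px * px
  margin <- params$margin_um
  rc <- params$cell_radius_um
  rn <- params$nucleus_radius_um
  spacing <- 2 * rc * params$spacing_factor

  pop <- sample_islet_population(params, params$n_islets)
  cell_types <- attr(pop, "cell_types")

  # per-islet local cell layouts and radii
  layouts <- lapply(pop$n_cells, hex_layout, spacing = spacing)
  radius <- vapply(layouts, function(l) sqrt(max(l[, 1L]^2 + l[, 2L]^2)) + rc,
                   numeric(1))

  # exclusion discs (as polygons), kept near the frame center-free zone
  excl <- list()
  excl_centers <- matrix(numeric(0), 0L, 3L)
  for (e in seq_len(params$n_exclusions)) {
    r <- stats::runif(1, params$exclusion_radius_um[1L],
                      params$exclusion_radius_um[2L])
    r <- min(r, (min(W, H) - 2 * margin) / 2 - 10)  # must fit the outline
    for (try in seq_len(200L)) {
      cx <- stats::runif(1, margin + r, W - margin - r)
      cy <- stats::runif(1, margin + r, H - margin - r)
      if (nrow(excl_centers) == 0L ||
          all(sqrt((excl_centers[, 1L] - cx)^2 + (excl_centers[, 2L] - cy)^2) >
              excl_centers[, 3L] + r + 20)) break
    }
    excl_centers <- rbind(excl_centers, c(cx, cy, r))
    th <- seq(0, 2 * pi, length.out = 25L)[-25L]
    excl[[e]] <- cbind(x = (cx + r * cos(th)) / px,
                       y = (cy + r * sin(th)) / px)
  }

  # islet placement: uniform or clustered, respecting gaps and exclusions
  if (params$clustering == "clustered") {
    cl_r <- 2.5 * params$cluster_sd_um
    clusters <- cbind(stats::runif(params$n_clusters, margin + cl_r, W - margin - cl_r),
                      stats::runif(params$n_clusters, margin + cl_r, H - margin - cl_r))
  }
  ord <- order(-radius)                       # place large islets first
  centers <- matrix(NA_real_, params$n_islets, 2L)
  placed <- logical(params$n_islets)
  for (i in ord) {
    r_i <- radius[i]
    ok <- FALSE
    for (try in seq_len(500L)) {
      if (params$clustering == "clustered" && try <= 400L) {
        ci <- ((i - 1L) %% params$n_clusters) + 1L
        cx <- clusters[ci, 1L] + stats::rnorm(1, 0, params$cluster_sd_um)
        cy <- clusters[ci, 2L] + stats::rnorm(1, 0, params$cluster_sd_um)
        if (sqrt((cx - clusters[ci, 1L])^2 + (cy - clusters[ci, 2L])^2) >
            2.5 * params$cluster_sd_um) next
      } else {
        cx <- stats::runif(1, margin + r_i + 2, W - margin - r_i - 2)
        cy <- stats::runif(1, margin + r_i + 2, H - margin - r_i - 2)
      }
      if (cx < margin + r_i + 2 || cx > W - margin - r_i - 2 ||
          cy < margin + r_i + 2 || cy > H - margin - r_i - 2) next
      if (any(placed)) {
        dmin <- sqrt((centers[placed, 1L] - cx)^2 + (centers[placed, 2L] - cy)^2)
        if (any(dmin < radius[placed] + r_i + params$islet_gap_um)) next
      }
      if (nrow(excl_centers) > 0L &&
          any(sqrt((excl_centers[, 1L] - cx)^2 + (excl_centers[, 2L] - cy)^2) <
              excl_centers[, 3L] + r_i + 15)) next
      ok <- TRUE
      break
    }
    if (!ok) next                              # overcrowded: skip this islet
    centers[i, ] <- c(cx, cy)
    placed[i] <- TRUE
  }

  # drop unplaced islets and renumber
  keep <- which(placed)
  pop <- pop[keep, , drop = FALSE]
  pop$islet_id <- seq_len(nrow(pop))
  layouts <- layouts[keep]
  cell_types <- cell_types[keep]
  radius <- radius[keep]
  centers <- centers[keep, , drop = FALSE]

  # cell table (jitter small enough to preserve spacing guarantees)
  cells <- do.call(rbind, lapply(seq_len(nrow(pop)), function(i) {
    l <- layouts[[i]]
    jit <- matrix(stats::runif(2L * nrow(l), -0.02, 0.02) * spacing,
                  ncol = 2L)
    data.frame(islet_id = i,
               x_um = centers[i, 1L] + l[, 1L] + jit[, 1L],
               y_um = centers[i, 2L] + l[, 2L] + jit[, 2L],
               type = cell_types[[i]])
  }))
  if (is.null(cells)) cells <- data.frame(islet_id = integer(0),
                                          x_um = numeric(0), y_um = numeric(0),
                                          type = character(0))
  cells$cell_id <- seq_len(nrow(cells))

  # exocrine (hormone-negative) nuclei, away from islets and exclusions
  area_mm2 <- (W - 2 * margin) * (H - 2 * margin) / 1e6
  n_exo <- stats::rpois(1, params$exocrine_nuclei_per_mm2 * area_mm2)
  if (n_exo > 0L) {
    ex <- cbind(stats::runif(n_exo, margin + rn + 2, W - margin - rn - 2),
                stats::runif(n_exo, margin + rn + 2, H - margin - rn - 2))
    ok <- rep(TRUE, n_exo)
    for (i in seq_len(nrow(pop)))
      ok <- ok & (sqrt((ex[, 1L] - centers[i, 1L])^2 +
                         (ex[, 2L] - centers[i, 2L])^2) > radius[i] + rc + 3)
    for (k in seq_len(nrow(excl_centers)))
      ok <- ok & (sqrt((ex[, 1L] - excl_centers[k, 1L])^2 +
                         (ex[, 2L] - excl_centers[k, 2L])^2) >
                    excl_centers[k, 3L] + rn + 3)
    exo <- ex[ok, , drop = FALSE]
  } else exo <- matrix(numeric(0), 0L, 2L)

  # rasterize signal masks (linear-index accumulation avoids matrix copies)
  blank <- matrix(FALSE, h_px, w_px)
  signal <- stats::setNames(rep(list(blank), length(params$hormones)),
                            params$hormones)
  nuc_idx <- vector("list", nrow(cells) + nrow(exo))
  for (tp in params$hormones) {
    rows <- which(cells$type == tp)
    if (length(rows)) {
      idx <- lapply(rows, function(i)
        disk_indices(cells$x_um[i], cells$y_um[i], rc, px, h_px, w_px))
      m <- blank
      m[unlist(idx)] <- TRUE
      signal[[tp]] <- m
    }
  }
  for (i in seq_len(nrow(cells)))
    nuc_idx[[i]] <- disk_indices(cells$x_um[i], cells$y_um[i], rn, px,
                                 h_px, w_px)
  for (i in seq_len(nrow(exo)))
    nuc_idx[[nrow(cells) + i]] <- disk_indices(exo[i, 1L], exo[i, 2L], rn, px,
                                               h_px, w_px)
  nuc_mask <- blank
  nuc_mask[unlist(nuc_idx)] <- TRUE

  # blank exclusions out of every signal mask
  if (length(excl)) {
    excl_mask <- rasterize_polygons(excl, h_px, w_px)
    signal <- lapply(signal, function(m) m & !excl_mask)
    nuc_mask <- nuc_mask & !excl_mask
  } else excl_mask <- blank

  # intensity model: background + linear gradient + signal + noise, quantized
  gx <- matrix(rep(seq_len(w_px) - 0.5, each = h_px), h_px, w_px) / w_px
  gy <- matrix(rep(seq_len(h_px) - 0.5, times = w_px), h_px, w_px) / h_px
  base <- params$background_level + params$gradient_amplitude * (gx + gy) / 2
  render <- function(mask) {
    img <- base + params$signal_level * mask
    if (params$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$noise_sd)
    img[excl_mask] <- 0
    matrix(pmin(65535, pmax(0, round(img))), h_px, w_px)
  }
  channels <- c(lapply(signal, render), list(nuclei = render(nuc_mask)))
  section <- section_image(channels, pixel_size = px)

  outline <- cbind(x = c(margin, W - margin, W - margin, margin) / px,
                   y = c(margin, margin, H - margin, H - margin) / px)
  contours <- contour_set(list(outline), excl)

  tissue_px <- rasterize_polygon(outline, h_px, w_px) & !excl_mask
  px2 <- px^2
  hormone_area <- vapply(signal, function(m) sum(m) * px2, numeric(1))
  endo_area <- sum(Reduce(`|`, signal)) * px2
  truth <- list(
    cells = cells[, c("cell_id", "islet_id", "x_um", "y_um", "type")],
    islets = cbind(pop,
                   x_um = centers[, 1L], y_um = centers[, 2L],
                   radius_um = radius),
    exocrine_nuclei = data.frame(x_um = exo[, 1L], y_um = exo[, 2L]),
    signal_masks = c(signal, list(nuclei = nuc_mask)),
    exclusion_mask = excl_mask,
    pancreas_area_um2 = sum(tissue_px) * px2,
    hormone_area_um2 = hormone_area,
    endocrine_area_um2 = endo_area,
    percent_endocrine = 100 * endo_area / (sum(tissue_px) * px2),
    clusters = if (params$clustering == "clustered") clusters else NULL,
    params = params)
  list(section = section, contours = contours, truth = truth)
}

# linear indices of pixels whose center lies within r of (cx, cy); units um
disk_indices <- function(cx, cy, r, px, h, w) {
  x0 <- max(1L, floor(cx / px - r / px)); x1 <- min(w, ceiling(cx / px + r / px) + 1L)
  y0 <- max(1L, floor(cy / px - r / px)); y1 <- min(h, ceiling(cy / px + r / px) + 1L)
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- ((x0:x1) - 0.5) * px
  ys <- ((y0:y1) - 0.5) * px
  dd <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  hit <- which(dd <= r^2, arr.ind = TRUE)
  (hit[, 2L] + x0 - 2L) * h + hit[, 1L] + y0 - 1L
}

#' Reference answer sheet for a generated section
#'
#' Summarizes the ground truth in the same shape as [section_summary()], so
#' pipeline output can be scored against it.
#'
#' @param truth the `truth` element of [generate_section()].
#' @return object of class `section_summary` built from ground truth.
#' @export
truth_summary <- function(truth) {
  counts <- truth$islets[, grep("^count_", names(truth$islets)), drop = FALSE]
  structure(list(
    pancreas_area_um2 = truth$pancreas_area_um2,
    hormone_area_um2 = truth$hormone_area_um2,
    endocrine_area_um2 = truth$endocrine_area_um2,
    total_islet_area_um2 = sum(truth$islets$total_islet_area_um2),
    percent_endocrine = truth$percent_endocrine,
    islet_count = nrow(truth$islets),
    cell_counts = colSums(counts),
    islets = truth$islets), class = "section_summary")
}

#' Synthetic organ blocks for block-selection simulations
#'
#' Emulates the regional endocrine-density profile of a whole pancreas: mean
#' percent endocrine area in head : body : tail of roughly 1 : 1 : 2, with
#' log-normal block-to-block variation.
#'
#' @param n_blocks blocks per region `c(head, body, tail)`.
#' @param region_density mean percent endocrine area per region.
#' @param block_area_um2 mean block section area.
#' @param sdlog log-sd of block-to-block density variation.
#' @param seed RNG seed.
#' @return data frame usable with [block_selection_estimates()].
#' @export
generate_organ_blocks <- function(n_blocks = c(head = 7, body = 7, tail = 7),
                                  region_density = c(head = 0.8, body = 0.8,
                                                     tail = 1.6),
                                  block_area_um2 = 3e8, sdlog = 0.25,
                                  seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  region <- rep(c("head", "body", "tail"), times = n_blocks)
  n <- length(region)
  area <- stats::rlnorm(n, log(block_area_um2), 0.15)
  dens <- region_density[region] * stats::rlnorm(n, 0, sdlog)
  data.frame(block = seq_len(n), region = region,
             pancreas_area_um2 = area,
             endocrine_area_um2 = area * dens / 100)
}

#' Synthetic within-block section series
#'
#' Percent endocrine areas of consecutive sections cut from one block:
#' a constant true fraction plus independent measurement noise.
#'
#' @param n_sections number of sections.
#' @param true_percent underlying percent endocrine area.
#' @param noise_sd measurement noise sd (percentage points).
#' @param seed RNG seed.
#' @return numeric vector of section percent values.
#' @export
generate_block_sections <- function(n_sections = 301, true_percent = 1,
                                    noise_sd = 0.02, seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  pmax(0, true_percent + stats::rnorm(n_sections, 0, noise_sd))
}
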