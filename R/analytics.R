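#' Cell-equivalent islet size
#'
#' Islet area divided by the nominal single-cell area (178 um^2), giving a
#' dimensionless proxy for the number of cells in the islet.
#'
#' @param islet_area_um2 islet area(s), um^2.
#' @param single_cell_area_um2 nominal endocrine cell area (default 178).
#' @return dimensionless cell-equivalent size(s).
#' @export
cell_equivalents <- function(islet_area_um2, single_cell_area_um2 = 178) {
  if (single_cell_area_um2 <= 0) stop("'single_cell_area_um2' must be positive")
  islet_area_um2 / single_cell_area_um2
}

#' Effective diameter of an islet
#'
#' Diameter of the circle with the same area, `2 * sqrt(area / pi)`; the
#' axis conversion used alongside logarithmic islet size.
#'
#' @param area_um2 islet area(s), um^2.
#' @return diameter(s) in micrometers.
#' @export
effective_diameter <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Log-binned islet size histogram with composition and area fractions
#'
#' Islet sizes in cell-equivalents are binned on a log10 scale (bin index =
#' `floor(log10(size) / bin_width)`), giving fine bins for the many small
#' islets and wide bins for the few large ones. Each bin reports the islet
#' count, the mean +/- SEM of each cell-type fraction (each islet is one
#' sample), and the bin's share of total islet area.
#'
#' @param islets islet table with `count_<type>` columns and an area column.
#' @param bin_width bin width in log10 units (default 0.25).
#' @param area_column which area drives the size axis; the filled
#'   `total_islet_area_um2` by default.
#' @param single_cell_area_um2 cell-equivalent conversion constant.
#' @param types cell types (default: `count_` columns except unclassified).
#' @return data frame, one row per occupied bin: `bin`, `log10_lo`,
#'   `log10_hi`, `n_islets`, `area_um2`, `area_fraction`, and per type
#'   `frac_<type>` / `sem_<type>`. Islets with zero counted cells contribute
#'   to counts and area but not to composition means; their number is in
#'   attribute `n_no_cells`.
#' @export
log_size_histogram <- function(islets, bin_width = 0.25,
                               area_column = "total_islet_area_um2",
                               single_cell_area_um2 = 178, types = NULL) {
  area <- islets[[area_column]]
  if (any(area <= 0)) stop("all islet areas must be positive")
  if (is.null(types))
    types <- setdiff(sub("^count_", "", grep("^count_", names(islets),
                                             value = TRUE)), "unclassified")
  ce <- cell_equivalents(area, single_cell_area_um2)
  bin <- floor(log10(ce) / bin_width)
  bins <- sort(unique(bin))
  cnt <- as.matrix(islets[, paste0("count_", types), drop = FALSE])
  tot <- rowSums(cnt)
  frac <- cnt / ifelse(tot > 0, tot, NA)
  out <- data.frame(bin = bins,
                    log10_lo = bins * bin_width,
                    log10_hi = (bins + 1) * bin_width)
  out$n_islets <- vapply(bins, function(b) sum(bin == b), integer(1))
  out$area_um2 <- vapply(bins, function(b) sum(area[bin == b]), numeric(1))
  out$area_fraction <- out$area_um2 / sum(area)
  for (j in seq_along(types)) {
    mu <- se <- rep(NA_real_, length(bins))
    for (k in seq_along(bins)) {
      f <- frac[bin == bins[k], j]
      f <- f[!is.na(f)]
      if (length(f)) {
        mu[k] <- mean(f)
        se[k] <- if (length(f) > 1L) stats::sd(f) / sqrt(length(f)) else 0
      }
    }
    out[[paste0("frac_", types[j])]] <- mu
    out[[paste0("sem_", types[j])]] <- se
  }
  attr(out, "n_no_cells") <- sum(tot == 0)
  attr(out, "bin_width") <- bin_width
  out
}

#' Size/shape scatter with local density coding
#'
#' One point per islet in (log10 cell-equivalent area, circularity, Feret)
#' space. Each axis is standardized (z-score) and the density score of a
#' point is the inverse mean Euclidean distance to its `k_neighbors` nearest
#' neighbours, so dense clouds of similar islets score high and isolated
#' large islets score low.
#'
#' @param islets islet table with `total_islet_area_um2`, `circularity`,
#'   `feret_um` (and optionally `contains_pp`).
#' @param k_neighbors neighbours used for the density score (default 10; for
#'   N <= k, N - 1 are used).
#' @param single_cell_area_um2 cell-equivalent conversion constant.
#' @return data frame `islet_id`, `log10_size`, `circularity`, `feret_um`,
#'   `density`, plus `contains_pp` when present.
#' @export
shape_scatter <- function(islets, k_neighbors = 10,
                          single_cell_area_um2 = 178) {
  n <- nrow(islets)
  if (n < 1L) stop("need at least one islet")
  out <- data.frame(
    islet_id = islets$islet_id,
    log10_size = log10(cell_equivalents(islets$total_islet_area_um2,
                                        single_cell_area_um2)),
    circularity = islets$circularity,
    feret_um = islets$feret_um)
  if (n == 1L) {
    out$density <- 0
    attr(out, "single_record") <- TRUE
    return(out)
  }
  z <- scale(as.matrix(out[, c("log10_size", "circularity", "feret_um")]))
  z[, apply(is.na(z) | is.nan(z), 2L, any)] <- 0   # constant axes carry no information
  dm <- as.matrix(stats::dist(z))
  k <- min(k_neighbors, n - 1L)
  # a tiny floor keeps the score finite for coincident points
  out$density <- vapply(seq_len(n), function(i) {
    nn <- sort(dm[i, -i])[seq_len(k)]
    1 / (mean(nn) + 1e-12)
  }, numeric(1))
  if (!is.null(islets$contains_pp)) out$contains_pp <- islets$contains_pp
  out
}

#' Flag islets containing pancreatic-polypeptide cells
#'
#' @param islets islet table with cell counts.
#' @param min_pp_cells minimum PP-cell count to flag (default 1).
#' @param pp_type name of the PP count column suffix (default `"pp"`).
#' @return the islet table with a logical `contains_pp` column; when no PP
#'   channel was configured all islets are `FALSE` with a warning.
#' @export
flag_pp_islets <- function(islets, min_pp_cells = 1, pp_type = "pp") {
  col <- paste0("count_", pp_type)
  if (is.null(islets[[col]])) {
    warning("no '", pp_type, "' cell counts present; flagging all islets FALSE")
    islets$contains_pp <- rep(FALSE, nrow(islets))
  } else {
    islets$contains_pp <- islets[[col]] >= min_pp_cells
  }
  islets
}

#' Plot the islet size histogram with the area-fraction curve
#'
#' Gray bars: fraction of islets per log-size bin; red line: fraction of
#' total islet area per bin.
#'
#' @param hist result of [log_size_histogram()].
#' @export
plot_size_histogram <- function(hist) {
  mids <- (hist$log10_lo + hist$log10_hi) / 2
  counts <- hist$n_islets / sum(hist$n_islets)
  graphics::barplot(counts, names.arg = sprintf("%.2f", mids),
                    col = "gray70", border = NA,
                    xlab = "log10 islet size (cell equivalents)",
                    ylab = "fraction")
  at <- seq_along(mids) * 1.2 - 0.5
  graphics::lines(at, hist$area_fraction, col = "red", lwd = 2)
  graphics::points(at, hist$area_fraction, col = "red", pch = 16)
  invisible(NULL)
}
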