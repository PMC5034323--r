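test_that("make_grid lays a lattice strictly inside the frame", {
  g <- make_grid(c(100, 100), 25)
  expect_equal(g$n_total, 16)
  expect_equal(sort(unique(g$vertices$x_um)), c(0, 25, 50, 75))
  g2 <- make_grid(c(100, 100), 25, offset_um = c(12.5, 12.5))
  expect_equal(g2$n_total, 16)
  expect_equal(sort(unique(g2$vertices$x_um)), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(make_grid(c(10, 10), 50)$n_total, 1)
  expect_equal(make_grid(c(10, 10), 50, offset_um = c(20, 0))$n_total, 0)
  expect_error(make_grid(c(10, 10), 0), "positive")
})

test_that("point counting is the positive-vertex fraction", {
  m <- matrix(TRUE, 20, 20)
  g <- make_grid(c(20, 20), 5)
  pc <- point_count_estimate(m, g, 1)
  expect_equal(pc$percent, 100)
  half <- matrix(FALSE, 20, 20); half[, 1:10] <- TRUE   # left half positive
  g2 <- make_grid(c(20, 20), 5, offset_um = c(2.5, 2.5))
  pc2 <- point_count_estimate(half, g2, 1)
  expect_equal(pc2$percent, 50)
  expect_error(point_count_estimate(m, make_grid(c(5, 5), 50, c(20, 0)), 1),
               "empty")
})

test_that("a 30-of-945 grid gives 100*30/945 percent, 3.17 at two decimals", {
  # 27 x 35 vertices at 25 um spacing
  frame <- c(27 * 25, 35 * 25)
  g <- make_grid(frame, 25, offset_um = c(12.5, 12.5))
  expect_equal(g$n_total, 945)
  mask <- matrix(FALSE, frame[2], frame[1])
  v <- g$vertices[order(g$vertices$y_um, g$vertices$x_um), ]
  hit <- v[seq_len(30), ]
  mask[cbind(floor(hit$y_um) + 1, floor(hit$x_um) + 1)] <- TRUE
  pc <- point_count_estimate(mask, g, 1)
  expect_equal(pc$n_positive, 30)
  expect_equal(pc$percent, 100 * 30 / 945)
  expect_equal(pc$percent_rounded, 3.17)
})

test_that("panels tile the frame and rank by content", {
  panels <- make_panels(c(100, 80), 1, panel_um = c(30, 25))
  p <- panels$panels
  cover <- matrix(0L, 80, 100)
  for (i in seq_len(nrow(p)))
    cover[(p$y0[i] + 1):p$y1[i], (p$x0[i] + 1):p$x1[i]] <-
      cover[(p$y0[i] + 1):p$y1[i], (p$x0[i] + 1):p$x1[i]] + 1L
  expect_true(all(cover == 1L))
  mask <- matrix(FALSE, 80, 100); mask[40:60, 40:60] <- TRUE
  ord <- rank_panels(panels, mask)
  cnt <- panel_counts(panels, mask)
  expect_equal(ord[1], which.max(cnt))
  # equal content everywhere (exact tiling, all positive): index order
  even <- make_panels(c(100, 80), 1, panel_um = c(25, 20))
  expect_equal(rank_panels(even, matrix(TRUE, 80, 100)),
               even$panels$panel_id)
  # random mask: ordering equals brute-force stable sort
  set.seed(4)
  rnd <- matrix(runif(8000) < 0.2, 80, 100)
  cnt2 <- panel_counts(panels, rnd)
  expect_equal(rank_panels(panels, rnd), order(-cnt2, p$panel_id))
})

test_that("selection curve reproduces the whole-section estimate at full k", {
  g <- std_section()
  res <- fixture("std_result", function() {
    g <- std_section()
    quantify_section(g$section, g$contours, manual_cfg(g$params))
  })
  endo <- composite_endocrine_mask(res$masks[g$section$hormones])
  panels <- make_panels(rep(900, 2), 1, panel_um = c(150, 150))
  ord <- rank_panels(panels, endo)
  curve <- selection_curve(panels, ord, endo, res$tissue)
  ref <- attr(curve, "reference")
  expect_identical(curve$percent[nrow(curve)], ref)
  expect_gte(max(curve$percent, na.rm = TRUE), ref)
  # uniform content: curve constant at the reference
  u <- matrix(FALSE, 80, 100); u[, ] <- rep(c(TRUE, FALSE), 4000)
  up <- make_panels(c(100, 80), 1, panel_um = c(20, 20))
  uc <- selection_curve(up, rank_panels(up, u), u, matrix(TRUE, 80, 100))
  expect_true(all(abs(uc$percent - attr(uc, "reference")) < 1e-9))
})

test_that("every_nth_section subsamples deterministically", {
  pct <- generate_block_sections(301, true_percent = 1, noise_sd = 0.02,
                                 seed = 2)
  sel <- every_nth_section(pct, 50)
  expect_length(sel$percent, 7)
  expect_equal(sel$indices, seq(1, 301, by = 50))
  expect_equal(every_nth_section(pct, 1)$percent, pct)
  noiseless <- every_nth_section(generate_block_sections(301, 1, 0, seed = 2), 50)
  expect_equal(diff(noiseless$range), 0)
  expect_lt(diff(sel$range), diff(range(pct)) + 1e-12)
  expect_error(every_nth_section(numeric(0)), "empty")
})

test_that("block selection schemes bracket the truth and expose regional bias", {
  blocks <- generate_organ_blocks(seed = 3)
  all <- block_selection_estimates(blocks, "all")
  expect_equal(all$fold, 1)
  singles <- block_selection_estimates(blocks, "single_block")
  expect_equal(nrow(singles), nrow(blocks))
  expect_lt(min(singles$fold), 1)
  expect_gt(max(singles$fold), 1)
  # tail density is twice head: tail-only overestimates
  tail_only <- block_selection_estimates(blocks, "region_only", region = "tail")
  expect_gt(tail_only$fold, 1)
  head_only <- block_selection_estimates(blocks, "region_only", region = "head")
  expect_lt(head_only$fold, tail_only$fold)
  opr <- block_selection_estimates(blocks, "one_per_region")
  expect_equal(nrow(opr), prod(table(blocks$region)))
  rk <- block_selection_estimates(blocks, "random_k", k = 3, replicates = 5,
                                  seed = 9)
  expect_equal(nrow(rk), 5)
  rk2 <- block_selection_estimates(blocks, "random_k", k = 3, replicates = 5,
                                   seed = 9)
  expect_identical(rk, rk2)
})

test_that("largest-N ratios equal all-islet ratios when N covers everything", {
  pop <- generate_islet_population(synth_params(seed = 5), n_islets = 40)
  r <- largest_n_ratios(pop, n = 1000)
  expect_true(all(r$fold[!r$undefined] == 1))
  pure <- pop
  pure$count_glucagon <- 0L; pure$count_somatostatin <- 0L
  rp <- largest_n_ratios(pure, n = 10)
  expect_true(rp$undefined[rp$pair == "glucagon/somatostatin"])
})

test_that("size-dependent alpha fraction depresses the top-N beta/alpha ratio", {
  pop <- generate_islet_population(
    synth_params(seed = 21, alpha_slope = 0.12, sdlog = 1.3), n_islets = 600)
  r <- largest_n_ratios(pop, n = 100)
  ba <- r[r$pair == "insulin/glucagon", ]
  expect_lt(ba$top_ratio, ba$all_ratio)
  # brute-force cross-check of both pooled ratios
  ord <- order(-pop$total_islet_area_um2)
  top <- pop[ord[1:100], ]
  expect_equal(ba$top_ratio, sum(top$count_insulin) / sum(top$count_glucagon))
  expect_equal(ba$all_ratio, sum(pop$count_insulin) / sum(pop$count_glucagon))
})
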