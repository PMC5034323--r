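test_that("generation is deterministic given the seed", {
  p <- synth_params(frame_um = c(400, 400), n_islets = 4, seed = 23,
                    exocrine_nuclei_per_mm2 = 100, n_exclusions = 0)
  g1 <- generate_section(p)
  g2 <- generate_section(p)
  expect_identical(g1$section$channels, g2$section$channels)
  expect_identical(g1$truth$cells, g2$truth$cells)
  g3 <- generate_section(synth_params(frame_um = c(400, 400), n_islets = 4,
                                      seed = 24, exocrine_nuclei_per_mm2 = 100,
                                      n_exclusions = 0))
  expect_false(identical(g1$section$channels, g3$section$channels))
})

test_that("at zero noise, thresholding recovers the ground-truth masks exactly", {
  p <- synth_params(frame_um = c(500, 500), n_islets = 5, seed = 31,
                    noise_sd = 0, exocrine_nuclei_per_mm2 = 150,
                    n_exclusions = 1, exclusion_radius_um = c(60, 80))
  g <- generate_section(p)
  tissue <- build_tissue_mask(g$section, g$contours)
  for (h in p$hormones) {
    m <- binarize(g$section$channels[[h]], p$signal_level / 2, tissue)
    expect_equal(m, g$truth$signal_masks[[h]] & tissue$mask,
                 ignore_attr = TRUE)
  }
  # stained area equals truth (signal never falls inside applied exclusions)
  m <- binarize(g$section$channels$insulin, p$signal_level / 2, tissue)
  expect_equal(sum(m), sum(g$truth$signal_masks$insulin))
})

test_that("clustered mode concentrates islets around the cluster centers", {
  p <- synth_params(frame_um = c(1500, 1500), n_islets = 40, seed = 37,
                    clustering = "clustered", n_clusters = 3,
                    cluster_sd_um = 100, exocrine_nuclei_per_mm2 = 0,
                    n_exclusions = 0)
  g <- generate_section(p)
  cl <- g$truth$clusters
  within <- vapply(seq_len(nrow(g$truth$islets)), function(i) {
    d <- sqrt((cl[, 1] - g$truth$islets$x_um[i])^2 +
                (cl[, 2] - g$truth$islets$y_um[i])^2)
    min(d) <= 2.5 * p$cluster_sd_um
  }, logical(1))
  expect_gte(mean(within), 0.8)
})

test_that("truth summary is consistent bookkeeping", {
  g <- std_section()
  ts <- truth_summary(g$truth)
  expect_equal(ts$islet_count, nrow(g$truth$islets))
  expect_equal(sum(ts$cell_counts), nrow(g$truth$cells))
  expect_equal(ts$percent_endocrine,
               100 * ts$endocrine_area_um2 / ts$pancreas_area_um2)
  counts <- g$truth$islets[, paste0("count_", g$params$hormones)]
  expect_equal(unname(rowSums(counts)), g$truth$islets$n_cells)
})

test_that("islet size-composition model shows the configured alpha trend", {
  pop <- generate_islet_population(
    synth_params(seed = 41, alpha_slope = 0.12, sdlog = 1.3), n_islets = 1500)
  frac <- pop$count_glucagon / pop$n_cells
  fit <- stats::lm(frac ~ log10(pop$n_cells), weights = pop$n_cells)
  expect_gt(stats::coef(fit)[2], 0)
  pop0 <- generate_islet_population(
    synth_params(seed = 41, alpha_slope = -0.12, sdlog = 1.3), n_islets = 1500)
  fit0 <- stats::lm(count_glucagon / n_cells ~ log10(n_cells), data = pop0,
                    weights = pop0$n_cells)
  expect_lt(stats::coef(fit0)[2], 0)
})

test_that("synth_params validates its invariants", {
  expect_error(synth_params(nucleus_radius_um = 10, cell_radius_um = 8))
  expect_error(synth_params(pixel_size = -1))
  expect_error(synth_params(baseline_fractions = c(insulin = 0.9, glucagon = 0.5),
                            hormones = c("insulin", "glucagon")))
  expect_error(synth_params(signal_level = 5, background_level = 10))
})

test_that("organ blocks reproduce the 1:1:2 regional density profile", {
  blocks <- generate_organ_blocks(n_blocks = c(head = 30, body = 30, tail = 30),
                                  sdlog = 0.1, seed = 43)
  dens <- with(blocks, 100 * endocrine_area_um2 / pancreas_area_um2)
  m <- tapply(dens, blocks$region, mean)
  expect_equal(unname(m["tail"] / m["head"]), 2, tolerance = 0.2)
  expect_equal(unname(m["body"] / m["head"]), 1, tolerance = 0.2)
})
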