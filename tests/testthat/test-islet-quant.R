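disk_mask <- function(h, w, cx, cy, r) {
  outer(seq_len(h) - 0.5, seq_len(w) - 0.5,
        function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

test_that("composite mask is the pixelwise OR of hormone masks", {
  a <- matrix(FALSE, 20, 20); a[1:5, 1:10] <- TRUE     # 50 px
  b <- matrix(FALSE, 20, 20); b[10:14, 11:20] <- TRUE  # 50 px, disjoint
  expect_equal(sum(composite_endocrine_mask(list(a, b))), 100)
  expect_equal(composite_endocrine_mask(list(a, a)), a, ignore_attr = TRUE)
  set.seed(2)
  ms <- replicate(3, matrix(runif(400) < 0.3, 20, 20), simplify = FALSE)
  brute <- matrix(FALSE, 20, 20)
  for (i in seq_len(400)) brute[i] <- ms[[1]][i] || ms[[2]][i] || ms[[3]][i]
  expect_equal(composite_endocrine_mask(ms), brute, ignore_attr = TRUE)
  expect_error(composite_endocrine_mask(list()), "at least one")
  expect_error(composite_endocrine_mask(list(a, matrix(FALSE, 5, 5))),
               "mismatch")
})

test_that("8-connected labeling merges diagonals and numbers in raster order", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1          # diagonal contact: one component
  m[5, 5] <- 1
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(sort(unique(lab[lab > 0])), 1:2)
  # raster-scan numbering: component containing (2,2) first
  expect_equal(lab[2, 2], 1L)
})

test_that("segment_islets handles empty, solid and gap-bridged structures", {
  empty <- segment_islets(matrix(FALSE, 30, 30), 1)
  expect_equal(nrow(empty$islets), 0)
  solid <- disk_mask(40, 40, 20, 20, 10)
  s1 <- segment_islets(solid, 1, close_radius_um = 0)
  expect_equal(nrow(s1$islets), 1)
  expect_equal(s1$islets$endocrine_area_um2, s1$islets$total_islet_area_um2)
  # two small disks, 3 px gap, closing radius 2: merged into one islet
  two <- disk_mask(40, 60, 20, 20, 5) | disk_mask(40, 60, 33, 20, 5)
  s2 <- segment_islets(two, 1, close_radius_um = 2)
  expect_equal(nrow(s2$islets), 1)
  expect_gt(s2$islets$total_islet_area_um2, sum(two))
  # without closing they stay separate
  s3 <- segment_islets(two, 1, close_radius_um = 0)
  expect_equal(nrow(s3$islets), 2)
})

test_that("stained area is conserved across islet records", {
  set.seed(8)
  m <- matrix(runif(200 * 200) < 0.08, 200, 200)
  seg <- segment_islets(m, pixel_size = 0.8, close_radius_um = 4)
  expect_equal(sum(seg$islets$endocrine_area_um2), sum(m) * 0.8^2)
  # labels contiguous and deterministic
  expect_equal(sort(unique(as.vector(seg$labels[seg$labels > 0]))),
               seq_len(nrow(seg$islets)))
  seg2 <- segment_islets(m, pixel_size = 0.8, close_radius_um = 4)
  expect_identical(seg$labels, seg2$labels)
  expect_identical(seg$islets, seg2$islets)
})

test_that("min_area filters small structures", {
  m <- matrix(FALSE, 30, 30)
  m[5, 5] <- TRUE                       # singlet, 1 um^2
  m[15:20, 15:20] <- TRUE               # 36 um^2
  s <- segment_islets(m, 1, close_radius_um = 0, min_area_um2 = 10)
  expect_equal(nrow(s$islets), 1)
  s0 <- segment_islets(m, 1, close_radius_um = 0, min_area_um2 = 0)
  expect_equal(nrow(s0$islets), 2)
})

test_that("holes are annexed into total islet area but not stained area", {
  ring <- disk_mask(50, 50, 25, 25, 15) & !disk_mask(50, 50, 25, 25, 6)
  s <- segment_islets(ring, 1, close_radius_um = 0)
  expect_equal(nrow(s$islets), 1)
  expect_equal(s$islets$endocrine_area_um2, sum(ring))
  expect_equal(s$islets$total_islet_area_um2, sum(disk_mask(50, 50, 25, 25, 15)))
})

test_that("disk circularity rises toward 1 and square matches pi/4", {
  circ <- vapply(c(10, 30, 100), function(r) {
    m <- disk_mask(2 * r + 20, 2 * r + 20, r + 10, r + 10, r)
    seg <- segment_islets(m, 1, close_radius_um = 0)
    seg$islets$circularity
  }, numeric(1))
  expect_true(all(diff(circ) > 0))
  expect_gt(circ[3], 0.98)
  sq <- matrix(FALSE, 220, 220); sq[10:209, 10:209] <- TRUE
  seg <- segment_islets(sq, 1, close_radius_um = 0)
  expect_equal(seg$islets$circularity, pi / 4, tolerance = 0.03)
})

test_that("islet metrics report centroid and a Pythagorean feret", {
  m <- matrix(FALSE, 50, 50)
  m[1, 1] <- TRUE; m[41, 31] <- TRUE    # centers (0.5,0.5) and (30.5,40.5)
  lab <- label_components(m)
  lab[lab > 0] <- 1L                    # treat as one structure
  met <- islet_metrics(lab, 1, pixel_size = 1)
  expect_gte(met$feret_um, 50)
  expect_error(islet_metrics(lab, 99, 1), "absent")
  solid <- disk_mask(40, 40, 20.3, 17.2, 9)
  seg <- segment_islets(solid, 2, close_radius_um = 0)
  expect_equal(seg$islets$centroid_x_um, 20.3 * 2, tolerance = 0.05 * 40.6)
  expect_equal(seg$islets$centroid_y_um, 17.2 * 2, tolerance = 0.05 * 34.4)
  # feret >= effective diameter minus 2 px
  eff <- 2 * sqrt(seg$islets$total_islet_area_um2 / pi)
  expect_gte(seg$islets$feret_um, eff - 2 * 2)
})

test_that("percent_area is the normalized percentage", {
  expect_equal(percent_area(2, 100), 2)
  expect_equal(percent_area(0, 55), 0)
  expect_equal(percent_area(77, 77), 100)
  expect_error(percent_area(1, 0), "positive")
})
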