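disk_mask2 <- function(h, w, cx, cy, r) {
  outer(seq_len(h) - 0.5, seq_len(w) - 0.5,
        function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

test_that("nucleus watershed separates touching nuclei", {
  expect_equal(max(segment_nuclei(matrix(FALSE, 20, 20), 1)), 0)
  one <- disk_mask2(30, 30, 15, 15, 6)
  lab1 <- segment_nuclei(one, 1, min_separation_um = 5)
  expect_equal(max(lab1), 1)
  # two overlapping disks, centers 1.5 radii apart
  two <- disk_mask2(40, 50, 18, 20, 6) | disk_mask2(40, 50, 27, 20, 6)
  lab2 <- segment_nuclei(two, 1, min_separation_um = 5)
  expect_equal(max(lab2), 2)
  # partition: every foreground pixel gets exactly one label
  expect_equal(unname(lab2 > 0), unname(two))
})

test_that("perinuclear ring is the 1 px expansion minus all nucleus bodies", {
  lab <- matrix(0L, 9, 9); lab[5, 5] <- 1L
  ring <- nucleus_ring(lab, 1, width_px = 1)
  expect_equal(nrow(ring), 8)           # Moore neighborhood
  # nucleus at the image border: ring clipped, no error
  labb <- matrix(0L, 5, 5); labb[1, 1] <- 1L
  expect_equal(nrow(nucleus_ring(labb, 1)), 3)
  # adjacent nuclei: rings exclude both bodies
  lab2 <- matrix(0L, 9, 9); lab2[5, 4] <- 1L; lab2[5, 5] <- 2L
  r1 <- nucleus_ring(lab2, 1); r2 <- nucleus_ring(lab2, 2)
  bodies <- rbind(c(5, 4), c(5, 5))
  for (r in list(r1, r2))
    expect_equal(nrow(merge(as.data.frame(r),
                            data.frame(row = bodies[, 1], col = bodies[, 2]))), 0)
  expect_error(nucleus_ring(lab, 99), "absent")
})

test_that("classification follows the prevalent-signal rule with tie-breaks", {
  lab <- matrix(0L, 9, 9); lab[5, 5] <- 1L
  ring <- nucleus_ring(lab, 1)
  mk <- function(n_pos) {
    m <- matrix(FALSE, 9, 9)
    if (n_pos > 0) m[ring[seq_len(n_pos), , drop = FALSE]] <- TRUE
    m
  }
  masks <- list(insulin = mk(5), glucagon = mk(2), somatostatin = mk(0))
  cl <- classify_nucleus(ring, masks)
  expect_identical(cl$cell_type, "insulin")
  expect_equal(unname(cl$ring_votes), c(5, 2, 0))
  expect_false(cl$tie_flag)
  none <- classify_nucleus(ring, lapply(masks, function(m) m & FALSE))
  expect_identical(none$cell_type, "unclassified")
  tie <- classify_nucleus(ring, list(insulin = mk(3), glucagon = mk(3)))
  expect_identical(tie$cell_type, "insulin")
  expect_true(tie$tie_flag)
  tie2 <- classify_nucleus(ring, list(insulin = mk(3), glucagon = mk(3)),
                           priority = c("glucagon", "insulin"))
  expect_identical(tie2$cell_type, "glucagon")
  # fully suppressed ring -> unclassified and flagged empty
  sup <- classify_nucleus(ring[0, , drop = FALSE], masks)
  expect_identical(sup$cell_type, "unclassified")
  expect_true(sup$empty_ring)
})

test_that("nuclei are assigned to the islet under their centroid", {
  islet_labels <- matrix(0L, 40, 40)
  islet_labels[5:15, 5:15] <- 1L
  islet_labels[25:35, 25:35] <- 3L
  nuclei <- data.frame(nucleus_id = 1:3,
                       x_um = c(10, 30, 2) * 2,   # pixel 10, 30, 2 at 2 um/px
                       y_um = c(10, 30, 2) * 2,
                       cell_type = c("insulin", "glucagon", "insulin"))
  asg <- assign_to_islets(nuclei, islet_labels, pixel_size = 2)
  expect_equal(asg$nuclei$islet_id, c(1L, 3L, NA))
})

test_that("per-islet counts match planted ground truth on a synthetic section", {
  g <- std_section()
  res <- fixture("std_result", function() {
    g <- std_section()
    quantify_section(g$section, g$contours, manual_cfg(g$params))
  })
  truth <- g$truth
  idx <- match_islets(truth$islets, res$islets)
  expect_false(anyDuplicated(idx) > 0)
  for (tp in g$params$hormones) {
    expect_equal(res$islets[[paste0("count_", tp)]][idx],
                 truth$islets[[paste0("count_", tp)]])
  }
  # conservation: per-type counts + unclassified = total nuclei
  tot <- sum(table(res$nuclei$cell_type))
  expect_equal(tot, nrow(res$nuclei))
})
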