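# brute-force grayscale opening with a disc: erosion (min) then dilation (max)
brute_opening <- function(img, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  br <- EBImage::makeBrush(2 * radius + 1, "disc")
  offs <- offs[br[cbind(offs$dr + radius + 1, offs$dc + radius + 1)] > 0, ]
  nr <- nrow(img); nc <- ncol(img)
  slide <- function(x, fun, pad) {
    out <- matrix(pad, nr, nc)
    for (k in seq_len(nrow(offs))) {
      r <- seq_len(nr) + offs$dr[k]; c <- seq_len(nc) + offs$dc[k]
      vr <- r >= 1 & r <= nr; vc <- c >= 1 & c <= nc
      sub <- matrix(pad, nr, nc)
      sub[vr, vc] <- x[r[vr], c[vc]]
      out <- fun(out, sub)
    }
    out
  }
  er <- slide(img, pmin, pad = Inf)
  slide(er, pmax, pad = -Inf)
}

test_that("background subtraction removes flat and smooth backgrounds", {
  expect_equal(subtract_background(matrix(7, 30, 30), 5), matrix(0, 30, 30))
  img <- matrix(0, 41, 41); img[21, 21] <- 100
  out <- subtract_background(img, 15)
  expect_gt(out[21, 21], 99)
  expect_error(subtract_background(img, 0), ">= 1")
})

test_that("background subtraction equals image minus brute-force opening", {
  set.seed(5)
  img <- matrix(runif(30 * 28, 0, 50), 30, 28) +
    outer(seq_len(30), seq_len(28), function(r, c) r + 0.5 * c)
  img[10:12, 10:12] <- img[10:12, 10:12] + 80
  for (radius in c(2, 4)) {
    expected <- img - brute_opening(img, radius)
    expect_equal(subtract_background(img, radius), expected, tolerance = 1e-12)
  }
})

test_that("background subtraction never increases or goes negative", {
  set.seed(9)
  img <- matrix(rlnorm(40 * 40, 2, 1), 40, 40)
  out <- subtract_background(img, 6)
  expect_true(all(out >= 0))
  expect_true(all(out <= img + 1e-12))
})

test_that("auto_threshold separates bimodal intensities", {
  set.seed(3)
  x <- matrix(c(rep(10, 900), rep(200, 100))[sample(1000)], 25, 40)
  thr <- auto_threshold(x)
  expect_s3_class(thr, "threshold_spec")
  expect_identical(thr$provenance, "automatic")
  expect_gt(thr$value, 10); expect_lt(thr$value, 200)
  g <- matrix(c(rnorm(2000, 20, 10), rnorm(2000, 180, 10)), 40, 100)
  thr2 <- auto_threshold(g)
  expect_gt(thr2$value, 50); expect_lt(thr2$value, 150)
  expect_error(auto_threshold(matrix(5, 4, 4)), "constant")
})

test_that("auto_threshold agrees with the EBImage reference within one bin", {
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(c(rnorm(1500, 30, 12), rnorm(500, 170, 20)), 40, 50)
    rg <- range(x)
    ours <- auto_threshold(x)$value
    ref <- as.numeric(EBImage::otsu(EBImage::Image(x), range = rg,
                                    levels = 256))
    expect_lt(abs(ours - ref), 2 * diff(rg) / 256)
  }
})

test_that("threshold files round-trip as key=value text", {
  thr <- list(insulin = threshold_spec(123.5, "manual"),
              nuclei = threshold_spec(80, "automatic"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_threshold_spec(thr, path)
  back <- read_threshold_spec(path)
  expect_equal(back$insulin$value, 123.5)
  expect_identical(back$nuclei$provenance, "automatic")
})

test_that("tissue mask applies the >0.05% exclusion rule", {
  ch <- matrix(0, 1000, 1000)
  sec <- section_image(list(nuclei = ch, insulin = ch), pixel_size = 1)
  full <- rect_poly(0, 0, 1000, 1000)
  tm <- build_tissue_mask(sec, contour_set(list(full)))
  expect_equal(tm$pancreas_area_um2, 1e6)
  # 400 px = 0.04% <= 0.05%: ignored
  small <- contour_set(list(full), list(rect_poly(10, 10, 30, 30)))
  tm2 <- build_tissue_mask(sec, small)
  expect_equal(tm2$pancreas_area_um2, 1e6)
  expect_length(tm2$applied_exclusions, 0)
  # 10000 px = 1%: subtracted
  big <- contour_set(list(full), list(rect_poly(100, 100, 200, 200)))
  tm3 <- build_tissue_mask(sec, big)
  expect_equal(tm3$pancreas_area_um2, 990000)
  expect_equal(tm3$applied_exclusions, 1L)
  expect_equal(tm3$excluded_area_um2, 10000)
})

test_that("pancreas area is monotone nonincreasing in applied exclusions", {
  ch <- matrix(0, 200, 200)
  sec <- section_image(list(nuclei = ch, insulin = ch), pixel_size = 1)
  full <- rect_poly(0, 0, 200, 200)
  excl <- list(rect_poly(10, 10, 40, 40), rect_poly(60, 60, 100, 100),
               rect_poly(120, 120, 190, 190))
  areas <- vapply(0:3, function(k) {
    cs <- contour_set(list(full), excl[seq_len(k)])
    build_tissue_mask(sec, cs)$pancreas_area_um2
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("binarize masks against threshold and tissue, and is idempotent", {
  ch <- matrix(rep(c(0, 255), 50 * 25), 50, 50)   # checkerboard by columns
  sec <- section_image(list(nuclei = ch, insulin = ch), pixel_size = 1)
  tissue <- build_tissue_mask(sec, contour_set(list(rect_poly(0, 0, 50, 50))))
  m <- binarize(ch, threshold_spec(128, "manual"), tissue)
  expect_equal(sum(m), 50 * 50 / 2)
  expect_equal(binarize(ch, -1, tissue), tissue$mask, ignore_attr = TRUE)
  expect_equal(sum(binarize(ch, 300, tissue)), 0)
  # idempotence: re-binarizing a mask with a threshold in (0, 1] is identity
  expect_equal(binarize(m * 1, 0.5, tissue), m, ignore_attr = TRUE)
  expect_error(binarize(matrix(0, 2, 2), 1, tissue), "mismatch")
})
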