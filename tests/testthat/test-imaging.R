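test_that("ROI cropping uses 0-based half-open rectangles", {
  px <- matrix(seq(0, 1, length.out = 16), 4, 4)
  img <- EMImage(px, nmPerPx = 1, imageId = "t")
  # (0,0,2,2) selects the 4 top-left pixels
  crop <- cropRois(img, data.frame(x0 = 0, y0 = 0, width = 2, height = 2))[[1]]
  expect_equal(crop, px[1:2, 1:2], ignore_attr = TRUE)
  # full-image rectangle is the identity
  full <- cropRois(img, data.frame(x0 = 0, y0 = 0, width = 4, height = 4))[[1]]
  expect_equal(full, px, ignore_attr = TRUE)
  # overlapping ROIs crop independently
  two <- cropRois(img, data.frame(x0 = c(0, 1), y0 = c(0, 1),
                                  width = 2, height = 2))
  expect_equal(two[[2]], px[2:3, 2:3], ignore_attr = TRUE)
  expect_error(cropRois(img, data.frame(x0 = 3, y0 = 0, width = 2,
                                        height = 2)), "ROI 1")
})

test_that("preprocessing is identity-at-defaults-off and propagates dark minima", {
  px <- matrix(0.5, 9, 9)
  idCfg <- GranuleConfig(gaussian_sigma = 0, min_filter_size = 1)
  expect_equal(preprocessRoi(px, idCfg), px)
  # constant image unchanged by both filters
  cfg <- GranuleConfig(gaussian_sigma = 1, min_filter_size = 3)
  expect_equal(preprocessRoi(px, cfg), px, tolerance = 1e-6)
  # single dark pixel propagates to its 3x3 neighbourhood under the min filter
  px2 <- matrix(0.8, 9, 9); px2[5, 5] <- 0.1
  out <- preprocessRoi(px2, GranuleConfig(gaussian_sigma = 0,
                                          min_filter_size = 3))
  expect_equal(out[4:6, 4:6], matrix(0.1, 3, 3))
  expect_equal(out[2, 2], 0.8)
})

test_that("binarization thresholds dark foreground with otsu support", {
  px <- matrix(0.9, 8, 8)
  cfg <- GranuleConfig(threshold = 0.5)
  expect_false(any(binarizeRoi(px, cfg)))
  px[3:5, 3:5] <- 0.1
  m <- binarizeRoi(px, cfg)
  expect_equal(sum(m), 9)
  expect_true(all(m[3:5, 3:5]))
  expect_true(all(binarizeRoi(px, GranuleConfig(threshold = 1))))
  expect_warning(m2 <- binarizeRoi(matrix(0.5, 4, 4),
                                   GranuleConfig(threshold = "otsu")),
                 "degenerate")
  expect_false(any(m2))
  m3 <- binarizeRoi(px, GranuleConfig(threshold = "otsu"))
  expect_true(all(m3[3:5, 3:5]))
})

test_that("component counting applies min-area and the merged-blob quotient", {
  cfg <- GranuleConfig(min_area = 4, single_granule_area = 9)
  mask <- matrix(FALSE, 40, 40)
  # 10 disjoint 2x2..3x3 blobs, each within [min_area, single]
  for (i in 0:9) {
    r <- 2 + (i %% 2)
    y <- 1 + (i %% 5) * 8; x <- 1 + (i %/% 5) * 20
    mask[y:(y + r - 1), x:(x + r - 1)] <- TRUE
  }
  expect_equal(countGranules(mask, cfg)$count, 10)

  # merged blob of exactly 3x the single-granule area counts 3
  blob <- matrix(FALSE, 10, 10); blob[2:4, 1:9] <- TRUE  # area 27
  expect_equal(countGranules(blob, cfg)$count, 3)
  # a speck below min_area counts 0
  speck <- matrix(FALSE, 6, 6); speck[2, 2:3] <- TRUE
  expect_equal(countGranules(speck, cfg)$count, 0)
  # a component between single and 2x single still counts 1
  mid <- matrix(FALSE, 8, 8); mid[2:4, 2:5] <- TRUE  # area 12
  expect_equal(countGranules(mid, cfg)$count, 1)
})

test_that("connectivity 8 joins diagonal pixels that connectivity 4 separates", {
  mask <- matrix(FALSE, 6, 6)
  mask[2:3, 2:3] <- TRUE
  mask[4:5, 4:5] <- TRUE  # touches the first blob only diagonally
  c4 <- GranuleConfig(min_area = 1, single_granule_area = 100,
                      connectivity = 4)
  c8 <- GranuleConfig(min_area = 1, single_granule_area = 100,
                      connectivity = 8)
  expect_equal(nrow(countGranules(mask, c4)$components), 2)
  expect_equal(nrow(countGranules(mask, c8)$components), 1)
})

test_that("density arithmetic respects calibration and units", {
  expect_equal(granuleDensity(100, 100, 1), 1)
  expect_equal(granuleDensity(100, 100, 2), 0.25)
  expect_equal(granuleDensity(100, 100, 2, unit = "per_um2"), 0.25e6)
  expect_error(granuleDensity(1, 0, 1), "positive")
})

test_that("counting is translation invariant and monotone in added granules", {
  mkimg <- function(centers) {
    px <- matrix(0.7, 120, 120)
    for (i in seq_len(nrow(centers)))
      px <- atriomics:::.stampDisk(px, centers[i, 1], centers[i, 2], 4, -0.4)
    EMImage(pmin(pmax(px, 0), 1), imageId = "t")
  }
  cfg <- GranuleConfig(min_area = 10, single_granule_area = 110)
  centers <- cbind(c(30, 60, 90), c(30, 60, 90))
  roi <- data.frame(x0 = 10, y0 = 10, width = 100, height = 100)
  base <- countGranulesInImage(mkimg(centers), roi, cfg)$count
  expect_equal(base, 3)
  # shift granules and ROI together by (8, 5)
  roi2 <- data.frame(x0 = 18, y0 = 15, width = 100, height = 100)
  shifted <- countGranulesInImage(mkimg(centers + rep(c(8, 5), each = 3)),
                                  roi2, cfg)$count
  expect_equal(shifted, base)
  # adding a non-touching granule never decreases the count
  more <- countGranulesInImage(mkimg(rbind(centers, c(90, 30))), roi,
                               cfg)$count
  expect_equal(more, base + 1)
})

test_that("group comparison of densities behaves like a pooled t-test", {
  d <- data.frame(density = c(1, 1.1, 0.9, 1.05, 1, 1.1, 0.9, 1.05),
                  group = rep(c("AF", "sham"), each = 4))
  same <- compareGranuleDensities(d)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(100)
  d2 <- data.frame(density = c(rnorm(10, 2, 0.1), rnorm(10, 1, 0.1)),
                   group = rep(c("AF", "sham"), each = 10))
  res <- compareGranuleDensities(d2)
  expect_lt(res$p, 0.01)
  flip <- compareGranuleDensities(transform(
    d2, group = ifelse(group == "AF", "sham", "AF")))
  expect_equal(flip$t, -res$t, tolerance = 1e-12)
  expect_equal(flip$p, res$p, tolerance = 1e-12)

  # per-animal aggregation path
  d3 <- data.frame(density = rnorm(12, 1, 0.05),
                   group = rep(c("AF", "sham"), each = 6),
                   animal_id = rep(c("a1", "a2", "a3", "b1", "b2", "b3"),
                                   each = 2))
  res3 <- compareGranuleDensities(d3, level = "animal")
  expect_equal(res3$df, 4)
  expect_error(compareGranuleDensities(
    data.frame(density = 1:3, group = c("AF", "sham", "sham"))),
    "at least 2")
})

test_that("end-to-end counts on synthetic micrographs track the planted truth", {
  spec <- GranuleImageSpec(n_granules = 60, seed = 17)
  sim <- simulateEMImage(spec)
  rois <- data.frame(x0 = 0, y0 = 0, width = spec$width,
                     height = spec$height)
  res <- countGranulesInImage(sim$image, rois, GranuleConfig())
  expect_lt(abs(res$count - 60) / 60, 0.1)
  expect_equal(res$area_nm2, spec$width * spec$height * spec$nm_per_px^2)
})
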