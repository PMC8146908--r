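test_that("denoise preserves constants, dimensions and removes speckle", {
  cfg <- seg_config()
  const <- new_frame(array(128, c(21, 21, 3)))
  out <- denoise(const, cfg)
  expect_equal(out$pixels, const$pixels, tolerance = 1e-8)
  expect_identical(dim(out$pixels), dim(const$pixels))

  # a single hot pixel is annihilated by the 9x9 median
  px <- array(0, c(21, 21, 3))
  px[11, 11, ] <- 255
  speck <- denoise(new_frame(px), cfg)
  expect_true(all(speck$pixels == 0))

  wide <- new_frame(array(40, c(15, 33, 3)))
  expect_identical(dim(denoise(wide, cfg)$pixels), c(15L, 33L, 3L))
})

test_that("kernel validation rejects even or undersized kernels", {
  expect_error(seg_config(median_kernel = 8), class = "sv_config_error")
  expect_error(seg_config(gaussian_kernel = 1), class = "sv_config_error")
  expect_error(denoise(new_frame(array(0, c(5, 5, 3))), seg_config()),
               class = "sv_config_error") # kernel larger than frame
})

test_that("to_hsv uses the 0-180 / 0-255 convention", {
  px <- array(0, c(4, 1, 3))
  px[1, 1, ] <- c(255, 0, 0)    # pure red
  px[2, 1, ] <- c(255, 255, 255) # white
  px[3, 1, ] <- c(128, 128, 128) # gray
  px[4, 1, ] <- c(0, 255, 0)    # green: 120 deg -> 60 on half-degree scale
  hsv <- to_hsv(new_frame(px))
  expect_equal(hsv[1, 1, ], c(0, 255, 255))
  expect_equal(hsv[2, 1, 2:3], c(0, 255))
  expect_equal(hsv[3, 1, 2], 0)
  expect_equal(hsv[4, 1, 1], 60)
})

test_that("threshold_onion matches the skin and specular ranges", {
  cfg <- seg_config()
  hsv <- hsv_array(H = c(20, 170, 90, 50, 50),
                   S = c(200, 180, 200, 250, 100),
                   V = c(150, 120, 200, 250, 150))
  m <- threshold_onion(hsv, cfg)
  expect_identical(m[, 1], c(1L,  # H=20 inside first skin range
                             1L,  # H=170 inside wrap-around skin range
                             0L,  # H=90 green, outside all ranges
                             1L,  # H=50 only via specular range (S>=240)
                             0L)) # H=50, S=100: neither skin nor specular
})

test_that("enlarging a hue range never shrinks the foreground", {
  set.seed(11)
  for (i in 1:5) {
    hsv <- array(runif(20 * 20 * 3, 0, 180), c(20, 20, 3))
    hsv[, , 2:3] <- runif(20 * 20 * 2, 0, 255)
    cfg1 <- seg_config(skin_ranges = list(hue_range(10, 30, s_lo = 60)))
    cfg2 <- seg_config(skin_ranges = list(hue_range(5, 40, s_lo = 40)))
    m1 <- threshold_onion(hsv, cfg1)
    m2 <- threshold_onion(hsv, cfg2)
    expect_true(all(m2[m1 == 1] == 1))
  }
})

test_that("morphological refinement removes small blobs and is stable", {
  cfg <- seg_config()
  empty <- matrix(0L, 40, 40)
  expect_identical(morph_refine(empty, cfg), empty)

  blob <- matrix(0L, 40, 40)
  blob[19:21, 19:21] <- 1L  # 3x3 blob, smaller than the 12 px element
  expect_true(all(morph_refine(blob, cfg) == 0))

  set.seed(21)
  for (i in 1:4) {
    m <- matrix(rbinom(60 * 60, 1, 0.45), 60, 60)
    once <- morph_refine(m, cfg)
    expect_identical(morph_refine(once, cfg), once) # open-close idempotent
  }

  # a disc the size of the element survives opening
  disc <- disc_mask(40, 40, 20, 20, 9)
  expect_gt(sum(morph_refine(disc, cfg)), 0)
})

test_that("distance map is exact Euclidean with the border contract", {
  expect_true(all(distance_map(matrix(0L, 10, 10)) == 0))

  # no background at all: the frame border acts as background
  allfg <- distance_map(matrix(1L, 9, 9))
  expect_equal(allfg[5, 5], 5)  # center is 5 px from just outside the frame
  expect_equal(allfg[1, 1], 1)

  d <- distance_map(disc_mask(31, 31, 16, 16, 10))
  expect_lte(abs(max(d) - 10), 1)
  w <- which(d == max(d), arr.ind = TRUE)
  expect_lte(max(abs(w[1, ] - c(16, 16))), 1)

  set.seed(31)
  for (i in 1:10) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.3, 0.8)), 32, 32)
    if (!any(m == 0) || !any(m == 1)) next
    expect_equal(distance_map(m), brute_distance_map(m), tolerance = 1e-6)
  }
})

test_that("markers sit on distance peaks, one per well-separated disc", {
  cfg <- seg_config()
  empty <- matrix(0L, 30, 30)
  expect_identical(find_markers(distance_map(empty), empty, cfg)$region_count, 0L)

  one <- disc_mask(60, 60, 30, 30, 15)
  mk1 <- find_markers(distance_map(one), one, cfg)
  expect_identical(mk1$region_count, 1L)

  two <- matrix(as.integer(disc_mask(60, 140, 30, 35, 15) |
                             disc_mask(60, 140, 30, 115, 15)), 60, 140)
  mk2 <- find_markers(distance_map(two), two, cfg)
  expect_identical(mk2$region_count, 2L)
  cen <- which(mk2$labels > 0, arr.ind = TRUE)
  for (ctr in list(c(30, 35), c(30, 115))) {
    dmin <- min(sqrt((cen[, 1] - ctr[1])^2 + (cen[, 2] - ctr[2])^2))
    expect_lte(dmin, 3)
  }
})

test_that("watershed split partitions the mask and separates touching discs", {
  cfg <- seg_config()
  one <- disc_mask(60, 60, 30, 30, 15)
  mk <- find_markers(distance_map(one), one, cfg)
  lab1 <- watershed_split(NULL, one, mk)
  expect_identical(lab1$region_count, 1L)
  inter <- sum(lab1$labels == 1 & one == 1)
  uni <- sum(lab1$labels == 1 | one == 1)
  expect_gte(inter / uni, 0.95)

  # overlapping pair, centers 24 px apart, radius 15
  m2 <- matrix(as.integer(disc_mask(70, 90, 35, 33, 15) |
                            disc_mask(70, 90, 35, 57, 15)), 70, 90)
  mk2 <- find_markers(distance_map(m2), m2, cfg)
  lab2 <- watershed_split(NULL, m2, mk2)
  expect_identical(lab2$region_count, 2L)
  reg <- extract_regions(lab2, seg_config(min_region_area = 10))
  for (ctr in list(c(35, 33), c(35, 57))) {
    dmin <- min(sqrt((reg$centroid_row - ctr[1])^2 +
                       (reg$centroid_col - ctr[2])^2))
    expect_lte(dmin, 3)
  }

  empty <- matrix(0L, 20, 20)
  mke <- find_markers(distance_map(empty), empty, cfg)
  expect_identical(watershed_split(NULL, empty, mke)$region_count, 0L)

  # partition: every labelled pixel was foreground; labels within 1..K
  expect_true(all(m2[lab2$labels > 0] == 1))
  expect_true(all(lab2$labels %in% 0:lab2$region_count))
})

test_that("region extraction measures and filters correctly", {
  cfg <- seg_config()
  # 5 px^2 speck is dropped by the default min_region_area = 200
  speck <- matrix(0L, 30, 30); speck[15, 13:17] <- 1L
  lab <- shallotvision:::new_labels(speck, 1L)
  expect_identical(nrow(extract_regions(lab, cfg)), 0L)

  disc <- disc_mask(120, 120, 60, 60, 25)
  labd <- shallotvision:::new_labels(disc, 1L)
  reg <- extract_regions(labd, cfg)
  expect_identical(nrow(reg), 1L)
  expect_lte(abs(reg$diameter_px - 50), 2)
  expect_equal(reg$centroid_row, 60, tolerance = 0.5)
  expect_gt(reg$perimeter, 0)
  expect_true(reg$centroid_row >= reg$bbox_row0 &
                reg$centroid_row < reg$bbox_row1)

  # equivalent-area alternative descriptor
  rega <- extract_regions(labd, seg_config(diameter = "equivalent_area"))
  expect_equal(rega$diameter_px, 2 * sqrt(sum(disc) / pi), tolerance = 1e-6)

  # border_margin drops edge-adjacent regions
  edge <- disc_mask(60, 60, 10, 10, 9)
  labe <- shallotvision:::new_labels(edge, 1L)
  expect_identical(nrow(extract_regions(labe, seg_config(border_margin = 5,
                                                         min_region_area = 10))),
                   0L)
  expect_identical(nrow(extract_regions(labe, seg_config(min_region_area = 10))),
                   1L)
})

test_that("the full pipeline is deterministic", {
  sc <- generate_scene(scene_spec(width = 320, height = 240, n_bulbs = 2,
                                  diameter_mm_range = c(28, 38), seed = 5))
  cfg <- run_config(pixel_metric = pixel_metric(3.38, 1))
  b1 <- detect_bulbs(sc$frame, cfg)
  b2 <- detect_bulbs(sc$frame, cfg)
  expect_identical(b1, b2)
  expect_gte(nrow(b1), 1)
})
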