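test_that("scene specs validate their parameters", {
  expect_error(scene_spec(overlap_fraction = 1.5), class = "sv_config_error")
  expect_error(scene_spec(specular_prob = -0.1), class = "sv_config_error")
  expect_error(scene_spec(pm = 0), class = "sv_config_error")
  expect_error(scene_spec(diameter_mm_range = c(5, 2)),
               class = "sv_config_error")
  expect_error(scene_spec(ellipse_ratio = 1.5), class = "sv_config_error")
})

test_that("empty scenes and determinism contracts hold", {
  spec <- scene_spec(width = 96, height = 96, n_bulbs = 0, seed = 2)
  sc <- generate_scene(spec)
  expect_identical(nrow(sc$truth), 0L)
  expect_identical(dim(sc$frame$pixels), c(96L, 96L, 3L))

  spec2 <- scene_spec(width = 300, height = 300, n_bulbs = 2,
                      diameter_mm_range = c(25, 32), seed = 31)
  a <- generate_scene(spec2)
  b <- generate_scene(spec2)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("rendered disc sizes match the truth to a pixel", {
  # one 44 mm bulb at 3.38 px/mm renders ~148.7 px wide
  spec <- scene_spec(width = 220, height = 220, n_bulbs = 1, pm = 3.38,
                     diameter_mm_range = c(44, 44), specular_prob = 0,
                     seed = 9)
  sc <- generate_scene(spec)
  expect_equal(sc$truth$diameter_px, 44 * 3.38, tolerance = 1e-9)
  hsv <- to_hsv(sc$frame)
  skin <- (hsv[, , 1] <= 40 | hsv[, , 1] >= 160) & hsv[, , 2] >= 60
  i <- which(skin, arr.ind = TRUE)
  ext <- max(diff(range(i[, 1])), diff(range(i[, 2]))) + 1
  expect_lte(abs(ext - sc$truth$diameter_px), 1.6)

  # ground-truth fidelity across a multi-bulb scene
  spec2 <- scene_spec(width = 420, height = 320, n_bulbs = 3,
                      diameter_mm_range = c(26, 40), specular_prob = 0,
                      seed = 12)
  sc2 <- generate_scene(spec2)
  hsv2 <- to_hsv(sc2$frame)
  skin2 <- (hsv2[, , 1] <= 40 | hsv2[, , 1] >= 160) & hsv2[, , 2] >= 60
  for (k in seq_len(nrow(sc2$truth))) {
    tr <- sc2$truth[k, ]
    i <- which(skin2, arr.ind = TRUE)
    near <- i[sqrt((i[, 1] - tr$row)^2 + (i[, 2] - tr$col)^2) <=
                tr$diameter_px / 2 + 3, , drop = FALSE]
    ext <- max(diff(range(near[, 1])), diff(range(near[, 2]))) + 1
    expect_lte(abs(ext - tr$diameter_px), 1.6)
  }
})

test_that("class mixture follows the configured weights", {
  spec <- scene_spec(seed = 1)  # weights 150:90:30
  set.seed(501)
  pop <- sample_bulbs(spec, 1000)
  w <- c(small = 150, medium = 90, large = 30) / 270
  for (cl in names(w)) {
    phat <- mean(pop$size_class == cl)
    se <- sqrt(w[[cl]] * (1 - w[[cl]]) / 1000)
    expect_lte(abs(phat - w[[cl]]), 3 * se)
  }
  # diameters stay inside their class bands
  expect_true(all(pop$diameter_mm[pop$size_class == "small"] < 44))
  expect_true(all(pop$diameter_mm[pop$size_class == "medium"] >= 44.13 &
                    pop$diameter_mm[pop$size_class == "medium"] <= 53.61))
  expect_true(all(pop$diameter_mm[pop$size_class == "large"] >= 54.20))
})

test_that("overlap fraction produces touching bulbs flagged as occluded", {
  spec <- scene_spec(width = 360, height = 300, n_bulbs = 4,
                     diameter_mm_range = c(26, 34), overlap_fraction = 0.5,
                     seed = 41)
  sc <- generate_scene(spec)
  expect_gte(sum(sc$truth$occluded), 2)
  # occluded truth still records the full pre-occlusion diameter
  expect_true(all(sc$truth$diameter_px ==
                    sc$truth$diameter_mm * spec$pm))
})

test_that("infeasible packings raise a generation error", {
  expect_error(
    generate_scene(scene_spec(width = 64, height = 64, n_bulbs = 10,
                              diameter_mm_range = c(12, 14), pm = 1,
                              seed = 1)),
    class = "sv_generation_error")
})

test_that("sequences advance in time with a spanning GPS track", {
  spec <- scene_spec(width = 80, height = 80, n_bulbs = 1, pm = 1,
                     diameter_mm_range = c(25, 30), seed = 8)
  sq <- generate_sequence(spec, n_frames = 5, fix_interval = 1,
                          frame_interval = 2.5)
  ts <- vapply(sq$scenes, function(s) s$frame$timestamp, numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_equal(range(sq$fixes$timestamp), c(0, 10))
  expect_identical(sum(vapply(sq$scenes, function(s) nrow(s$truth),
                              integer(1))), 5L)
  # per-frame seeds differ, so scenes differ
  expect_false(identical(sq$scenes[[1]]$frame$pixels,
                         sq$scenes[[2]]$frame$pixels))
})

test_that("scenes with a calibration ball support end-to-end calibration", {
  spec <- scene_spec(width = 200, height = 200, n_bulbs = 0, pm = 2,
                     include_ball = TRUE, seed = 6)
  sc <- generate_scene(spec)
  expect_equal(sc$ball$diameter_px, 65.4 * 2)
  pm <- calibrate_from_frames(sc$frame, true_diameter_mm = 65.4)
  expect_lte(abs(pm$pm - 2) / 2, 0.03)
})
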