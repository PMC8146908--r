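test_that("centroid matching is greedy, one-to-one and bounded", {
  pts <- data.frame(row = c(10, 40, 80), col = c(10, 40, 80))
  m <- match_detections(pts, pts, max_dist = 5)
  expect_identical(c(m$tp, m$fp, m$fn), c(3, 0, 0))

  # two predictions within range of one truth: one-to-one enforced
  pred <- data.frame(row = c(10, 12), col = c(10, 10))
  truth <- data.frame(row = 11, col = 10)
  m2 <- match_detections(pred, truth, max_dist = 5)
  expect_identical(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  # the closer prediction wins
  expect_identical(attr(m2, "matches")$pred, 1L)

  m3 <- match_detections(data.frame(row = numeric(0), col = numeric(0)),
                         data.frame(row = c(1, 2, 3), col = c(1, 2, 3)),
                         max_dist = 5)
  expect_identical(c(m3$tp, m3$fp, m3$fn), c(0, 0, 3))

  expect_error(match_detections(pred, truth, max_dist = 0),
               class = "sv_domain_error")
})

test_that("matching is symmetric with fp and fn exchanged", {
  set.seed(17)
  for (i in 1:10) {
    a <- data.frame(row = runif(7, 0, 100), col = runif(7, 0, 100))
    b <- data.frame(row = runif(5, 0, 100), col = runif(5, 0, 100))
    ab <- match_detections(a, b, max_dist = 25)
    ba <- match_detections(b, a, max_dist = 25)
    expect_identical(ab$tp, ba$tp)
    expect_identical(ab$fp, ba$fn)
    expect_identical(ab$fn, ba$fp)
  }
})

test_that("fraction metrics follow their closed forms", {
  expect_equal(accuracy(confusion_counts(1, 1, 1, 1)), 0.5)
  expect_equal(accuracy(confusion_counts(10, 0, 0, 0)), 1.0)
  expect_equal(accuracy(confusion_counts(2, 1, 4, 3)), 0.5)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)),
               class = "sv_domain_error")

  expect_equal(precision(1115, 352), 1115 / 1467)
  expect_lte(abs(precision(1115, 352) - 0.760), 5e-4)
  expect_equal(precision(5, 0), 1.0)
  expect_equal(precision(0, 5), 0.0)
  expect_error(precision(0, 0), class = "sv_domain_error")

  expect_lte(abs(recall(1115, 418) - 0.727), 5e-4)
  expect_equal(recall(0, 7), 0.0)
  expect_equal(recall(3, 1), 0.75)
  expect_error(recall(0, 0), class = "sv_domain_error")

  # monotone non-decreasing in tp at fixed fp / fn
  p <- vapply(1:20, function(tp) precision(tp, 7), numeric(1))
  r <- vapply(1:20, function(tp) recall(tp, 7), numeric(1))
  expect_true(all(diff(p) >= 0) && all(diff(r) >= 0))
  expect_true(all(p >= 0 & p <= 1 & r >= 0 & r <= 1))
})

test_that("dispersion and error statistics match their formulas", {
  expect_equal(sample_sd(rep(4.2, 10)), 0)
  expect_equal(sample_sd(c(2, 4)), sqrt(2))
  set.seed(23)
  x <- rnorm(15)
  expect_equal(sample_sd(x + 100), sample_sd(x))
  expect_error(sample_sd(1), class = "sv_domain_error")

  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(0, 2)), sqrt(0.5))
  pred <- rnorm(20); obs <- rnorm(20)
  expect_gte(rmse(pred, obs), abs(mean(pred - obs)))
  expect_error(rmse(1:3, 1:4), class = "sv_domain_error")

  expect_equal(sem(0, 5), 0)
  expect_equal(sem(1, 100), 0.1)
  expect_equal(sem(2.5, 1), 2.5)
  expect_error(sem(1, 0), class = "sv_domain_error")
})

test_that("size evaluation reproduces hand-computed toy values", {
  # perfect prediction: accuracies 1, differences 0, D = 0
  truth <- data.frame(diameter_mm = c(30, 35, 48, 50, 60),
                      size_class = c("small", "small", "medium", "medium",
                                     "large"))
  ev0 <- size_eval(truth, truth)
  expect_true(all(ev0$classes$accuracy == 1))
  expect_true(all(ev0$classes$mean_difference == 0))
  expect_true(all(ev0$classes$ks_d == 0))
  expect_equal(ev0$overall$rmse, 0)

  # toy with errors, checked against spreadsheet-style arithmetic
  pred <- data.frame(diameter_mm = c(33, 36, 45, 55, 58),
                     size_class = c("small", "small", "medium", "large",
                                    "large"))
  ev <- size_eval(pred, truth)
  small <- ev$classes[ev$classes$size_class == "small", ]
  expect_equal(small$mean_pred, mean(c(33, 36)))
  expect_equal(small$mean_difference, mean(c(33, 36)) - mean(c(30, 35)))
  expect_equal(small$sd_pred, sd(c(33, 36)))
  expect_equal(small$accuracy, 1)
  med <- ev$classes[ev$classes$size_class == "medium", ]
  expect_equal(med$n_correct, 1L)  # the 55 mm prediction left the class
  expect_equal(med$accuracy, 0.5)
  expect_equal(ev$overall$accuracy, 4 / 5)
  expect_equal(ev$overall$rmse,
               sqrt(mean((pred$diameter_mm - truth$diameter_mm)^2)))

  expect_error(size_eval(pred[1:3, ], truth), class = "sv_domain_error")

  # broom-style accessors
  expect_identical(tidy(ev), ev$classes)
  expect_identical(glance(ev), ev$overall)
})
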