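# Threshold application, rendering, and the model-style fitting interface.

test_that("threshold application labels and renders by class", {
  img <- matrix(c(40L, 200L, 150L, 250L), 2)  # [[40,150],[200,250]]
  seg <- threshold_apply(img, c(100L, 180L))
  expect_identical(seg$labels, matrix(c(0L, 2L, 1L, 2L), 2))
  expect_identical(seg$rendered, matrix(c(40L, 225L, 150L, 225L), 2))
  # midpoint mode uses the class interval midpoints
  seg2 <- threshold_apply(img, c(100L, 180L), render = "midpoint")
  expect_identical(seg2$representatives,
                   as.integer(round(c((0 + 99) / 2, (100 + 179) / 2,
                                      (180 + 255) / 2))))
  expect_error(threshold_apply(img, c(180L, 100L)), "increasing")
  expect_error(threshold_apply(img, 300L), "thresholds")
})

test_that("an empty threshold set yields a single mean-valued class", {
  img <- matrix(c(10L, 20L, 30L, 41L), 2)
  seg <- threshold_apply(img, integer(0))
  expect_true(all(seg$labels == 0L))
  expect_true(all(seg$rendered == as.integer(round(mean(img)))))
})

test_that("labels equal the count of thresholds at or below each pixel", {
  set.seed(8)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 60, replace = TRUE), 6, 10)
    thr <- random_thresholds(sample(1:5, 1))
    seg <- threshold_apply(img, thr)
    manual <- matrix(vapply(as.integer(img),
                            function(g) sum(thr <= g), integer(1)), 6, 10)
    expect_identical(seg$labels, manual)
    expect_true(all(threshold_apply(matrix(0L, 2, 2), 1L)$labels == 0L))
  }
})

test_that("rendering is idempotent under the same thresholds", {
  set.seed(9)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  thr <- c(64L, 128L, 192L)
  seg1 <- threshold_apply(img, thr)
  seg2 <- threshold_apply(seg1$rendered, thr)
  expect_identical(seg2$labels, seg1$labels)
  expect_identical(seg2$rendered, seg1$rendered)
})

test_that("fitting a two-level image recovers the exact optimum and scores perfectly", {
  img <- synth_two_delta_image(0, 255, 16, 16)
  fit <- otsu_segment(img, 1, control = coot_control(max_iter = 40, seed = 3))
  expect_equal(fit$fitness, 16256.25)
  # one threshold splits a two-level image losslessly
  expect_identical(fit$rendered, img)
  expect_equal(fit$metrics$psnr, Inf)
  expect_equal(fit$metrics$ssim, 1)
})

test_that("a constant image has zero objective but valid thresholds", {
  img <- matrix(42L, 8, 8)
  fit <- otsu_segment(img, 2, control = fast_control())
  expect_equal(fit$fitness, 0)
  expect_length(fit$thresholds, 2L)
  expect_true(all(diff(fit$thresholds) >= 1))
  expect_equal(fit$metrics$ssim, 1)   # rendering reproduces the constant
})

test_that("the fitted object supports the standard model methods", {
  img <- synth_multimodal_image(three_mode_spec(), 48, 48, seed = 2)
  fit <- otsu_segment(img, 2, control = fast_control(seed = 2))
  expect_s3_class(fit, "otsu_seg")
  expect_identical(coef(fit), fit$thresholds)
  expect_identical(fitted(fit), fit$rendered)
  expect_identical(residuals(fit), img - fit$rendered)
  expect_identical(predict(fit), fit$labels)
  expect_identical(predict(fit, newdata = img, type = "rendered"),
                   fit$rendered)
  expect_output(print(fit), "Multilevel Otsu")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.otsu_seg")
  expect_equal(sum(sm$classes$weight), 1, tolerance = 1e-12)
  expect_output(print(sm), "Intensity classes")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("fitting from a histogram alone yields thresholds without images", {
  h <- gray_histogram(synth_two_delta_image(10, 200, 8, 8))
  fit <- otsu_segment(h, 1, control = fast_control())
  expect_null(fit$rendered)
  expect_null(fit$metrics)
  expect_error(residuals(fit), "rendered")
  expect_identical(predict(fit, newdata = matrix(c(0L, 255L), 1)),
                   matrix(c(0L, 1L), 1))
})

test_that("replicated runs return per-seed rows with a mean/sd summary", {
  img <- synth_two_delta_image(0, 255, 16, 16)
  runs <- otsu_segment_runs(img, 1, seeds = 1:3,
                            control = coot_control(max_iter = 25))
  expect_equal(nrow(runs), 3L)
  expect_true(all(c("seed", "fitness", "psnr", "ssim", "fsim", "t1") %in%
                    names(runs)))
  expect_equal(runs$fitness, rep(16256.25, 3))
  sm <- attr(runs, "summary")
  expect_identical(sm$statistic, c("mean", "sd"))
  expect_equal(sm$fitness[1], 16256.25)
})
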