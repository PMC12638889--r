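# Histogram statistics, the between-class-variance objective, the threshold
# decoder and the exhaustive oracle.

two_delta_hist <- gray_histogram(synth_two_delta_image(0, 255, 2, 2))

test_that("histograms count pixels and normalize to probabilities", {
  h <- two_delta_hist
  expect_equal(h$probs[1], 0.5)
  expect_equal(h$probs[256], 0.5)
  expect_equal(sum(h$probs), 1)
  hc <- gray_histogram(matrix(7L, 3, 3))
  expect_equal(hc$probs[8], 1)
  expect_error(gray_histogram(matrix(integer(0), 0, 0)), "non-empty")
  expect_error(gray_histogram(matrix(300L, 2, 2)), "outside")
  expect_error(gray_histogram(matrix(1.5, 2, 2)), "integer")
})

test_that("the global mean is the probability-weighted gray level", {
  expect_equal(hist_mean(two_delta_hist), 127.5)
  expect_equal(hist_mean(gray_histogram(matrix(7L, 2, 2))), 7)
  h <- gray_hist_from_probs({p <- numeric(256); p[51] <- 0.25; p[201] <- 0.75; p})
  expect_equal(hist_mean(h), 162.5)
})

test_that("class weights and means satisfy the decomposition identities", {
  st <- class_stats(two_delta_hist, 128L)
  expect_equal(st$omega, c(0.5, 0.5))
  expect_equal(st$mu, c(0, 255))
  h <- gray_hist_from_probs({p <- numeric(256); p[51] <- 0.25; p[201] <- 0.75; p})
  st <- class_stats(h, 100L)
  expect_equal(st$omega, c(0.25, 0.75))
  expect_equal(st$mu, c(50, 200))
  # random sweep: sum(omega) = 1 and sum(omega * mu) = global mean
  for (s in 1:40) {
    h <- random_hist(s)
    thr <- random_thresholds(sample(1:5, 1))
    st <- class_stats(h, thr)
    expect_equal(sum(st$omega), 1, tolerance = 1e-12)
    expect_equal(sum(st$omega * st$mu), hist_mean(h), tolerance = 1e-12)
  }
})

test_that("between-class variance matches hand-computed two-class values", {
  expect_equal(between_class_variance(two_delta_hist, 128L), 16256.25)
  h <- gray_hist_from_probs({p <- numeric(256); p[51] <- 0.25; p[201] <- 0.75; p})
  expect_equal(between_class_variance(h, 100L), 4218.75)
  expect_equal(between_class_variance(gray_histogram(matrix(7L, 4, 4)), 100L), 0)
})

test_that("the second-moment form differs from the variance by the squared mean", {
  h <- two_delta_hist
  expect_equal(between_class_moment(h, 128L), 32512.5)
  expect_equal(between_class_moment(h, 128L) - hist_mean(h)^2, 16256.25)
  hc <- gray_histogram(matrix(7L, 4, 4))
  expect_equal(between_class_moment(hc, 100L), 49)
  for (s in 1:40) {
    h <- random_hist(s + 500)
    thr <- random_thresholds(sample(1:5, 1))
    lhs <- between_class_moment(h, thr) - hist_mean(h)^2
    rhs <- between_class_variance(h, thr)
    # identity checked relative to the scale of the cancelled moments
    expect_lt(abs(lhs - rhs), 1e-9 * max(1, between_class_moment(h, thr)))
  }
})

test_that("the objective agrees with a per-pixel partition computation", {
  set.seed(31)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    thr <- random_thresholds(sample(1:4, 1))
    expect_equal(between_class_variance(gray_histogram(img), thr),
                 bcv_from_pixels(img, thr), tolerance = 1e-9)
  }
})

test_that("the objective is bounded by the total intensity variance", {
  set.seed(17)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    total_var <- mean((img - mean(img))^2)
    thr <- random_thresholds(sample(1:5, 1))
    v <- between_class_variance(gray_histogram(img), thr)
    expect_gte(v, 0)
    expect_lte(v, total_var + 1e-9)
  }
})

test_that("continuous positions decode to valid threshold sets", {
  expect_identical(decode_thresholds(c(180.4, 99.7)), c(100L, 180L))
  expect_identical(decode_thresholds(c(100.2, 99.8)), c(100L, 101L))
  expect_identical(decode_thresholds(-5.0), 1L)
  expect_identical(decode_thresholds(c(300, 400)), c(254L, 255L))  # cascade
  expect_identical(decode_thresholds(c(255, 255, 255)), c(253L, 254L, 255L))
  expect_error(decode_thresholds(rep(1, 255)), "distinct")
  # property: always strictly increasing within [1, 255]
  set.seed(5)
  for (i in 1:50) {
    t <- decode_thresholds(stats::runif(sample(1:8, 1), -20, 275))
    expect_true(all(diff(t) >= 1))
    expect_true(all(t >= 1 & t <= 255))
  }
})

test_that("the exhaustive oracle returns the smallest optimal tuple", {
  res <- otsu_exhaustive(two_delta_hist, 1)
  expect_equal(res$value, 16256.25)
  expect_identical(res$thresholds, 1L)   # all cuts tie; smallest returned
  # three equal spikes at 30/120/210: optimum separates them exactly
  p <- numeric(256); p[c(31, 121, 211)] <- 1 / 3
  h3 <- gray_hist_from_probs(p)
  res2 <- otsu_exhaustive(h3, 2)
  expect_equal(res2$value, 5400)
  expect_identical(res2$thresholds, c(31L, 121L))
  expect_equal(otsu_exhaustive(gray_histogram(matrix(9L, 2, 2)), 1)$value, 0)
  expect_error(otsu_exhaustive(two_delta_hist, 4), "n_thresh")
})

test_that("oracle fitness is non-decreasing in the number of thresholds", {
  h <- random_hist(77)
  vals <- vapply(1:3, function(n) otsu_exhaustive(h, n)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("the stochastic optimizer never beats the exhaustive oracle", {
  h <- random_hist(123)
  oracle <- otsu_exhaustive(h, 2)
  for (s in 1:5) {
    fit <- otsu_segment(h, 2, control = coot_control(max_iter = 100, seed = s))
    expect_lte(fit$fitness, oracle$value + 1e-9)
  }
})
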