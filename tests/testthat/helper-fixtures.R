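# Shared fixtures and independent oracles used across the suite.
# Everything is generated in code; no binary fixtures.

# A random gray-level probability histogram with a few Gaussian-ish bumps.
random_hist <- function(seed, levels = 256L) {
  set.seed(seed)
  n_modes <- sample(2:5, 1)
  w <- abs(stats::rnorm(n_modes)) + 0.2
  w <- w / sum(w)
  p <- numeric(levels)
  lev <- seq_len(levels) - 1L
  for (m in seq_len(n_modes)) {
    mu <- stats::runif(1, 10, levels - 11)
    sd <- stats::runif(1, 3, 25)
    p <- p + w[m] * stats::dnorm(lev, mu, sd)
  }
  p <- p / sum(p)
  gray_hist_from_probs(p)
}

# Re-create a "gray_hist" from bare probabilities without going through an
# image (counts are synthesized at a nominal 10^6 pixels).
gray_hist_from_probs <- function(p) {
  counts <- round(p * 1e6)
  img_levels <- length(p)
  structure(list(counts = counts, probs = p, total = sum(counts),
                 levels = img_levels), class = "gray_hist")
}

# A random strictly increasing integer threshold set.
random_thresholds <- function(n, levels = 256L) {
  sort(sample(seq_len(levels - 1L), n))
}

# Independent oracle: between-class variance computed per level, straight
# from the class definitions, without cumulative sums.
bcv_direct <- function(hist, thresholds) {
  p <- hist$probs
  lev <- seq_along(p) - 1L
  bnd <- c(0L, as.integer(thresholds), hist$levels)
  mu_g <- sum(lev * p)
  total <- 0
  for (k in seq_len(length(bnd) - 1L)) {
    in_class <- lev >= bnd[k] & lev < bnd[k + 1L]
    w <- sum(p[in_class])
    if (w > 0) {
      m <- sum(lev[in_class] * p[in_class]) / w
      total <- total + w * (m - mu_g)^2
    }
  }
  total
}

# Independent oracle on an actual image: partition the pixels themselves.
bcv_from_pixels <- function(image, thresholds) {
  px <- as.numeric(image)
  lab <- findInterval(px, thresholds)
  mu_g <- mean(px)
  total <- 0
  for (k in unique(lab)) {
    sel <- px[lab == k]
    total <- total + (length(sel) / length(px)) * (mean(sel) - mu_g)^2
  }
  total
}

excess_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

fast_control <- function(seed = 1L, ...) {
  coot_control(max_iter = 60L, seed = seed, ...)
}
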