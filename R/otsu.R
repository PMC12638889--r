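#' Gray-level histogram of an image
#'
#' Counts pixels per gray level and normalizes to a probability distribution
#' \eqn{p_i = n_i / N}. The histogram is the sole input to the thresholding
#' objective, so it is computed once per image.
#'
#' @param image Integer matrix with values in `0:(levels - 1)`.
#' @param levels Number of gray levels \eqn{L} (default 256).
#' @return An object of class `"gray_hist"`: list with `counts` (length
#'   `levels`), `probs`, `total` pixel count and `levels`.
#' @examples
#' h <- gray_histogram(matrix(c(0L, 0L, 255L, 255L), 2))
#' h$probs[c(1, 256)]   # 0.5 at levels 0 and 255
#' @export
gray_histogram <- function(image, levels = 256L) {
  image <- check_gray_image(image, levels)
  counts <- tabulate(as.integer(image) + 1L, nbins = levels)
  structure(list(counts = counts, probs = counts / length(image),
                 total = length(image), levels = as.integer(levels)),
            class = "gray_hist")
}

as_gray_hist <- function(x, levels = 256L) {
  if (inherits(x, "gray_hist")) return(x)
  if (is.matrix(x)) return(gray_histogram(x, levels))
  stop("expected a gray-level histogram or an image matrix", call. = FALSE)
}

## Build a histogram object directly from probabilities (internal; used by
## tests and the exhaustive sweep on synthetic distributions).
hist_from_probs <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("'probs' must be a probability vector", call. = FALSE)
  structure(list(counts = NULL, probs = probs, total = NA_integer_,
                 levels = length(probs)), class = "gray_hist")
}

#' @export
print.gray_hist <- function(x, ...) {
  cat(sprintf("Gray-level histogram: %d levels, %s pixels, mean %.2f\n",
              x$levels, format(x$total), hist_mean(x)))
  invisible(x)
}

#' Histogram mean and per-class statistics
#'
#' `hist_mean()` is the global mean gray level \eqn{\mu = \sum_i i\, p_i}.
#' `class_stats()` partitions the gray axis at the given thresholds using the
#' half-open convention (level \eqn{g} belongs to class \eqn{k} iff
#' \eqn{T_k \le g < T_{k+1}}, with \eqn{T_0 = 0} and \eqn{T_{n+1} = L}) and
#' returns the class weights \eqn{\omega_k} and means \eqn{\mu_k}. An empty
#' class has weight 0 and, by convention, mean 0; it contributes nothing to
#' the variance. The statistics satisfy \eqn{\sum_k \omega_k = 1} and
#' \eqn{\sum_k \omega_k \mu_k = \mu}.
#'
#' @param hist A `"gray_hist"` object (or an image matrix, converted).
#' @param thresholds Strictly increasing integer thresholds in
#'   `1:(levels - 1)`; may be empty (a single class).
#' @return `hist_mean()`: a scalar. `class_stats()`: list with `omega`, `mu`
#'   (length `length(thresholds) + 1`) and `mu_global`.
#' @examples
#' h <- gray_histogram(matrix(c(0L, 0L, 255L, 255L), 2))
#' hist_mean(h)                    # 127.5
#' class_stats(h, 128L)$mu        # c(0, 255)
#' @export
hist_mean <- function(hist) {
  hist <- as_gray_hist(hist)
  sum((seq_len(hist$levels) - 1) * hist$probs)
}

check_thresholds <- function(thresholds, levels) {
  if (length(thresholds) == 0L) return(integer(0))
  thresholds <- as.numeric(thresholds)
  if (any(thresholds != round(thresholds)))
    stop("thresholds must be integers", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (thresholds[1L] < 1 || thresholds[length(thresholds)] > levels - 1)
    stop(sprintf("thresholds must lie in [1, %d]", levels - 1), call. = FALSE)
  as.integer(thresholds)
}

#' @rdname hist_mean
#' @export
class_stats <- function(hist, thresholds) {
  hist <- as_gray_hist(hist)
  L <- hist$levels
  thr <- check_thresholds(thresholds, L)
  bnd <- c(0L, thr, L)                       # class k covers [bnd_k, bnd_{k+1})
  cp <- c(0, cumsum(hist$probs))             # cp[m + 1] = sum_{i < m} p_i
  cs <- c(0, cumsum((seq_len(L) - 1) * hist$probs))
  omega <- cp[bnd[-1L] + 1L] - cp[bnd[-length(bnd)] + 1L]
  s <- cs[bnd[-1L] + 1L] - cs[bnd[-length(bnd)] + 1L]
  mu <- ifelse(omega > 0, s / omega, 0)
  list(omega = omega, mu = mu, mu_global = cs[L + 1L])
}

#' Between-class variance of a thresholded histogram
#'
#' The multilevel Otsu criterion
#' \eqn{\sigma_B^2 = \sum_k \omega_k (\mu_k - \mu)^2}, maximized over
#' threshold sets to segment an image. `between_class_moment()` is the
#' equivalent second-moment form \eqn{\sum_k \omega_k \mu_k^2}, which differs
#' from \eqn{\sigma_B^2} by the constant \eqn{\mu^2} and therefore shares its
#' argmax.
#'
#' @inheritParams class_stats
#' @return A non-negative scalar.
#' @examples
#' h <- gray_histogram(matrix(c(0L, 0L, 255L, 255L), 2))
#' between_class_variance(h, 128L)   # 16256.25
#' between_class_moment(h, 128L) - hist_mean(h)^2  # identical
#' @export
between_class_variance <- function(hist, thresholds) {
  st <- class_stats(hist, thresholds)
  sum(st$omega * (st$mu - st$mu_global)^2)
}

#' @rdname between_class_variance
#' @export
between_class_moment <- function(hist, thresholds) {
  st <- class_stats(hist, thresholds)
  sum(st$omega * st$mu^2)
}

#' Decode a continuous optimizer position into integer thresholds
#'
#' Agents of [coot_optim()] live in the continuous box `[0, levels - 1]^n`;
#' at evaluation time each coordinate is rounded to the nearest integer,
#' clamped into `[1, levels - 1]`, and the set is sorted. Duplicates are
#' resolved by pushing the later duplicate up to the next free integer; if
#' that overflows the top of the range the set cascades back down from
#' `levels - 1` so the result is always strictly increasing.
#'
#' @param position Numeric vector, one coordinate per requested threshold.
#' @param levels Number of gray levels (default 256).
#' @return An increasing integer vector of the same length.
#' @examples
#' decode_thresholds(c(180.4, 99.7))   # c(100, 180)
#' decode_thresholds(c(100.2, 99.8))   # c(100, 101)
#' decode_thresholds(-5)               # 1
#' @export
decode_thresholds <- function(position, levels = 256L) {
  n <- length(position)
  if (n == 0L) return(integer(0))
  if (n >= levels - 1L)
    stop("cannot form that many distinct thresholds", call. = FALSE)
  t <- sort(pmin(pmax(round(position), 1), levels - 1))
  if (n > 1L) {
    for (k in 2:n) if (t[k] <= t[k - 1L]) t[k] <- t[k - 1L] + 1
    if (t[n] > levels - 1L) {           # overflow: cascade down from the top
      t[n] <- levels - 1L
      for (k in (n - 1L):1L) t[k] <- min(t[k], t[k + 1L] - 1L)
    }
  }
  as.integer(t)
}

#' Exhaustive-search Otsu oracle
#'
#' Enumerates every strictly increasing threshold tuple and returns the
#' lexicographically smallest one attaining the maximal between-class
#' variance. Feasible for up to three thresholds (the enumeration is
#' polynomial but grows as \eqn{L^n}); used as the ground-truth oracle
#' against which the stochastic optimizer is validated.
#'
#' @inheritParams class_stats
#' @param n_thresh Number of thresholds, in `1:3` (raise `max_n` at your own
#'   risk).
#' @param max_n Combinatorial guard (default 3).
#' @return List with `thresholds` (integer vector) and `value` (the maximal
#'   between-class variance).
#' @examples
#' h <- gray_histogram(matrix(c(0L, 0L, 255L, 255L), 2))
#' otsu_exhaustive(h, 1)   # thresholds 1 (all cuts tie), value 16256.25
#' @export
otsu_exhaustive <- function(hist, n_thresh, max_n = 3L) {
  hist <- as_gray_hist(hist)
  if (!is_count(n_thresh) || n_thresh > max_n)
    stop(sprintf("'n_thresh' must be an integer in [1, %d]", max_n),
         call. = FALSE)
  L <- hist$levels
  p <- hist$probs
  cp <- c(0, cumsum(p))
  cs <- c(0, cumsum((seq_len(L) - 1) * p))
  mu <- cs[L + 1L]

  ## between-class variance for a matrix of boundary columns (vectorized in
  ## the last threshold); bnd is c(0, t1, ..., tn, L)
  segvar <- function(lo, hi) {            # vectors of class bounds [lo, hi)
    w <- cp[hi + 1L] - cp[lo + 1L]
    s <- cs[hi + 1L] - cs[lo + 1L]
    m <- ifelse(w > 0, s / w, 0)
    w * (m - mu)^2
  }

  best_val <- -Inf
  best_thr <- NULL
  tmax <- L - 1L
  if (n_thresh == 1L) {
    t1 <- seq_len(tmax)
    v <- segvar(rep(0L, tmax), t1) + segvar(t1, rep(L, tmax))
    i <- which.max(v)                     # first index = smallest tuple
    best_val <- v[i]; best_thr <- t1[i]
  } else if (n_thresh == 2L) {
    for (t1 in seq_len(tmax - 1L)) {
      t2 <- seq.int(t1 + 1L, tmax)
      v <- segvar(rep(0L, length(t2)), rep(t1, length(t2))) +
        segvar(rep(t1, length(t2)), t2) + segvar(t2, rep(L, length(t2)))
      i <- which.max(v)                   # ascending sweep + strict improvement
      if (v[i] > best_val) { best_val <- v[i]; best_thr <- c(t1, t2[i]) }
    }
  } else {
    for (t1 in seq_len(tmax - 2L)) {
      head1 <- segvar(0L, t1)
      for (t2 in seq.int(t1 + 1L, tmax - 1L)) {
        t3 <- seq.int(t2 + 1L, tmax)
        v <- head1 + segvar(rep(t1, length(t3)), rep(t2, length(t3))) +
          segvar(rep(t2, length(t3)), t3) + segvar(t3, rep(L, length(t3)))
        i <- which.max(v)
        if (v[i] > best_val) { best_val <- v[i]; best_thr <- c(t1, t2, t3[i]) }
      }
    }
  }
  list(thresholds = as.integer(best_thr), value = best_val)
}

## Fast closure evaluating between-class variance at a continuous position.
## Precomputes the cumulative sums once so each call is O(n_thresh).
make_otsu_objective <- function(hist) {
  L <- hist$levels
  p <- hist$probs
  cp <- c(0, cumsum(p))
  cs <- c(0, cumsum((seq_len(L) - 1) * p))
  mu <- cs[L + 1L]
  function(position) {
    thr <- decode_thresholds(position, L)
    bnd <- c(0L, thr, L)
    w <- cp[bnd[-1L] + 1L] - cp[bnd[-length(bnd)] + 1L]
    s <- cs[bnd[-1L] + 1L] - cs[bnd[-length(bnd)] + 1L]
    m <- ifelse(w > 0, s / w, 0)
    sum(w * (m - mu)^2)
  }
}
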