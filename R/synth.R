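#' Synthetic multimodal test images
#'
#' Generates grayscale images whose histograms are Gaussian mixtures with 2-6
#' modes, emulating the multimodal histograms of the natural and CT benchmark
#' images commonly used to evaluate multilevel thresholding. The image is laid
#' out as contiguous horizontal bands, one per mode (band heights proportional
#' to the mode weights), with per-pixel Gaussian noise, so that a correct
#' segmentation is visually obvious.
#'
#' @param modes A data frame (or list of vectors) with columns `mean` (gray
#'   level in `0:(levels-1)`), `sd` (gray levels, `>= 0`) and `weight`
#'   (fractions summing to 1).
#' @param height,width Image size in pixels.
#' @param seed RNG seed; the generator is deterministic given the seed and
#'   restores the caller's RNG state.
#' @param levels Number of gray levels (default 256).
#' @return An integer matrix in `0:(levels - 1)`.
#' @examples
#' img <- synth_multimodal_image(three_mode_spec(), 64, 64, seed = 1)
#' dim(img)
#' @export
synth_multimodal_image <- function(modes, height, width, seed = NULL,
                                   levels = 256L) {
  modes <- as.data.frame(modes)
  if (nrow(modes) < 1L) stop("need at least one mode", call. = FALSE)
  if (!all(c("mean", "sd", "weight") %in% names(modes)))
    stop("'modes' needs columns mean, sd, weight", call. = FALSE)
  if (any(modes$mean < 0) || any(modes$mean > levels - 1L))
    stop("mode means must lie in the gray range", call. = FALSE)
  if (any(modes$sd < 0)) stop("mode sds must be non-negative", call. = FALSE)
  if (abs(sum(modes$weight) - 1) > 1e-8 || any(modes$weight < 0))
    stop("mode weights must be non-negative and sum to 1", call. = FALSE)
  if (!is_count(height) || !is_count(width))
    stop("invalid image dimensions", call. = FALSE)

  ## band boundaries: cumulative weights over rows, last band absorbs rounding
  edges <- c(0, round(cumsum(modes$weight) * height))
  edges[length(edges)] <- height
  with_seed(seed, {
    img <- matrix(0L, height, width)
    for (m in seq_len(nrow(modes))) {
      rows <- seq.int(edges[m] + 1L, edges[m + 1L])
      if (edges[m + 1L] <= edges[m]) next
      vals <- stats::rnorm(length(rows) * width, modes$mean[m], modes$sd[m])
      img[rows, ] <- as.integer(pmin(pmax(round(vals), 0), levels - 1L))
    }
    img
  })
}

#' @describeIn synth_multimodal_image The three-mode specification used
#'   throughout the package's tests: modes at 60, 128 and 200 gray levels,
#'   sd 8, equal weights.
#' @export
three_mode_spec <- function() {
  data.frame(mean = c(60, 128, 200), sd = 8, weight = 1 / 3)
}

#' Two-delta test image with a closed-form optimum
#'
#' Half the pixels at gray level `low`, half at `high` (top rows get `low`;
#' with an odd pixel count the low half receives the extra pixel). Its
#' bilevel Otsu optimum is known in closed form: any threshold separating the
#' two levels attains \eqn{\sigma_B^2 = (high - low)^2 / 4}, e.g. 16256.25
#' for (0, 255). This makes the image an exact oracle fixture.
#'
#' @param low,high Gray levels with `0 <= low < high <= 255`.
#' @param height,width Image size.
#' @return An integer matrix.
#' @examples
#' synth_two_delta_image(0, 255, 2, 2)
#' @export
synth_two_delta_image <- function(low, high, height, width) {
  if (low >= high || low < 0 || high > 255)
    stop("need 0 <= low < high <= 255", call. = FALSE)
  if (!is_count(height) || !is_count(width))
    stop("invalid image dimensions", call. = FALSE)
  n <- height * width
  n_low <- ceiling(n / 2)
  vals <- c(rep(as.integer(low), n_low), rep(as.integer(high), n - n_low))
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

#' Analytic benchmark objectives
#'
#' Standard continuous test functions with global minimum 0 at a known point,
#' used to validate the optimizers: `sphere` (minimum at the origin),
#' `rastrigin` (highly multimodal, minimum at the origin) and `rosenbrock`
#' (curved valley, minimum at the all-ones point).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param dim Problem dimension (the returned function still checks its
#'   input length).
#' @return A function of a numeric vector returning a scalar, with
#'   attributes `minimum` (the optimal value, 0) and `argmin`.
#' @examples
#' f <- test_function("sphere", 3)
#' f(c(0, 0, 0))   # 0
#' @export
test_function <- function(name, dim) {
  if (!is_count(dim)) stop("'dim' must be a positive integer", call. = FALSE)
  f <- switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      if (length(x) < 2L) return((1 - x)^2)
      sum(100 * (x[-1L] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
    },
    stop(sprintf("unknown test function '%s'", name), call. = FALSE))
  attr(f, "minimum") <- 0
  attr(f, "argmin") <- if (identical(name, "rosenbrock")) rep(1, dim) else rep(0, dim)
  f
}
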