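#' Apply a threshold set to an image
#'
#' Labels each pixel with its intensity class under the half-open convention:
#' class \eqn{k} (0-based) iff \eqn{T_k \le g < T_{k+1}} with \eqn{T_0 = 0}
#' and \eqn{T_{n+1} = L}; equivalently, a pixel's label is the number of
#' thresholds less than or equal to it. The rendered image replaces each
#' pixel with its class representative: the rounded class mean intensity
#' (`render = "class_mean"`, default) or the class interval midpoint
#' (`"midpoint"`). An empty class falls back to its interval midpoint.
#'
#' @param image Integer matrix in `0:(levels - 1)`.
#' @param thresholds Strictly increasing integer thresholds in
#'   `1:(levels - 1)`; may be empty (single class).
#' @param render Representative-intensity rule.
#' @param levels Number of gray levels (default 256).
#' @return List with `labels` (integer matrix in `0:length(thresholds)`),
#'   `rendered` (integer matrix), `thresholds` and `representatives`.
#' @examples
#' img <- matrix(c(40L, 200L, 150L, 250L), 2)
#' threshold_apply(img, c(100L, 180L))$labels
#' @export
threshold_apply <- function(image, thresholds,
                            render = c("class_mean", "midpoint"),
                            levels = 256L) {
  image <- check_gray_image(image, levels)
  render <- match.arg(render)
  thr <- check_thresholds(thresholds, levels)
  labels <- matrix(findInterval(image, thr), nrow(image), ncol(image))
  bnd <- c(0L, thr, levels)                # class k covers [bnd_k, bnd_{k+1})
  n_class <- length(thr) + 1L
  mids <- as.integer(round((bnd[-length(bnd)] + bnd[-1L] - 1L) / 2))
  reps <- mids
  if (render == "class_mean") {
    for (k in seq_len(n_class)) {
      px <- image[labels == k - 1L]
      if (length(px) > 0L) reps[k] <- as.integer(round(mean(px)))
    }
  }
  rendered <- matrix(reps[labels + 1L], nrow(image), ncol(image))
  storage.mode(labels) <- "integer"
  storage.mode(rendered) <- "integer"
  list(labels = labels, rendered = rendered, thresholds = thr,
       representatives = reps)
}

#' Multilevel Otsu thresholding by coot swarm optimization
#'
#' Fits a multilevel threshold set to a grayscale image by maximizing the
#' between-class variance of its gray-level histogram with the improved coot
#' optimizer (default) or the baseline variant. The continuous optimizer
#' works on `[0, levels - 1]^k`; positions are decoded to strictly increasing
#' integer thresholds at evaluation time (see [decode_thresholds()]). The
#' fitted object carries the thresholds, the objective value, the convergence
#' trace, the segmented image and (optionally) PSNR/SSIM/FSIM scores of the
#' rendered segmentation against the original.
#'
#' @param image Integer matrix in `0:(levels - 1)` (see [read_gray_image()]),
#'   or a `"gray_hist"` object if only thresholds are wanted (no rendering or
#'   metrics are then computed).
#' @param k Number of thresholds, 1 to 8.
#' @param algorithm `"icoot"` (improved, default) or `"coot"` (baseline).
#' @param control A [coot_control()] object; `seed` makes the fit
#'   reproducible.
#' @param render Representative-intensity rule for the segmented image.
#' @param metrics Compute the image-quality metric report (default `TRUE`
#'   when an image is supplied).
#' @param levels Number of gray levels (default 256).
#'
#' @return An object of class `"otsu_seg"`: list with `thresholds`,
#'   `fitness` (between-class variance at the thresholds), `trace`,
#'   `labels`, `rendered`, `metrics`, `histogram`, `algorithm`, `control`,
#'   `levels` and `call`. Methods: `print`, `summary`, `coef` (the
#'   thresholds), `fitted` (the rendered image), `residuals` (original minus
#'   rendered), `predict` (segment a new image with the fitted thresholds)
#'   and `plot` (histogram with threshold cuts plus convergence trace).
#'
#' @examples
#' img <- synth_multimodal_image(three_mode_spec(), 64, 64, seed = 1)
#' fit <- otsu_segment(img, k = 2,
#'                     control = coot_control(max_iter = 60, seed = 1))
#' coef(fit)
#' fit$fitness
#' @seealso [coot_optim()], [otsu_exhaustive()] for the exact oracle,
#'   [metric_report()].
#' @export
otsu_segment <- function(image, k, algorithm = c("icoot", "coot"),
                         control = coot_control(),
                         render = c("class_mean", "midpoint"),
                         metrics = TRUE, levels = 256L) {
  algorithm <- match.arg(algorithm)
  render <- match.arg(render)
  if (!is_count(k) || k > 8)
    stop("'k' must be an integer between 1 and 8", call. = FALSE)
  have_image <- !inherits(image, "gray_hist")
  if (have_image) image <- check_gray_image(image, levels)
  h <- as_gray_hist(image, levels)

  fn <- make_otsu_objective(h)
  opt <- coot_optim(fn, lower = rep(0, k), upper = rep(levels - 1, k),
                    control = control, algorithm = algorithm,
                    mode = "maximize")
  thr <- decode_thresholds(opt$par, levels)
  fitness <- between_class_variance(h, thr)   # exact value at the decoded set

  seg <- if (have_image) threshold_apply(image, thr, render, levels) else NULL
  rep_metrics <- if (have_image && metrics)
    metric_report(image, seg$rendered) else NULL

  structure(list(thresholds = thr, fitness = fitness, trace = opt$trace,
                 labels = seg$labels, rendered = seg$rendered,
                 representatives = seg$representatives,
                 metrics = rep_metrics, histogram = h, image = if (have_image) image,
                 algorithm = algorithm, control = control,
                 render = render, levels = as.integer(levels),
                 evaluations = opt$evaluations, call = match.call()),
            class = "otsu_seg")
}

#' @export
print.otsu_seg <- function(x, digits = 6L, ...) {
  cat(sprintf("Multilevel Otsu thresholding (%s), %d threshold%s\n",
              toupper(x$algorithm), length(x$thresholds),
              if (length(x$thresholds) == 1L) "" else "s"))
  cat("Thresholds: ", paste(x$thresholds, collapse = ", "), "\n", sep = "")
  cat("Between-class variance: ", format(x$fitness, digits = digits),
      "\n", sep = "")
  if (!is.null(x$metrics))
    cat(sprintf("PSNR %s dB, SSIM %.4f, FSIM %.4f\n",
                if (is.infinite(x$metrics$psnr)) "inf"
                else sprintf("%.4f", x$metrics$psnr),
                x$metrics$ssim, x$metrics$fsim))
  invisible(x)
}

#' @export
summary.otsu_seg <- function(object, ...) {
  st <- class_stats(object$histogram, object$thresholds)
  out <- list(fit = object,
              classes = data.frame(
                class = seq_along(st$omega) - 1L,
                from = c(0L, object$thresholds),
                to = c(object$thresholds, object$levels) - 1L,
                weight = st$omega, mean = st$mu,
                representative = if (!is.null(object$representatives))
                  object$representatives else NA_integer_))
  class(out) <- "summary.otsu_seg"
  out
}

#' @export
print.summary.otsu_seg <- function(x, ...) {
  print(x$fit)
  cat("\nIntensity classes:\n")
  print(x$classes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.otsu_seg <- function(object, ...) object$thresholds

#' @export
fitted.otsu_seg <- function(object, ...) object$rendered

#' @export
residuals.otsu_seg <- function(object, ...) {
  if (is.null(object$rendered))
    stop("fit has no rendered image (fitted from a histogram)", call. = FALSE)
  object$image - object$rendered
}

#' Segment a new image with fitted thresholds
#'
#' @param object An `"otsu_seg"` fit.
#' @param newdata Integer gray-level matrix; defaults to the training image.
#' @param type `"labels"` for the class map, `"rendered"` for the rendered
#'   segmentation.
#' @param ... Unused.
#' @return An integer matrix.
#' @export
predict.otsu_seg <- function(object, newdata = NULL,
                             type = c("labels", "rendered"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$labels))
      stop("no training image stored; supply 'newdata'", call. = FALSE)
    return(object[[if (type == "labels") "labels" else "rendered"]])
  }
  seg <- threshold_apply(newdata, object$thresholds, object$render,
                         object$levels)
  seg[[if (type == "labels") "labels" else "rendered"]]
}

#' Plot a fitted multilevel thresholding
#'
#' Left: the gray-level histogram with the fitted threshold cuts. Right: the
#' optimizer's convergence trace.
#'
#' @param x An `"otsu_seg"` object.
#' @param ... Passed to the histogram panel's [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.otsu_seg <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lev <- seq_len(x$levels) - 1L
  graphics::plot(lev, x$histogram$probs, type = "h", col = "grey50",
                 xlab = "Gray level", ylab = "Probability",
                 main = "Histogram and thresholds", ...)
  graphics::abline(v = x$thresholds, col = "red", lwd = 2)
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "Iteration", ylab = "Best between-class variance",
                 main = sprintf("%s convergence", toupper(x$algorithm)))
  invisible(x)
}

#' Replicated segment-and-evaluate runs
#'
#' Runs [otsu_segment()] across several seeds and collects per-run
#' thresholds, fitness and quality metrics, the replicated protocol used to
#' report mean/standard-deviation tables for stochastic thresholding
#' optimizers.
#'
#' @inheritParams otsu_segment
#' @param seeds Integer vector of seeds, one run each.
#' @return A data frame with one row per run (columns `seed`, `fitness`,
#'   `psnr`, `ssim`, `fsim`, `rmse` and `t1..tk` threshold columns) carrying
#'   a `"summary"` attribute with per-column means and standard deviations.
#' @examples
#' img <- synth_two_delta_image(0, 255, 32, 32)
#' runs <- otsu_segment_runs(img, 1, seeds = 1:2,
#'                           control = coot_control(max_iter = 25))
#' attr(runs, "summary")
#' @export
otsu_segment_runs <- function(image, k, seeds = 1:10,
                              algorithm = c("icoot", "coot"),
                              control = coot_control(),
                              render = c("class_mean", "midpoint"),
                              levels = 256L) {
  algorithm <- match.arg(algorithm)
  render <- match.arg(render)
  rows <- lapply(seeds, function(s) {
    ctl <- control
    ctl$seed <- as.integer(s)
    fit <- otsu_segment(image, k, algorithm = algorithm, control = ctl,
                        render = render, metrics = TRUE, levels = levels)
    thr <- as.list(fit$thresholds)
    names(thr) <- paste0("t", seq_along(thr))
    c(list(seed = as.integer(s), fitness = fit$fitness,
           psnr = fit$metrics$psnr, ssim = fit$metrics$ssim,
           fsim = fit$metrics$fsim, rmse = fit$metrics$rmse), thr)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  num <- out[, setdiff(names(out), "seed"), drop = FALSE]
  attr(out, "summary") <- data.frame(
    statistic = c("mean", "sd"),
    rbind(vapply(num, mean, numeric(1)), vapply(num, stats::sd, numeric(1))))
  out
}
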