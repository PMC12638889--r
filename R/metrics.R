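#' Image fidelity metrics: RMSE, PSNR, SSIM
#'
#' Reference implementations of the metrics used to score a segmented image
#' against its original. `img_rmse()` is the root-mean-squared intensity
#' difference; `img_psnr()` the peak signal-to-noise ratio
#' \eqn{20 \log_{10}(255 / RMSE)} in dB, returning `Inf` for identical
#' images; `img_ssim()` the structural similarity index
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' computed from whole-image statistics by default (the formulation used when
#' scoring thresholded segmentations), with an 11 x 11 sliding-window
#' mean-SSIM mode behind `windowed = TRUE`. Variances and the covariance are
#' population moments (denominator \eqn{n}).
#'
#' @param ref,test Numeric matrices of identical dimensions (gray levels).
#' @param c1,c2 SSIM stabilizing constants; defaults 6.5025 and 58.52252
#'   (the usual \eqn{(0.01 \cdot 255)^2} and \eqn{(0.03 \cdot 255)^2}).
#' @param windowed Use the 11 x 11 sliding-window mean SSIM instead of global
#'   statistics.
#' @param window Window side for the windowed mode (odd, default 11).
#' @return A scalar.
#' @examples
#' a <- matrix(0L, 4, 4); b <- matrix(255L, 4, 4)
#' img_rmse(a, b)   # 255
#' img_psnr(a, b)   # 0 dB
#' img_ssim(a, a)   # 1
#' @name image_fidelity
NULL

#' @rdname image_fidelity
#' @export
img_rmse <- function(ref, test) {
  check_same_dim(ref, test)
  sqrt(mean((as.numeric(ref) - as.numeric(test))^2))
}

#' @rdname image_fidelity
#' @export
img_psnr <- function(ref, test) {
  r <- img_rmse(ref, test)
  if (r == 0) Inf else 20 * log10(255 / r)
}

#' @rdname image_fidelity
#' @export
img_ssim <- function(ref, test, c1 = 6.5025, c2 = 58.52252,
                     windowed = FALSE, window = 11L) {
  check_same_dim(ref, test)
  x <- ref; y <- test
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  if (!windowed) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mx <- box_mean(x, window); my <- box_mean(y, window)
  vx <- box_mean(x * x, window) - mx^2
  vy <- box_mean(y * y, window) - my^2
  cxy <- box_mean(x * y, window) - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

## Moving-average filter with replicate padding (separable box filter).
box_mean <- function(x, k) {
  pad <- (k - 1L) %/% 2L
  xp <- x[c(rep(1L, pad), seq_len(nrow(x)), rep(nrow(x), pad)),
          c(rep(1L, pad), seq_len(ncol(x)), rep(ncol(x), pad)), drop = FALSE]
  ## cumulative-sum trick along both axes
  cs <- apply(xp, 2L, cumsum)
  rowsum_ <- cs[k:nrow(xp), , drop = FALSE] -
    rbind(0, cs[seq_len(nrow(xp) - k), , drop = FALSE])
  cs2 <- t(apply(rowsum_, 1L, cumsum))
  out <- cs2[, k:ncol(xp), drop = FALSE] -
    cbind(0, cs2[, seq_len(ncol(xp) - k), drop = FALSE])
  out / (k * k)
}

#' Scharr gradient magnitude
#'
#' Per-pixel gradient magnitude using the 3 x 3 Scharr stencil
#' (weights 3/10/3, normalized by 16), with replicate border padding. Used by
#' the gradient-similarity term of [img_fsim()].
#'
#' @param image Numeric matrix.
#' @return A numeric matrix of the same size, non-negative.
#' @examples
#' scharr_gradient(matrix(5, 4, 4))   # all zero on a constant image
#' @export
scharr_gradient <- function(image) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a non-empty matrix", call. = FALSE)
  x <- image
  storage.mode(x) <- "double"
  nr <- nrow(x); nc <- ncol(x)
  up    <- x[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- x[c(seq.int(2L, length.out = nr - 1L), nr), , drop = FALSE]
  shl <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]      # left
  shr <- function(m) m[, c(seq.int(2L, length.out = nc - 1L), nc), drop = FALSE]
  gx <- (3 * shl(up) + 10 * shl(x) + 3 * shl(down) -
           3 * shr(up) - 10 * shr(x) - 3 * shr(down)) / 16
  gy <- (3 * shl(up) + 10 * up + 3 * shr(up) -
           3 * shl(down) - 10 * down - 3 * shr(down)) / 16
  sqrt(gx^2 + gy^2)
}

#' Log-Gabor phase congruency map
#'
#' Contrast-invariant per-pixel feature significance in \[0, 1\], computed
#' from a bank of log-Gabor filters (4 scales, 4 orientations by default)
#' via the frequency domain. For each orientation the filter responses are
#' combined into local energy and normalized by the summed amplitudes; the
#' orientation sums give the phase-congruency map. Noise compensation is not
#' applied (see the methods vignette). A constant image has no features and
#' maps to zero everywhere.
#'
#' @param image Numeric matrix (at least 2 x 2).
#' @param nscale,norient Filter-bank size.
#' @param min_wavelength Wavelength of the smallest-scale filter (pixels).
#' @param mult Scaling factor between successive filter wavelengths.
#' @param sigma_on_f Ratio defining the radial bandwidth of each filter.
#' @return A numeric matrix of the same size with values in \[0, 1\].
#' @examples
#' pc <- phase_congruency(synth_two_delta_image(0, 255, 16, 16))
#' range(pc)
#' @export
phase_congruency <- function(image, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2, sigma_on_f = 0.55) {
  if (!is.matrix(image) || nrow(image) < 2L || ncol(image) < 2L)
    stop("'image' must be a matrix of at least 2 x 2", call. = FALSE)
  x <- image
  storage.mode(x) <- "double"
  nr <- nrow(x); nc <- ncol(x)
  eps <- 1e-4

  freq_axis <- function(n) {
    c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L)) / n
  }
  fy <- matrix(freq_axis(nr), nr, nc)
  fx <- matrix(freq_axis(nc), nr, nc, byrow = TRUE)
  radius <- sqrt(fx^2 + fy^2)
  radius[1L, 1L] <- 1                      # avoid log(0) at DC; filter zeroed
  theta <- atan2(-fy, fx)
  sin_t <- sin(theta); cos_t <- cos(theta)

  imfft <- stats::fft(x)
  sum_energy <- matrix(0, nr, nc)
  sum_amp <- matrix(0, nr, nc)
  sigma_theta <- pi / norient / 1.5

  for (o in seq_len(norient)) {
    angle <- (o - 1) * pi / norient
    ds <- sin_t * cos(angle) - cos_t * sin(angle)
    dc <- cos_t * cos(angle) + sin_t * sin(angle)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * sigma_theta^2))

    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc)
    e_list <- vector("list", nscale); o_list <- vector("list", nscale)
    for (s in seq_len(nscale)) {
      wavelength <- min_wavelength * mult^(s - 1)
      f0 <- 1 / wavelength
      loggabor <- exp(-(log(radius / f0))^2 / (2 * log(sigma_on_f)^2))
      loggabor[1L, 1L] <- 0
      filt <- loggabor * spread
      resp <- stats::fft(imfft * filt, inverse = TRUE) / length(x)
      e <- Re(resp); od <- Im(resp)
      e_list[[s]] <- e; o_list[[s]] <- od
      sumE <- sumE + e; sumO <- sumO + od
      sumAn <- sumAn + sqrt(e^2 + od^2)
    }
    xmag <- sqrt(sumE^2 + sumO^2) + eps
    meanE <- sumE / xmag; meanO <- sumO / xmag
    energy <- matrix(0, nr, nc)
    for (s in seq_len(nscale)) {
      e <- e_list[[s]]; od <- o_list[[s]]
      energy <- energy + e * meanE + od * meanO - abs(e * meanO - od * meanE)
    }
    sum_energy <- sum_energy + pmax(energy, 0)
    sum_amp <- sum_amp + sumAn
  }
  pc <- sum_energy / (sum_amp + eps)
  pmin(pmax(pc, 0), 1)
}

#' Feature similarity index (FSIM)
#'
#' Combines phase-congruency similarity \eqn{S_{PC}} and gradient-magnitude
#' similarity \eqn{S_G},
#' \deqn{S_{PC} = \frac{2 PC_1 PC_2 + T_1}{PC_1^2 + PC_2^2 + T_1}, \quad
#'       S_G = \frac{2 G_1 G_2 + T_2}{G_1^2 + G_2^2 + T_2},}
#' into the per-pixel similarity \eqn{S_L = S_{PC} S_G}, then averages it
#' weighted by the maximal phase congruency \eqn{PC_m = \max(PC_1, PC_2)}:
#' \eqn{FSIM = \sum S_L PC_m / \sum PC_m}. Gradients use the Scharr operator;
#' phase congruency the log-Gabor bank of [phase_congruency()].
#'
#' @inheritParams image_fidelity
#' @param t1,t2 Stabilizing constants for the phase-congruency and gradient
#'   terms (defaults 0.85 and 160, the customary values for 8-bit images).
#' @param ... Passed to [phase_congruency()].
#' @return A scalar in \[0, 1\]. Two identical constant images (no features
#'   anywhere) are defined to have FSIM 1; differing featureless images raise
#'   an error.
#' @examples
#' img <- synth_two_delta_image(0, 255, 16, 16)
#' img_fsim(img, img)   # 1
#' @export
img_fsim <- function(ref, test, t1 = 0.85, t2 = 160, ...) {
  check_same_dim(ref, test)
  pc1 <- phase_congruency(ref, ...)
  pc2 <- phase_congruency(test, ...)
  g1 <- scharr_gradient(ref)
  g2 <- scharr_gradient(test)
  s_pc <- (2 * pc1 * pc2 + t1) / (pc1^2 + pc2^2 + t1)
  s_g <- (2 * g1 * g2 + t2) / (g1^2 + g2^2 + t2)
  pcm <- pmax(pc1, pc2)
  denom <- sum(pcm)
  if (denom < .Machine$double.eps * length(pcm)) {
    if (all(ref == test)) return(1)
    stop("neither image contains detectable features", call. = FALSE)
  }
  sum(s_pc * s_g * pcm) / denom
}

#' Full metric report between a reference and a test image
#'
#' Convenience wrapper computing RMSE, PSNR, SSIM and FSIM in one pass and
#' recording the constants used, as embedded in segmentation reports.
#'
#' @inheritParams image_fidelity
#' @param c1,c2 SSIM constants.
#' @param t1,t2 FSIM constants.
#' @return A list with `rmse`, `psnr`, `ssim`, `fsim` and `constants_used`.
#' @export
metric_report <- function(ref, test, c1 = 6.5025, c2 = 58.52252,
                          t1 = 0.85, t2 = 160) {
  list(rmse = img_rmse(ref, test),
       psnr = img_psnr(ref, test),
       ssim = img_ssim(ref, test, c1 = c1, c2 = c2),
       fsim = img_fsim(ref, test, t1 = t1, t2 = t2),
       constants_used = list(c1 = c1, c2 = c2, t1 = t1, t2 = t2))
}
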