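#' Read an image as 8-bit grayscale
#'
#' Reads PNG, TIFF, PGM or JPEG files into an integer matrix of gray levels
#' in `0:255`. Color inputs are converted with the standard luma transform
#' \eqn{0.2989 R + 0.5870 G + 0.1140 B}. An optional bilinear resize (e.g. to
#' the conventional 512 x 512 benchmark size) is applied after conversion.
#'
#' @param path Path to the image file.
#' @param size Optional `c(height, width)` (a single number is used for
#'   both) to resize to, bilinear interpolation.
#' @return An integer matrix (rows = image rows) with values in `0:255`.
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_gray_image(matrix(c(0L, 0L, 255L, 255L), 2), f)
#' read_gray_image(f)
#' @export
read_gray_image <- function(path, size = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path) / 255,
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L)
      img <- 0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
    else
      img <- img[, , 1L]
  }
  if (!is.null(size)) {
    size <- rep_len(as.integer(size), 2L)
    img <- EBImage::resize(img, w = size[1L], h = size[2L],
                           filter = "bilinear")
  }
  out <- round(pmin(pmax(img, 0), 1) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit grayscale image
#'
#' Writes PNG (via the png package) or PGM. PGM output is the plain-text P2
#' variant by default, handy for small human-readable fixtures; `ascii =
#' FALSE` writes binary P5.
#'
#' @param image Integer matrix in `0:255`.
#' @param path Output path; format chosen by extension (`.png` or `.pgm`).
#' @param ascii For PGM: write plain text (P2, default) or binary (P5).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, ascii = TRUE) {
  image <- check_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, target = path)
  } else if (ext == "pgm") {
    write_pgm(image, path, ascii = ascii)
  } else {
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

## Minimal PGM (P2 plain / P5 binary) reader. Returns an integer matrix in
## [0, maxval] rescaled to 0:255 only when maxval == 255 is violated.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("'%s' is not a PGM file", path), call. = FALSE)

  ## read header tokens (width, height, maxval), skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {                      # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch %in% c("\n", "\r")) break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  if (maxval > 255L) stop("only 8-bit PGM images are supported", call. = FALSE)
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])[seq_len(n)]
  }
  if (length(vals) < n || anyNA(vals))
    stop("truncated PGM pixel data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path, ascii = TRUE) {
  h <- nrow(image); w <- ncol(image)
  if (ascii) {
    con <- file(path, "wb")               # binary mode: stable newlines
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con, sep = "\n")
    rows <- apply(image, 1L, paste, collapse = " ")
    writeLines(rows, con, sep = "\n")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.integer(t(image))), con)
  }
  invisible(path)
}
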