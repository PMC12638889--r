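## Internal helpers shared across the package.

## Clamp every coordinate into [lb, ub] (nearest-bound boundary handling).
clamp_bounds <- function(x, lb, ub) {
  pmin(pmax(x, lb), ub)
}

## Evaluate a block with a temporary RNG seed, restoring the caller's RNG
## state afterwards so seeded generators do not clobber the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Validate an 8-bit-style grayscale image matrix: integer-valued entries in
## [0, levels - 1]. Returns the matrix with storage mode integer.
check_gray_image <- function(image, levels = 256L, arg = "image") {
  if (!is.matrix(image) || length(image) == 0L)
    stop(sprintf("'%s' must be a non-empty matrix", arg), call. = FALSE)
  if (anyNA(image)) stop(sprintf("'%s' contains missing values", arg), call. = FALSE)
  if (any(image != round(image)))
    stop(sprintf("'%s' must contain integer gray levels", arg), call. = FALSE)
  if (min(image) < 0 || max(image) > levels - 1L)
    stop(sprintf("'%s' has intensities outside [0, %d]", arg, levels - 1L),
         call. = FALSE)
  storage.mode(image) <- "integer"
  image
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 1
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
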