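#' Gaussian kernels for temporal noise filtering
#'
#' `gauss1d_kernel()` samples `exp(-(j - c)^2 / (2 * sigma^2))` at integer
#' offsets around the center of an odd-length window and normalizes to unit
#' sum; `gauss2d_kernel()` is the separable outer product of two such 1-D
#' kernels. Unit sum makes the filters mass-preserving: a constant series is
#' mapped to itself.
#'
#' @param length Odd kernel length (`>= 1`).
#' @param sigma Standard deviation in samples, `> 0`.
#' @return An object of class `sofi_kernel`: list with `shape`, `sigma` and
#'   `weights` (matrix of the given shape, non-negative, summing to 1).
#' @export
gauss1d_kernel <- function(length, sigma) {
  l <- check_odd(length, "length")
  check_sigma(sigma)
  c0 <- (l - 1L) / 2
  w <- exp(-((seq_len(l) - 1L - c0)^2) / (2 * sigma^2))
  structure(list(shape = c(1L, l), sigma = sigma,
                 weights = matrix(w / sum(w), nrow = 1L)),
            class = "sofi_kernel")
}

#' @param shape Length-2 vector of odd dimensions `(rows, cols)`.
#' @rdname gauss1d_kernel
#' @export
gauss2d_kernel <- function(shape, sigma) {
  if (length(shape) != 2L) stop("'shape' must be c(rows, cols)")
  r <- check_odd(shape[1L], "shape[1]")
  c <- check_odd(shape[2L], "shape[2]")
  check_sigma(sigma)
  wr <- gauss1d_kernel(r, sigma)$weights
  wc <- gauss1d_kernel(c, sigma)$weights
  structure(list(shape = c(r, c), sigma = sigma,
                 weights = outer(drop(wr), drop(wc))),
            class = "sofi_kernel")
}

check_odd <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || x < 1 || x != round(x) || x %% 2 == 0)
    stop(sprintf("'%s' must be a single odd integer >= 1", what))
  as.integer(x)
}

check_sigma <- function(sigma) {
  if (length(sigma) != 1L || !is.numeric(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  invisible(sigma)
}

#' @export
print.sofi_kernel <- function(x, ...) {
  cat(sprintf("Gaussian kernel %d x %d, sigma = %g\n", x$shape[1L], x$shape[2L], x$sigma))
  invisible(x)
}

#' Pixel-wise temporal noise filtering across time blocks
#'
#' Convolves, for every pixel, its series of values across an ordered set of
#' per-block reconstruction images (e.g., the sixth-order moment image of
#' each of 20 consecutive acquisition blocks) with a 1-D unit-sum kernel.
#' Because the filter acts along the time axis only, spatial resolution is
#' untouched. Series ends are padded by reflection (mirrored without
#' repeating the edge sample), which avoids the edge attenuation a truncated
#' kernel would cause when the series is shorter than the kernel.
#'
#' @param series Ordered list of equally-shaped `H x W` matrices, one per
#'   time block; names (block identifiers) are preserved in the output.
#' @param kernel A 1-D [gauss1d_kernel()] (one dimension of `shape` is 1).
#' @return List of filtered images with the same length, shapes, names and
#'   order as `series`.
#' @export
noise_filter1d <- function(series, kernel) {
  if (!is.list(series) || length(series) < 1L)
    stop("'series' must be a non-empty list of images")
  if (!inherits(kernel, "sofi_kernel") || min(kernel$shape) != 1L)
    stop("'kernel' must be a 1-D sofi_kernel")
  dims <- dim(series[[1L]])
  for (im in series)
    if (!is.matrix(im) || !identical(dim(im), dims))
      stop("all images in 'series' must be matrices of one common shape")
  m <- length(series)
  w <- drop(kernel$weights)
  l <- length(w)
  if (l > 2L * m - 1L)
    stop(sprintf("kernel length (%d) exceeds 2 * blocks - 1 (%d)", l, 2L * m - 1L))
  if (m == 1L) return(series)
  h <- (l - 1L) %/% 2L
  x <- vapply(series, as.vector, numeric(prod(dims)))  # P x M
  out <- matrix(0, nrow(x), m)
  for (i in seq_len(m)) {
    for (o in seq.int(-h, h)) {
      j <- i + o
      if (j < 1L) j <- 2L - j else if (j > m) j <- 2L * m - j
      out[, i] <- out[, i] + w[o + h + 1L] * x[, j]
    }
  }
  res <- lapply(seq_len(m), function(i) matrix(out[, i], dims[1L], dims[2L]))
  names(res) <- names(series)
  res
}
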