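#' Forward DFT matrix
#'
#' Unnormalized forward discrete-Fourier-transform matrix
#' `W[j, m] = exp(-2i * pi * j * m / n)` (0-based indices); the inverse
#' transform carries the `1/n` factor.
#'
#' @param n Size, `n >= 1`.
#' @return `n x n` complex matrix.
#' @export
dft_matrix <- function(n) {
  n <- check_size(n, "n")
  jm <- outer(0:(n - 1L), 0:(n - 1L))
  exp(-2i * pi * jm / n)
}

check_size <- function(n, what) {
  if (length(n) != 1L || !is.numeric(n) || n < 1 || n != round(n))
    stop(sprintf("'%s' must be a single integer >= 1", what))
  as.integer(n)
}

#' Interpolating inverse DFT matrix
#'
#' Evaluates the inverse DFT at the fractional sample coordinates
#' `x_p = p / factor`, `p = 0 .. factor * (n - 1)`, using centered frequency
#' indices `k = -floor(n/2) .. ceiling(n/2) - 1`. For even `n` the Nyquist
#' coefficient is split evenly between `+n/2` and `-n/2` (the term becomes
#' `cos(pi * x)`), which is the standard real trigonometric interpolant:
#' real inputs yield real outputs. No frequency-domain zero padding is used;
#' the extra positions are carried directly by the matrix rows.
#'
#' @param n Input length.
#' @param factor Integer interpolation fold, `>= 1`.
#' @return `(factor * (n - 1) + 1) x n` complex matrix; applied to a forward
#'   DFT spectrum it returns the trigonometric interpolant at the refined
#'   positions (the `1/n` inverse normalization is included).
#' @export
idft_interp_matrix <- function(n, factor) {
  n <- check_size(n, "n")
  factor <- check_size(factor, "factor")
  x <- (0:(factor * (n - 1L))) / factor
  j <- 0:(n - 1L)
  k <- ifelse(j < ceiling(n / 2), j, j - n)
  m <- exp(2i * pi * outer(x, k) / n) / n
  if (n %% 2L == 0L) {
    # bin n/2 carries the Nyquist term: split across +-n/2 -> cos(pi x)
    m[, n / 2L + 1L] <- cos(pi * x) / n
  }
  m
}

# Real interpolation operator along one axis: maps a length-n sample vector
# to factor*(n-1)+1 refined samples. Real by construction of the Nyquist
# split; the residual imaginary part is floating-point noise.
interp_operator <- function(n, factor) {
  Re(idft_interp_matrix(n, factor) %*% dft_matrix(n))
}

#' Fourier interpolation of an image
#'
#' Trigonometric (band-limited) interpolation of an `H x W` image onto a
#' refined grid of `factor * (H - 1) + 1` by `factor * (W - 1) + 1` pixels
#' spanning the original extent, applied separably along the two axes.
#' Original grid points are reproduced exactly and a constant image is a
#' fixed point at any factor.
#'
#' @param image `H x W` numeric matrix, `H, W >= 2` when `factor > 1`.
#' @param factor Integer interpolation fold `>= 1`; `factor = 1` returns the
#'   input unchanged.
#' @return Refined real matrix.
#' @export
fourier_interp_image <- function(image, factor) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  factor <- check_size(factor, "factor")
  if (factor == 1L) return(image)
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("'image' must be at least 2 x 2 for interpolation factors > 1")
  bh <- interp_operator(nrow(image), factor)
  bw <- interp_operator(ncol(image), factor)
  bh %*% image %*% t(bw)
}

#' Fourier interpolation of a movie
#'
#' Frame-wise [fourier_interp_image()] for one or more interpolation folds.
#' With `save = TRUE` each refined stack is written as a 32-bit float TIFF
#' named `<stem>_InterpNum<k>.tiff`.
#'
#' @inheritParams average_image
#' @param factors Non-empty vector of integer folds.
#' @param save Write each interpolated stack to disk.
#' @param stem Output file stem (without extension); required when saving.
#' @param dir Output directory for saved stacks.
#' @return Named list (one element per factor, names are the factors) of
#'   refined `T' x H' x W'` movies.
#' @export
fourier_interp_movie <- function(movie, factors, frame_range = NULL,
                                 save = FALSE, stem = NULL, dir = ".") {
  movie <- as_movie(movie)
  if (length(factors) < 1L) stop("'factors' must contain at least one interpolation fold")
  d <- dim(movie)
  sel <- resolve_frames(frame_range, d[1L])
  out <- vector("list", length(factors))
  names(out) <- as.character(factors)
  for (fi in seq_along(factors)) {
    f <- check_size(factors[fi], "factor")
    if (f == 1L) {
      res <- movie[sel, , , drop = FALSE]
    } else {
      bh <- interp_operator(d[2L], f)
      bw <- interp_operator(d[3L], f)
      res <- array(0, c(length(sel), nrow(bh), nrow(bw)))
      for (t in seq_along(sel))
        res[t, , ] <- bh %*% movie[sel[t], , ] %*% t(bw)
    }
    if (isTRUE(save)) {
      if (is.null(stem)) stop("'stem' is required when save = TRUE")
      write_movie(res, file.path(dir, sprintf("%s_InterpNum%d.tiff", stem, f)),
                  bits = 32L)
    }
    out[[fi]] <- res
  }
  out
}
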