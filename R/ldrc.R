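#' Local dynamic range compression
#'
#' High-order moment and cumulant images span an extreme dynamic range that
#' hides dim structure. `ldrc` rescales the input locally to the dynamic
#' range of a reference image that shows the same features with confined
#' intensities (typically the temporal average or the second-order image).
#' A window scans the image with a stride of 1 pixel, staying fully inside
#' the image; in each window the input values are linearly mapped so the
#' window minimum/maximum match the reference window's minimum/maximum, and
#' each pixel's final value is the average of its rescaled values over all
#' windows covering it.
#'
#' A window with constant input (no contrast to place within the reference
#' range) maps to the reference window minimum, the zero of the normalized
#' scale, so flat backgrounds stay at the reference floor.
#'
#' @param input_im `H x W` matrix to compress.
#' @param mask_im `H x W` reference image of the same shape.
#' @param window Window size `c(rows, cols)` (a single integer is used for
#'   both); must fit inside the image.
#' @return `H x W` compressed image.
#' @export
ldrc <- function(input_im, mask_im, window = c(20L, 20L)) {
  if (!is.matrix(input_im) || !is.numeric(input_im))
    stop("'input_im' must be a numeric matrix")
  if (!is.matrix(mask_im) || !identical(dim(mask_im), dim(input_im)))
    stop("'mask_im' must be a numeric matrix with the same shape as 'input_im'")
  if (length(window) == 1L) window <- c(window, window)
  wr <- as.integer(window[1L]); wc <- as.integer(window[2L])
  h <- nrow(input_im); w <- ncol(input_im)
  if (wr < 1L || wc < 1L || wr > h || wc > w)
    stop(sprintf("window %d x %d does not fit inside the %d x %d image", wr, wc, h, w))
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (r in seq_len(h - wr + 1L)) {
    ri <- r:(r + wr - 1L)
    for (c in seq_len(w - wc + 1L)) {
      ci <- c:(c + wc - 1L)
      win <- input_im[ri, ci]
      ref <- mask_im[ri, ci]
      mn <- min(win); mx <- max(win)
      rmn <- min(ref); rmx <- max(ref)
      scaled <- if (mx > mn) (win - mn) / (mx - mn) * (rmx - rmn) + rmn
                else matrix(rmn, wr, wc)
      acc[ri, ci] <- acc[ri, ci] + scaled
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  acc / cnt
}
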