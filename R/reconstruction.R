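#' Temporal average image
#'
#' Per-pixel arithmetic mean of the selected frames. The average image is both
#' the first step of every moment reconstruction (fluctuations are deviations
#' from it) and a common low-dynamic-range reference for [ldrc()].
#'
#' @param movie `T x H x W` array (see [as_movie()]).
#' @param frame_range Optional half-open 0-based frame interval `c(start, end)`;
#'   `NULL` selects all frames.
#' @return `H x W` matrix.
#' @export
average_image <- function(movie, frame_range = NULL) {
  movie <- as_movie(movie)
  d <- dim(movie)
  sel <- resolve_frames(frame_range, d[1L])
  x <- flatten_movie(movie)[sel, , drop = FALSE]
  unflatten_image(colMeans(x), d[2:3])
}

#' Centered temporal moment image
#'
#' Per-pixel centered temporal moment `<(F - <F>)^n>` over the selected
#' frames. The first moment is identically zero by construction. Estimators
#' are population-style time averages (divide by the number of frames, no
#' small-sample correction), matching the definition of the correlation
#' functions the cumulants are built from.
#'
#' @inheritParams average_image
#' @param order Moment order `n >= 1`.
#' @return `H x W` matrix.
#' @export
moment_image <- function(movie, order, frame_range = NULL) {
  movie <- as_movie(movie)
  if (length(order) != 1L || !is.numeric(order) || order < 1 || order != round(order))
    stop("'order' must be a single integer >= 1")
  d <- dim(movie)
  sel <- resolve_frames(frame_range, d[1L])
  if (order >= 2 && length(sel) < 2L)
    stop(sprintf("at least 2 frames are required for a moment of order %d (got %d)",
                 order, length(sel)))
  if (order == 1) return(matrix(0, d[2L], d[3L]))
  x <- flatten_movie(movie)[sel, , drop = FALSE]
  xc <- x - rep(colMeans(x), each = nrow(x))
  unflatten_image(colMeans(xc^order), d[2:3])
}

#' Compute all centered moment images up to a given order
#'
#' Single two-pass sweep over the movie: the per-pixel temporal mean first,
#' then all powered deviations. Results equal per-order [moment_image()]
#' calls exactly.
#'
#' @inheritParams average_image
#' @param highest_order Highest moment order (>= 1).
#' @return An object of class `sofi_moments`: a list with `order_to_image`
#'   (list of `H x W` matrices for orders `1..highest_order`), `average`
#'   (the temporal mean image) and `highest_order`.
#' @export
calc_moments <- function(movie, highest_order, frame_range = NULL) {
  movie <- as_movie(movie)
  if (length(highest_order) != 1L || highest_order < 1 || highest_order != round(highest_order))
    stop("'highest_order' must be a single integer >= 1")
  highest_order <- as.integer(highest_order)
  d <- dim(movie)
  sel <- resolve_frames(frame_range, d[1L])
  if (highest_order >= 2 && length(sel) < 2L)
    stop("at least 2 frames are required for moments of order >= 2")
  x <- flatten_movie(movie)[sel, , drop = FALSE]
  mu <- colMeans(x)
  xc <- x - rep(mu, each = nrow(x))
  orders <- vector("list", highest_order)
  orders[[1L]] <- matrix(0, d[2L], d[3L])
  if (highest_order >= 2) {
    p <- xc
    for (n in 2:highest_order) {
      p <- p * xc
      orders[[n]] <- unflatten_image(colMeans(p), d[2:3])
    }
  }
  structure(list(order_to_image = orders,
                 average = unflatten_image(mu, d[2:3]),
                 highest_order = highest_order),
            class = "sofi_moments")
}

check_order_maps <- function(x, what) {
  n <- x$highest_order
  for (i in seq_len(n))
    if (i > length(x$order_to_image) || is.null(x$order_to_image[[i]]))
      stop(sprintf("%s is missing order %d (orders 1..%d are required)", what, i, n))
  invisible(x)
}

#' Cumulant images from moment images
#'
#' Pixel-wise moment-to-cumulant recursion, applied in ascending order:
#' `Cum_n = G_n - sum_{i=1}^{n-1} choose(n-1, i) * Cum_{n-i} * G_i`.
#' With centered moments (`G_1 = 0`) the second- and third-order cumulants
#' equal the corresponding moments; from the fourth order on the lower-order
#' mixed products are subtracted. The n-th order cumulant image carries the
#' `U^n` point-spread-function narrowing that gives SOFI its resolution gain,
#' at the price of signed "virtual brightness" values.
#'
#' @param moments A `sofi_moments` object with all orders `1..highest_order`.
#' @return An object of class `sofi_cumulants`: list with `order_to_image`
#'   and `highest_order`.
#' @export
cumulants_from_moments <- function(moments) {
  if (!inherits(moments, "sofi_moments"))
    stop("'moments' must be a sofi_moments object")
  check_order_maps(moments, "moment set")
  n <- moments$highest_order
  g <- moments$order_to_image
  k <- vector("list", n)
  k[[1L]] <- g[[1L]]
  if (n >= 2) for (ord in 2:n) {
    acc <- g[[ord]]
    for (i in seq_len(ord - 1L))
      acc <- acc - choose(ord - 1L, i) * k[[ord - i]] * g[[i]]
    k[[ord]] <- acc
  }
  structure(list(order_to_image = k, highest_order = n),
            class = "sofi_cumulants")
}

#' Moment images from cumulant images
#'
#' Inverts the moment-to-cumulant recursion in ascending order:
#' `G_n = Cum_n + sum_{i=1}^{n-1} choose(n-1, i) * Cum_{n-i} * G_i`.
#' The round trip through [cumulants_from_moments()] is the identity.
#'
#' @param cumulants A `sofi_cumulants` object with all orders present.
#' @return A `sofi_moments` object (the `average` slot is `NULL`, since the
#'   cumulants carry no information about the mean image).
#' @export
moments_from_cumulants <- function(cumulants) {
  if (!inherits(cumulants, "sofi_cumulants"))
    stop("'cumulants' must be a sofi_cumulants object")
  check_order_maps(cumulants, "cumulant set")
  n <- cumulants$highest_order
  k <- cumulants$order_to_image
  g <- vector("list", n)
  g[[1L]] <- k[[1L]]
  if (n >= 2) for (ord in 2:n) {
    acc <- k[[ord]]
    for (i in seq_len(ord - 1L))
      acc <- acc + choose(ord - 1L, i) * k[[ord - i]] * g[[i]]
    g[[ord]] <- acc
  }
  structure(list(order_to_image = g, average = NULL, highest_order = n),
            class = "sofi_moments")
}

#' Total signal per frame
#'
#' `I(t)`: the sum of all pixel values of frame `t`. Its smoothed, monotone
#' envelope estimates the photobleaching profile of an acquisition.
#'
#' @inheritParams average_image
#' @return Numeric vector of length `T`.
#' @export
total_signal <- function(movie) {
  movie <- as_movie(movie)
  rowSums(flatten_movie(movie))
}

#' Monotone smoothing of a total-signal curve
#'
#' Moving average with the given odd window (windows are shortened at the
#' series edges), followed by a running minimum so the output is monotone
#' non-increasing everywhere -- the estimated bleaching profile.
#'
#' @param signal Numeric series (typically [total_signal()]).
#' @param smooth_kernel Odd window length, `1 <= smooth_kernel <= length(signal)`.
#' @return Non-increasing numeric series of the same length.
#' @export
smooth_monotone <- function(signal, smooth_kernel) {
  if (!is.numeric(signal) || length(signal) < 1L)
    stop("'signal' must be a non-empty numeric vector")
  w <- as.integer(smooth_kernel)
  if (length(w) != 1L || w < 1L || w %% 2L == 0L)
    stop("'smooth_kernel' must be a single odd integer >= 1")
  tt <- length(signal)
  if (w > tt)
    stop(sprintf("'smooth_kernel' (%d) exceeds the series length (%d)", w, tt))
  h <- (w - 1L) %/% 2L
  i <- seq_len(tt)
  lo <- pmax(1L, i - h); hi <- pmin(tt, i + h)
  cs <- c(0, cumsum(signal))
  cummin((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Split frames into blocks of equal fractional signal decay
#'
#' Walks the monotone bleaching profile and closes a block at the first frame
#' where the signal falls below `(1 - fbc)` times the signal at the block
#' start, so every (full) block spans the same fractional decay `fbc`. The
#' trailing partial block is kept if it has at least 2 frames and merged into
#' the previous block otherwise.
#'
#' @param smoothed Monotone non-increasing series (see [smooth_monotone()]).
#' @param fbc Bleaching-correction factor, the fractional decay per block,
#'   in (0, 1).
#' @param total_signal Optional raw total-signal series, stored alongside.
#' @return An object of class `bleach_schedule`: list with `total_signal`,
#'   `smoothed`, `fbc` and `blocks`, a matrix with columns `start`, `end`
#'   holding 0-based half-open frame intervals covering `[0, T)`.
#' @export
bleach_blocks <- function(smoothed, fbc, total_signal = NULL) {
  if (!is.numeric(fbc) || length(fbc) != 1L || fbc <= 0 || fbc >= 1)
    stop("'fbc' must be a single number in (0, 1)")
  if (!is.numeric(smoothed) || length(smoothed) < 1L)
    stop("'smoothed' must be a non-empty numeric vector")
  tol <- 1e-9 * max(abs(smoothed), 1)
  if (any(diff(smoothed) > tol))
    stop("'smoothed' must be monotone non-increasing")
  tt <- length(smoothed)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= tt) {
    thr <- smoothed[i] * (1 - fbc)
    below <- which(smoothed[seq.int(i, tt)] < thr)
    j <- if (length(below)) i + below[1L] - 1L else tt + 1L
    starts <- c(starts, i); ends <- c(ends, j)
    i <- j
  }
  nb <- length(starts)
  # merge a trailing < 2 frame remainder into the previous block
  if (nb >= 2L && (ends[nb] - starts[nb]) < 2L) {
    ends[nb - 1L] <- ends[nb]
    starts <- starts[-nb]; ends <- ends[-nb]
  }
  blocks <- cbind(start = starts - 1L, end = ends - 1L)
  structure(list(total_signal = total_signal, smoothed = smoothed,
                 fbc = fbc, blocks = blocks),
            class = "bleach_schedule")
}

# Average per-order cumulant images over an explicit list of frame blocks
# (0-based half-open intervals). Each block is reconstructed independently
# (its own mean, moments and cumulants) and the per-order images are averaged
# without weighting.
cumulants_by_blocks <- function(movie, blocks, highest_order) {
  nb <- nrow(blocks)
  acc <- NULL
  for (b in seq_len(nb)) {
    fr <- c(blocks[b, 1L], blocks[b, 2L])
    if (fr[2L] - fr[1L] < 2L)
      stop(sprintf("bleaching block %d ([%d, %d)) has fewer than 2 frames",
                   b, fr[1L], fr[2L]))
    k <- cumulants_from_moments(calc_moments(movie, highest_order, frame_range = fr))
    if (is.null(acc)) {
      acc <- k$order_to_image
    } else {
      for (n in seq_len(highest_order))
        acc[[n]] <- acc[[n]] + k$order_to_image[[n]]
    }
  }
  for (n in seq_len(highest_order)) acc[[n]] <- acc[[n]] / nb
  structure(list(order_to_image = acc, highest_order = as.integer(highest_order)),
            class = "sofi_cumulants")
}

#' Bleaching-corrected cumulant reconstruction
#'
#' Photobleaching acts like a prolonged off state and corrupts the virtual
#' brightness of moment/cumulant images. The correction splits the movie into
#' blocks of equal fractional total-signal decay (`fbc`), reconstructs
#' cumulants independently within each block (where the signal is
#' approximately stationary), and averages the per-order images over blocks
#' without weighting.
#'
#' @inheritParams average_image
#' @param fbc Fractional signal decay per block, in (0, 1).
#' @param smooth_kernel Odd moving-average window for the bleaching profile.
#' @param highest_order Highest cumulant order.
#' @return A `sofi_cumulants` object with an additional `schedule` element
#'   (the [bleach_blocks()] result used for the split).
#' @export
correct_bleaching <- function(movie, fbc = 0.04, smooth_kernel = 251, highest_order = 4) {
  movie <- as_movie(movie)
  ts <- total_signal(movie)
  sm <- smooth_monotone(ts, smooth_kernel)
  sched <- bleach_blocks(sm, fbc, total_signal = ts)
  out <- cumulants_by_blocks(movie, sched$blocks, highest_order)
  out$schedule <- sched
  out
}

#' @export
print.sofi_moments <- function(x, ...) {
  d <- if (!is.null(x$order_to_image[[1L]])) dim(x$order_to_image[[1L]]) else c(NA, NA)
  cat(sprintf("SOFI moment set: orders 1..%d, %d x %d pixels%s\n",
              x$highest_order, d[1L], d[2L],
              if (is.null(x$average)) " (no average image)" else ""))
  invisible(x)
}

#' @export
print.sofi_cumulants <- function(x, ...) {
  d <- dim(x$order_to_image[[1L]])
  cat(sprintf("SOFI cumulant set: orders 1..%d, %d x %d pixels%s\n",
              x$highest_order, d[1L], d[2L],
              if (!is.null(x$schedule)) sprintf(", bleaching-corrected (%d blocks)",
                                                nrow(x$schedule$blocks)) else ""))
  invisible(x)
}

#' @export
print.bleach_schedule <- function(x, ...) {
  cat(sprintf("Bleaching schedule: %d block(s), fbc = %g, %d frames\n",
              nrow(x$blocks), x$fbc, length(x$smoothed)))
  invisible(x)
}
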