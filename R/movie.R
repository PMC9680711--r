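#' Validate a movie array
#'
#' A movie is a plain 3-D numeric array with frames along the first axis
#' (`T x H x W`), the raw input to every reconstruction. Values are arbitrary
#' camera units; they are typically non-negative but this is not enforced.
#' All values must be finite.
#'
#' @param movie A `T x H x W` numeric array.
#' @return The validated array, invisibly unchanged.
#' @export
as_movie <- function(movie) {
  if (!is.array(movie) || length(dim(movie)) != 3L)
    stop("'movie' must be a 3-D array (frames x rows x cols)")
  if (!is.numeric(movie))
    stop("'movie' must be numeric")
  if (any(!is.finite(movie)))
    stop("'movie' contains non-finite values")
  movie
}

#' @return Number of frames of a movie.
#' @rdname as_movie
#' @export
n_frames <- function(movie) dim(movie)[1L]

# Resolve a 0-based half-open frame interval [start, end) into 1-based frame
# indices. NULL selects all frames. The half-open 0-based convention mirrors
# the frames = [0, 50] idiom meaning "the first 50 frames".
resolve_frames <- function(frame_range, n_frames) {
  if (is.null(frame_range)) return(seq_len(n_frames))
  if (length(frame_range) != 2L || !is.numeric(frame_range))
    stop("'frame_range' must be NULL or a numeric vector c(start, end)")
  a <- as.integer(frame_range[1L]); b <- as.integer(frame_range[2L])
  if (a < 0L || b > n_frames || a >= b)
    stop(sprintf("empty or invalid frame range [%d, %d) for a movie of %d frames",
                 a, b, n_frames))
  seq.int(a + 1L, b)
}

# Flatten a T x H x W movie to a T x (H*W) matrix; column p corresponds to the
# pixel at (row, col) with p = row + (col - 1) * H (column-major image layout).
flatten_movie <- function(movie) {
  d <- dim(movie)
  dim(movie) <- c(d[1L], d[2L] * d[3L])
  movie
}

unflatten_image <- function(v, dims) matrix(v, nrow = dims[1L], ncol = dims[2L])
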