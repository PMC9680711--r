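#' Read a multi-page TIFF stack as a movie
#'
#' Any integer or float grayscale sample format is accepted; values are
#' promoted to double precision in camera units (integer samples are read
#' as-is, without rescaling to [0, 1]).
#'
#' @param path Path to a multi-page TIFF file.
#' @param frames Optional half-open 0-based frame interval `c(start, end)`.
#' @return `T x H x W` numeric array.
#' @export
read_movie <- function(path, frames = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  info <- movie_info(path)
  sel <- resolve_frames(frames, info$frames)
  pages <- read_pages(path, sel)
  out <- array(0, c(length(pages), info$height, info$width))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # drop extra channels
    out[i, , ] <- p
  }
  out
}

# Read selected pages in camera units: integer formats as raw counts
# (as.is), float formats verbatim (as.is is rejected for floats).
read_pages <- function(path, sel) {
  pages <- tryCatch(tiff::readTIFF(path, all = sel, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = sel))
  if (!is.list(pages)) list(pages) else pages
}

# File metadata without materializing pixel data.
movie_info <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  meta <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e)
                     stop(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e))))
  list(frames = nrow(meta), height = meta$length[1L], width = meta$width[1L],
       bits = meta$bits.per.sample[1L])
}

#' Write a movie or image stack as multi-page TIFF
#'
#' With `bits = 16`, values must be integers in `[0, 65535]` and are stored
#' as unsigned 16-bit samples (the usual camera format; the round trip
#' through [read_movie()] is bit-exact). With `bits = 32`, values are stored
#' as IEEE 32-bit floats with no range restriction, the format used for all
#' reconstruction outputs.
#'
#' @param movie `T x H x W` array (or `H x W` matrix for a single image).
#' @param path Output path.
#' @param bits 16 (unsigned integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits = 16L) {
  if (is.matrix(movie)) movie <- array(movie, c(1L, dim(movie)))
  as_movie(movie)
  if (bits == 16L) {
    if (any(movie < 0) || any(movie > 65535) || any(movie != round(movie)))
      stop("16-bit output requires integer values in [0, 65535]; use bits = 32 for float data")
    pages <- lapply(seq_len(dim(movie)[1L]), function(t) movie[t, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else if (bits == 32L) {
    write_float_tiff(movie, path)
  } else stop("'bits' must be 16 or 32")
  invisible(path)
}

#' @param image `H x W` matrix.
#' @rdname write_movie
#' @export
write_image <- function(image, path, bits = 32L) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  write_movie(array(image, c(1L, dim(image))), path, bits = bits)
}

# Minimal uncompressed little-endian 32-bit-float multi-page TIFF writer.
# (The sample format matters: reconstruction images are signed with a huge
# dynamic range, so they cannot pass through a unit-range integer writer.)
write_float_tiff <- function(movie, path) {
  tt <- dim(movie)[1L]; h <- dim(movie)[2L]; w <- dim(movie)[3L]
  ifd_bytes <- 2L + 10L * 12L + 4L
  data_bytes <- 4L * h * w
  ifd_off <- 8L + (seq_len(tt) - 1L) * (ifd_bytes + data_bytes)
  data_off <- ifd_off + ifd_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (t in seq_len(tt)) {
    writeBin(10L, con, size = 2, endian = "little")   # tag count
    tag(256, 4, 1, w)                                 # ImageWidth
    tag(257, 4, 1, h)                                 # ImageLength
    tag(258, 3, 1, 32)                                # BitsPerSample
    tag(259, 3, 1, 1)                                 # Compression: none
    tag(262, 3, 1, 1)                                 # Photometric: black is zero
    tag(273, 4, 1, data_off[t])                       # StripOffsets
    tag(277, 3, 1, 1)                                 # SamplesPerPixel
    tag(278, 4, 1, h)                                 # RowsPerStrip
    tag(279, 4, 1, data_bytes)                        # StripByteCounts
    tag(339, 3, 1, 3)                                 # SampleFormat: IEEE float
    writeBin(if (t < tt) ifd_off[t + 1L] else 0L, con, size = 4, endian = "little")
    writeBin(as.numeric(t(movie[t, , ])), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a simulation ground-truth sidecar
#'
#' JSON record of the simulator inputs and ground truth (positions,
#' brightness, on-time ratios, per-emitter empirical on fractions, bleach
#' times, seed) next to a simulated TIFF stack.
#'
#' @param sim A `sofi_sim` object from [simulate_movie()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  if (!inherits(sim, "sofi_sim")) stop("'sim' must be a sofi_sim object")
  gt <- list(
    n_emitters = nrow(sim$field$positions),
    positions = sim$field$positions,
    brightness = sim$field$brightness,
    on_ratio = sim$field$on_ratio,
    cycle_frames = sim$field$cycle_frames,
    bleach_lifetime = sim$field$bleach_lifetime,
    bleach_times = sim$bleach_times,
    empirical_on_fraction = colMeans(sim$traces),
    psf_sigma = sim$psf$sigma,
    frames = dim(sim$movie)[1L],
    shape = dim(sim$movie)[2:3],
    noise = unclass(sim$noise),
    seed = sim$seed)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
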