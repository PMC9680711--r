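#' Open a TIFF stack as a SOFI dataset
#'
#' The dataset object bundles the source file, cached intermediate results
#' (average image, moment/cumulant sets, filtered and compressed images) and
#' a provenance log of every processing step with its parameters. Only file
#' metadata is read at load time; frames are streamed from disk in chunks
#' when a computation needs them, so reconstructions of long movies never
#' hold the full stack in memory. Results are cached per parameter set:
#' re-running a step with identical parameters returns the cached image
#' without recomputation (visible in the provenance log), and changing the
#' frame range or interpolation settings computes a fresh entry.
#'
#' @param filepath Directory containing the file.
#' @param filename File name of a multi-page grayscale TIFF.
#' @return An environment of class `sofi_dataset` with fields `frames`,
#'   `height`, `width`, `ave`, `moments_set`, `cumulants_set`, `filtered`,
#'   `ldrc_result` and `provenance`.
#' @export
sofi_dataset <- function(filepath, filename) {
  path <- file.path(filepath, filename)
  info <- movie_info(path)
  d <- new.env(parent = emptyenv())
  d$filepath <- filepath
  d$filename <- filename
  d$stem <- sub("\\.[^.]*$", "", filename)
  d$path <- path
  d$frames <- info$frames
  d$height <- info$height
  d$width <- info$width
  d$bits <- info$bits
  d$ave <- NULL
  d$moments_set <- NULL
  d$cumulants_set <- NULL
  d$bc <- FALSE
  d$filtered <- NULL
  d$ldrc_result <- NULL
  d$cache <- list()
  d$provenance <- list()
  class(d) <- "sofi_dataset"
  if (info$frames < 2L)
    warning(sprintf("'%s' has a single frame; moments of order >= 2 are unavailable",
                    filename))
  d
}

#' @export
print.sofi_dataset <- function(x, ...) {
  cat(sprintf("SOFI dataset '%s': %d frames, %d x %d pixels, %d-bit\n",
              x$filename, x$frames, x$height, x$width, x$bits))
  if (length(x$provenance))
    cat(sprintf("  %d processing step(s) logged\n", length(x$provenance)))
  invisible(x)
}

log_step <- function(d, step, params, cached = FALSE) {
  d$provenance[[length(d$provenance) + 1L]] <-
    list(step = step, params = params, cached = cached, time = Sys.time())
  invisible(d)
}

cache_get <- function(d, key) if (key %in% names(d$cache)) d$cache[[key]] else NULL

cache_put <- function(d, key, value) { d$cache[[key]] <- value; invisible(d) }

frame_chunks <- function(sel, chunk) split(sel, ceiling(seq_along(sel) / chunk))

# Stream the per-pixel temporal mean from disk.
stream_mean <- function(d, sel, chunk) {
  acc <- 0
  for (idx in frame_chunks(sel, chunk)) {
    x <- read_pages(d$path, idx)
    if (!is.list(x)) x <- list(x)
    for (p in x) acc <- acc + p
  }
  acc / length(sel)
}

#' Average image of a dataset
#'
#' @param d A [sofi_dataset()].
#' @param frame_range Optional half-open 0-based frame interval.
#' @param chunk_frames Frames read per chunk while streaming.
#' @return `H x W` matrix (also cached as `d$ave`).
#' @export
ds_average_image <- function(d, frame_range = NULL, chunk_frames = 200L) {
  stopifnot(inherits(d, "sofi_dataset"))
  sel <- resolve_frames(frame_range, d$frames)
  key <- paste0("ave:", sel[1L], ":", sel[length(sel)])
  hit <- cache_get(d, key)
  if (!is.null(hit)) {
    log_step(d, "average_image", list(frame_range = frame_range), cached = TRUE)
    return(hit)
  }
  ave <- stream_mean(d, sel, chunk_frames)
  d$ave <- ave
  cache_put(d, key, ave)
  log_step(d, "average_image", list(frame_range = frame_range))
  ave
}

#' Moment images of a dataset
#'
#' Streaming two-pass computation: the temporal mean in a first pass over
#' the file, then all centered powered deviations in a second pass, chunk by
#' chunk. Equal to [calc_moments()] on the materialized movie.
#'
#' @inheritParams ds_average_image
#' @param highest_order Highest moment order.
#' @return A `sofi_moments` object (also cached as `d$moments_set`).
#' @export
ds_moments <- function(d, highest_order, frame_range = NULL, chunk_frames = 200L) {
  stopifnot(inherits(d, "sofi_dataset"))
  highest_order <- as.integer(highest_order)
  sel <- resolve_frames(frame_range, d$frames)
  if (highest_order >= 2 && length(sel) < 2L)
    stop("at least 2 frames are required for moments of order >= 2")
  key <- paste0("mom:", highest_order, ":", sel[1L], ":", sel[length(sel)])
  hit <- cache_get(d, key)
  if (!is.null(hit)) {
    log_step(d, "moments", list(highest_order = highest_order,
                                frame_range = frame_range), cached = TRUE)
    d$moments_set <- hit
    return(hit)
  }
  mu <- stream_mean(d, sel, chunk_frames)
  sums <- rep(list(0), highest_order)
  for (idx in frame_chunks(sel, chunk_frames)) {
    x <- read_pages(d$path, idx)
    if (!is.list(x)) x <- list(x)
    for (p in x) {
      dev <- p - mu
      pw <- dev
      for (n in seq_len(highest_order)[-1L]) {
        pw <- pw * dev
        sums[[n]] <- sums[[n]] + pw
      }
    }
  }
  orders <- vector("list", highest_order)
  orders[[1L]] <- matrix(0, d$height, d$width)
  for (n in seq_len(highest_order)[-1L]) orders[[n]] <- sums[[n]] / length(sel)
  res <- structure(list(order_to_image = orders, average = mu,
                        highest_order = highest_order),
                   class = "sofi_moments")
  d$moments_set <- res
  cache_put(d, key, res)
  log_step(d, "moments", list(highest_order = highest_order, frame_range = frame_range))
  res
}

#' Single moment image of a dataset
#'
#' @inheritParams ds_moments
#' @param order Moment order.
#' @return `H x W` matrix.
#' @export
ds_moment_image <- function(d, order, frame_range = NULL, chunk_frames = 200L) {
  ds_moments(d, order, frame_range, chunk_frames)$order_to_image[[order]]
}

#' Cumulant images of a dataset
#'
#' Moment-to-cumulant recursion on the dataset's moment set, optionally with
#' bleaching correction (block splitting at equal fractional total-signal
#' decay; see [correct_bleaching()]). With correction, blocks are streamed
#' from disk one at a time.
#'
#' @inheritParams ds_moments
#' @param bleach_correction Split into bleaching blocks and average.
#' @param fbc Fractional decay per block.
#' @param smooth_kernel Odd smoothing window for the bleaching profile.
#' @return A `sofi_cumulants` object (also cached as `d$cumulants_set`).
#' @export
ds_cumulants <- function(d, highest_order, frame_range = NULL,
                         bleach_correction = FALSE, fbc = 0.04,
                         smooth_kernel = 251, chunk_frames = 200L) {
  stopifnot(inherits(d, "sofi_dataset"))
  highest_order <- as.integer(highest_order)
  sel <- resolve_frames(frame_range, d$frames)
  key <- paste0("cum:", highest_order, ":", sel[1L], ":", sel[length(sel)], ":",
                bleach_correction, ":", fbc, ":", smooth_kernel)
  hit <- cache_get(d, key)
  if (!is.null(hit)) {
    log_step(d, "cumulants", list(highest_order = highest_order, bc = bleach_correction),
             cached = TRUE)
    d$cumulants_set <- hit
    return(hit)
  }
  if (!bleach_correction) {
    res <- cumulants_from_moments(ds_moments(d, highest_order, frame_range, chunk_frames))
  } else {
    ts <- numeric(0)
    for (idx in frame_chunks(sel, chunk_frames)) {
      x <- read_pages(d$path, idx)
      if (!is.list(x)) x <- list(x)
      ts <- c(ts, vapply(x, sum, numeric(1)))
    }
    sched <- bleach_blocks(smooth_monotone(ts, smooth_kernel), fbc, total_signal = ts)
    off <- sel[1L] - 1L   # schedule is relative to the selected range
    acc <- NULL
    for (b in seq_len(nrow(sched$blocks))) {
      fr <- sched$blocks[b, ] + off
      if (fr[2L] - fr[1L] < 2L)
        stop(sprintf("bleaching block %d has fewer than 2 frames", b))
      mv <- read_movie(d$path, frames = fr)
      k <- cumulants_from_moments(calc_moments(mv, highest_order))
      acc <- if (is.null(acc)) k$order_to_image
             else Map(`+`, acc, k$order_to_image)
    }
    acc <- lapply(acc, function(a) a / nrow(sched$blocks))
    res <- structure(list(order_to_image = acc, highest_order = highest_order,
                          schedule = sched),
                     class = "sofi_cumulants")
    d$bc <- TRUE
  }
  d$cumulants_set <- res
  cache_put(d, key, res)
  log_step(d, "cumulants", list(highest_order = highest_order, bc = bleach_correction,
                                fbc = fbc, smooth_kernel = smooth_kernel))
  res
}

#' Fourier-interpolate a dataset's frames
#'
#' @inheritParams ds_average_image
#' @param factors Vector of integer interpolation folds.
#' @param save Write one `<stem>_InterpNum<k>.tiff` float stack per factor.
#' @return Named list of refined movies (one per factor).
#' @export
ds_finterp <- function(d, factors, frame_range = NULL, save = FALSE) {
  stopifnot(inherits(d, "sofi_dataset"))
  mv <- read_movie(d$path, frames = frame_range)
  out <- fourier_interp_movie(mv, factors, save = save, stem = d$stem,
                              dir = d$filepath)
  log_step(d, "finterp", list(factors = factors, frame_range = frame_range,
                              save = save))
  out
}

#' Save an intermediate result of a dataset
#'
#' Writes a cached intermediate as a 32-bit float TIFF whose name carries a
#' provenance suffix: `_m<n>` for moment images, `_k<n>` for cumulant images
#' (`_k<n>_bc` when bleaching-corrected), `_filtered` for the temporally
#' filtered image and `_ldrc` for the compressed image.
#'
#' @param d A [sofi_dataset()].
#' @param which One of `"average"`, `"m<n>"` (e.g. `"m6"`), `"k<n>"`,
#'   `"filtered"`, `"ldrc"`.
#' @param dir Output directory (defaults to the dataset's directory).
#' @return The written path, invisibly.
#' @export
save_intermediate <- function(d, which, dir = NULL) {
  stopifnot(inherits(d, "sofi_dataset"))
  if (is.null(dir)) dir <- d$filepath
  avail <- character(0)
  if (!is.null(d$ave)) avail <- c(avail, "average")
  if (!is.null(d$moments_set))
    avail <- c(avail, paste0("m", seq_len(d$moments_set$highest_order)))
  if (!is.null(d$cumulants_set))
    avail <- c(avail, paste0("k", seq_len(d$cumulants_set$highest_order)))
  if (!is.null(d$filtered)) avail <- c(avail, "filtered")
  if (!is.null(d$ldrc_result)) avail <- c(avail, "ldrc")
  if (!(which %in% avail))
    stop(sprintf("no computed result named '%s'; available: %s", which,
                 if (length(avail)) paste(avail, collapse = ", ") else "(none)"))
  im <- if (which == "average") d$ave
        else if (which == "filtered") d$filtered
        else if (which == "ldrc") d$ldrc_result
        else {
          n <- as.integer(sub("^[mk]", "", which))
          if (startsWith(which, "m")) d$moments_set$order_to_image[[n]]
          else d$cumulants_set$order_to_image[[n]]
        }
  suffix <- if (which == "average") "_mean"
            else if (startsWith(which, "k") && d$bc) paste0("_", which, "_bc")
            else paste0("_", which)
  path <- file.path(dir, paste0(d$stem, suffix, ".tiff"))
  write_image(im, path, bits = 32L)
  log_step(d, "save_intermediate", list(which = which, path = path))
  invisible(path)
}

#' SOFI 2.0 processing chain over consecutive time blocks
#'
#' The live-cell workflow: each dataset is one time block of a long
#' acquisition. Per block, a high-order moment image is computed (optionally
#' on Fourier-interpolated frames); the per-block images are then noise
#' filtered pixel-wise along the block axis, passed through an optional
#' deconvolution hook, and compressed with [ldrc()] against a per-block
#' reference image. Every intermediate can be written to disk.
#'
#' @param datasets List of [sofi_dataset()] objects with consistent shapes,
#'   ordered by acquisition time.
#' @param order Moment order for the per-block reconstruction.
#' @param kernel 1-D temporal filter kernel (default length 21, sigma 2).
#' @param window `ldrc` window size.
#' @param reference Reference for `ldrc`: `"mean"` (per-block average image)
#'   or `"m2"` (per-block second-order moment image).
#' @param interp_factor Fourier-interpolation fold applied to the frames
#'   before reconstruction (1 = none).
#' @param frame_range Optional frame interval within each block.
#' @param deconv Optional function `image -> image` applied between
#'   filtering and `ldrc` (extension hook for deconvolution; default none).
#' @param save Write per-block `_filtered` and `_ldrc` images.
#' @param dir Output directory when saving (defaults to each block's own).
#' @return List with `moments`, `reference`, `filtered` and `ldrc`, each a
#'   named list with one image per block.
#' @export
run_sofi2 <- function(datasets, order = 6, kernel = gauss1d_kernel(21, 2),
                      window = c(20L, 20L), reference = c("mean", "m2"),
                      interp_factor = 1, frame_range = NULL, deconv = NULL,
                      save = FALSE, dir = NULL) {
  if (!is.list(datasets) || length(datasets) < 1L)
    stop("'datasets' must be a non-empty list of sofi_dataset objects")
  reference <- match.arg(reference)
  shapes <- vapply(datasets, function(d) c(d$height, d$width), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("all blocks must share one image shape")
  nb <- length(datasets)
  m_im <- vector("list", nb); ref_im <- vector("list", nb)
  nm <- vapply(datasets, function(d) d$filename, character(1))
  names(m_im) <- nm; names(ref_im) <- nm
  for (i in seq_len(nb)) {
    d <- datasets[[i]]
    if (interp_factor > 1) {
      mv <- fourier_interp_movie(read_movie(d$path, frames = frame_range),
                                 interp_factor)[[1L]]
      m_im[[i]] <- moment_image(mv, order)
      ref_im[[i]] <- if (reference == "mean") average_image(mv)
                     else moment_image(mv, 2)
    } else {
      ms <- ds_moments(d, max(order, if (reference == "m2") 2L else 1L),
                       frame_range = frame_range)
      m_im[[i]] <- ms$order_to_image[[order]]
      ref_im[[i]] <- if (reference == "mean") ms$average else ms$order_to_image[[2L]]
    }
  }
  filtered <- noise_filter1d(m_im, kernel)
  if (!is.null(deconv)) filtered <- lapply(filtered, deconv)
  compressed <- vector("list", nb); names(compressed) <- nm
  for (i in seq_len(nb)) {
    compressed[[i]] <- ldrc(filtered[[i]], ref_im[[i]], window)
    d <- datasets[[i]]
    d$filtered <- filtered[[i]]
    d$ldrc_result <- compressed[[i]]
    log_step(d, "sofi2", list(order = order, interp_factor = interp_factor,
                              reference = reference, window = window))
    if (isTRUE(save)) {
      save_intermediate(d, "filtered", dir = dir %||% d$filepath)
      save_intermediate(d, "ldrc", dir = dir %||% d$filepath)
    }
  }
  list(moments = m_im, reference = ref_im, filtered = filtered, ldrc = compressed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) file of named parameters
#' mirroring the command-line flags; command-line values override the file.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: '%s'", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
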