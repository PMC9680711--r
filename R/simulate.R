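#' Emitter field description
#'
#' Ground truth for the blinking-emitter simulator: emitter positions,
#' on-state brightnesses, on-time ratios and the dwell-time scale of the
#' two-state (on/off) switching process, plus an optional photobleaching
#' lifetime.
#'
#' Positions are in pixel units with `(1, 1)` at the center of the top-left
#' pixel; sub-pixel coordinates are allowed. Dwell means default to
#' `mean_on = on_ratio * cycle_frames` and
#' `mean_off = (1 - on_ratio) * cycle_frames`, so `on_ratio` is exactly the
#' stationary on fraction. Per-frame switching probabilities are clipped to
#' valid probabilities while preserving their ratio, so the stationary
#' marginal equals `on_ratio` for any ratio in (0, 1); for extreme ratios
#' the dwell correlation simply saturates near one frame.
#'
#' @param positions `n x 2` matrix of (row, col) coordinates.
#' @param brightness On-state brightness per emitter (photons/frame),
#'   recycled to the number of emitters.
#' @param on_ratio On-time ratio per emitter, each in (0, 1]; recycled.
#' @param cycle_frames Mean blink cycle length `mean_on + mean_off` in
#'   frames (default 20).
#' @param bleach_lifetime Expected number of frames until permanent
#'   photobleaching (`NULL` or `Inf` disables bleaching).
#' @return An object of class `emitter_field`.
#' @export
emitter_field <- function(positions, brightness = 100, on_ratio = 0.5,
                          cycle_frames = 20, bleach_lifetime = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("'positions' must be an n x 2 matrix (row, col)")
  n <- nrow(positions)
  brightness <- rep_len(brightness, n)
  on_ratio <- rep_len(on_ratio, n)
  if (any(brightness <= 0)) stop("'brightness' must be positive")
  if (any(on_ratio <= 0 | on_ratio > 1)) stop("'on_ratio' must be in (0, 1]")
  if (cycle_frames <= 0) stop("'cycle_frames' must be positive")
  if (!is.null(bleach_lifetime) && (!is.numeric(bleach_lifetime) || bleach_lifetime <= 0))
    stop("'bleach_lifetime' must be positive (or NULL)")
  structure(list(positions = positions, brightness = brightness,
                 on_ratio = on_ratio, cycle_frames = cycle_frames,
                 mean_on = on_ratio * cycle_frames,
                 mean_off = (1 - on_ratio) * cycle_frames,
                 bleach_lifetime = bleach_lifetime),
            class = "emitter_field")
}

#' @export
print.emitter_field <- function(x, ...) {
  cat(sprintf("Emitter field: %d emitter(s), rho in [%g, %g], cycle %g frames%s\n",
              nrow(x$positions), min(x$on_ratio), max(x$on_ratio), x$cycle_frames,
              if (is.null(x$bleach_lifetime)) "" else
                sprintf(", bleach lifetime %g frames", x$bleach_lifetime)))
  invisible(x)
}

#' Gaussian point-spread-function model
#'
#' Isotropic Gaussian PSF evaluated analytically at pixel centers,
#' `U(d) = exp(-|d|^2 / (2 * sigma^2))`, normalized to peak amplitude 1 (the
#' emitter brightness carries the scale) and truncated outside the support
#' radius.
#'
#' @param sigma PSF width in pixels, `> 0`.
#' @param support_radius Truncation radius in pixels (default `4 * sigma`).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(sigma, support_radius = ceiling(4 * sigma)) {
  check_sigma(sigma)
  structure(list(sigma = sigma, support_radius = support_radius),
            class = "psf_model")
}

#' Camera noise model
#'
#' Optional shot noise (Poisson draw on the expected photon counts), Gaussian
#' read noise and a constant camera baseline offset. The model is invoked by
#' [simulate_movie()] under its seed, so identical inputs give bit-identical
#' movies.
#'
#' @param poisson Apply Poisson shot noise to the expected counts.
#' @param read_sigma Gaussian read-noise standard deviation (counts), `>= 0`.
#' @param baseline Constant camera offset (counts).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(poisson = FALSE, read_sigma = 0, baseline = 0) {
  if (read_sigma < 0) stop("'read_sigma' must be >= 0")
  structure(list(poisson = isTRUE(poisson), read_sigma = read_sigma,
                 baseline = baseline),
            class = "noise_model")
}

# Per-frame switching probabilities for one emitter. a = P(on -> off),
# b = P(off -> on); both are jointly rescaled into [0, 1] preserving a/b so
# the stationary on fraction b / (a + b) equals rho exactly.
switch_probs <- function(mean_on, mean_off) {
  if (mean_off <= 0) return(c(a = 0, b = 1))   # always on
  a <- 1 / mean_on
  b <- 1 / mean_off
  s <- min(1, 1 / max(a, b))
  c(a = a * s, b = b * s)
}

# Simulate one emitter's 0/1 telegraph trace of the given length via
# alternating geometric dwell times (the dwell law of the per-frame chain),
# started from the stationary state. Geometric dwells are memoryless, so a
# stationary start needs no residual-time correction.
telegraph_trace <- function(frames, rho, mean_on, mean_off) {
  if (rho >= 1 || mean_off <= 0) return(rep(1, frames))
  p <- switch_probs(mean_on, mean_off)
  state <- stats::runif(1) < rho
  states <- integer(0); dwells <- integer(0)
  total <- 0L
  cyc <- 1 / p[["a"]] + 1 / p[["b"]]
  while (total < frames) {
    k <- max(8L, ceiling((frames - total) / cyc) + 4L)
    d_on <- 1L + stats::rgeom(k, p[["a"]])
    d_off <- 1L + stats::rgeom(k, p[["b"]])
    dw <- if (state) rbind(d_on, d_off) else rbind(d_off, d_on)
    st <- if (state) c(1L, 0L) else c(0L, 1L)
    states <- c(states, rep(st, k))
    dwells <- c(dwells, as.integer(dw))
    total <- total + sum(dw)
  }
  rep(states, dwells)[seq_len(frames)]
}

#' Blinking traces without photobleaching
#'
#' Draws the two-state (telegraph) on/off trace of every emitter in the
#' field: geometric dwell times with the field's per-emitter means, started
#' from the stationary distribution.
#'
#' @param field An [emitter_field()].
#' @param frames Number of frames.
#' @param seed Optional RNG seed for reproducibility.
#' @return `frames x n_emitters` 0/1 matrix.
#' @export
blink_traces <- function(field, frames, seed = NULL) {
  if (!inherits(field, "emitter_field")) stop("'field' must be an emitter_field")
  frames <- check_size(frames, "frames")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(field$positions)
  tr <- matrix(0, frames, n)
  for (k in seq_len(n))
    tr[, k] <- telegraph_trace(frames, field$on_ratio[k],
                               field$mean_on[k], field$mean_off[k])
  tr
}

#' Blinking traces with photobleaching
#'
#' Photobleaching is modeled as a switch to a permanent off state: each
#' emitter's telegraph trace is truncated to zero from its exponentially
#' distributed bleach time on. The expected total signal therefore decays
#' as `exp(-t / bleach_lifetime)`.
#'
#' @inheritParams blink_traces
#' @return List with `traces` (`frames x n` 0/1 matrix) and `bleach_times`
#'   (per-emitter bleach time in frames; an emitter is dark from the first
#'   0-based frame index `>= bleach_time`).
#' @export
bleach_traces <- function(field, frames, seed = NULL) {
  if (!inherits(field, "emitter_field")) stop("'field' must be an emitter_field")
  if (is.null(field$bleach_lifetime))
    stop("'field' has no bleach_lifetime; set one in emitter_field()")
  if (!is.null(seed)) set.seed(seed)
  tr <- blink_traces(field, frames)
  bt <- if (is.finite(field$bleach_lifetime))
    stats::rexp(ncol(tr), rate = 1 / field$bleach_lifetime)
  else rep(Inf, ncol(tr))
  t0 <- seq_len(nrow(tr)) - 1L   # 0-based frame times
  for (k in seq_len(ncol(tr)))
    tr[t0 >= bt[k], k] <- 0
  list(traces = tr, bleach_times = bt)
}

# Render each emitter's brightness-scaled PSF footprint on the pixel grid.
# Returns an n_emitters x (H*W) matrix in column-major pixel order.
render_emitters <- function(field, psf, shape) {
  h <- shape[1L]; w <- shape[2L]
  n <- nrow(field$positions)
  e <- matrix(0, n, h * w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_len(n)) {
    dr <- rr - field$positions[k, 1L]
    dc <- cc - field$positions[k, 2L]
    u <- exp(-(dr^2 + dc^2) / (2 * psf$sigma^2))
    u[abs(dr) > psf$support_radius | abs(dc) > psf$support_radius] <- 0
    e[k, ] <- field$brightness[k] * as.vector(u)
  }
  e
}

#' Simulate a blinking-emitter movie
#'
#' Renders the multi-emitter signal model: each frame is
#' `sum_k eps_k * b_k(t) * U(r - r_k)` with `b_k(t)` the emitter's two-state
#' blinking trace (with optional photobleaching when the field carries a
#' bleach lifetime), `eps_k` its on-state brightness and `U` a Gaussian PSF,
#' followed by optional camera noise. The exact blink traces are returned as
#' ground truth.
#'
#' @param field An [emitter_field()] (all emitters inside the field of view).
#' @param psf A [psf_model()].
#' @param frames Number of frames, `>= 1`.
#' @param shape Image shape `c(H, W)`.
#' @param noise A [noise_model()].
#' @param seed Optional RNG seed; identical inputs and seed give a
#'   bit-identical movie.
#' @param traces Optional pre-drawn `frames x n` 0/1 trace matrix overriding
#'   the stochastic blinking (useful for controlled experiments).
#' @return List of class `sofi_sim` with `movie` (`frames x H x W` array),
#'   `traces`, `bleach_times` (or `NULL`), and the `field`, `psf`, `noise`,
#'   `seed` used.
#' @export
simulate_movie <- function(field, psf, frames, shape, noise = noise_model(),
                           seed = NULL, traces = NULL) {
  if (!inherits(field, "emitter_field")) stop("'field' must be an emitter_field")
  if (!inherits(psf, "psf_model")) stop("'psf' must be a psf_model")
  if (!inherits(noise, "noise_model")) stop("'noise' must be a noise_model")
  frames <- check_size(frames, "frames")
  if (length(shape) != 2L || any(shape < 1)) stop("'shape' must be c(H, W) with H, W >= 1")
  shape <- as.integer(shape)
  n <- nrow(field$positions)
  if (n > 0 && (any(field$positions[, 1L] < 1) || any(field$positions[, 1L] > shape[1L]) ||
                any(field$positions[, 2L] < 1) || any(field$positions[, 2L] > shape[2L])))
    stop("all emitter positions must lie inside the field of view")
  if (!is.null(seed)) set.seed(seed)
  bleach_times <- NULL
  if (is.null(traces)) {
    if (n == 0L) {
      traces <- matrix(0, frames, 0L)
    } else if (!is.null(field$bleach_lifetime) && is.finite(field$bleach_lifetime)) {
      bt <- bleach_traces(field, frames)
      traces <- bt$traces
      bleach_times <- bt$bleach_times
    } else {
      traces <- blink_traces(field, frames)
    }
  } else {
    traces <- as.matrix(traces)
    if (nrow(traces) != frames || ncol(traces) != n)
      stop("'traces' must be a frames x n_emitters matrix")
  }
  flat <- if (n == 0L) matrix(0, frames, prod(shape))
          else traces %*% render_emitters(field, psf, shape)
  if (noise$poisson)
    flat <- matrix(stats::rpois(length(flat), pmax(flat, 0)), nrow(flat), ncol(flat))
  flat <- flat + noise$baseline
  if (noise$read_sigma > 0)
    flat <- flat + matrix(stats::rnorm(length(flat), sd = noise$read_sigma),
                          nrow(flat), ncol(flat))
  movie <- array(flat, c(frames, shape[1L], shape[2L]))
  structure(list(movie = movie, traces = traces, bleach_times = bleach_times,
                 field = field, psf = psf, noise = noise, seed = seed),
            class = "sofi_sim")
}

#' @export
print.sofi_sim <- function(x, ...) {
  d <- dim(x$movie)
  cat(sprintf("Simulated movie: %d frames, %d x %d pixels, %d emitter(s)\n",
              d[1L], d[2L], d[3L], nrow(x$field$positions)))
  invisible(x)
}

#' Semicircle test scene
#'
#' Emitters equally spaced in angle over the upper half of a circle, with
#' on-time ratios linearly spaced left to right -- the standard scene for
#' studying the sign structure of high-order cumulants (virtual brightness
#' changes sign along the arc) and the effect of photobleaching correction.
#' The default 51 emitters spanning ratios 0.01 to 0.99 give a ratio spacing
#' of 0.0196.
#'
#' @param n_emitters Number of emitters, `>= 2`.
#' @param rho_min,rho_max On-time ratio range, `0 < rho_min < rho_max < 1`.
#' @param radius Semicircle radius in pixels.
#' @param center Circle center `c(row, col)` in pixels.
#' @param brightness On-state brightness (photons/frame).
#' @param cycle_frames Mean blink cycle length in frames.
#' @param bleach_lifetime Optional bleaching lifetime in frames.
#' @return An [emitter_field()].
#' @export
semicircle_field <- function(n_emitters = 51, rho_min = 0.01, rho_max = 0.99,
                             radius = 26, center = c(44, 32), brightness = 100,
                             cycle_frames = 20, bleach_lifetime = NULL) {
  if (n_emitters < 2) stop("'n_emitters' must be >= 2")
  if (!(rho_min > 0 && rho_min < rho_max && rho_max < 1))
    stop("need 0 < rho_min < rho_max < 1")
  theta <- seq(pi, 0, length.out = n_emitters)  # left to right
  pos <- cbind(row = center[1L] - radius * sin(theta),
               col = center[2L] + radius * cos(theta))
  emitter_field(pos, brightness = brightness,
                on_ratio = seq(rho_min, rho_max, length.out = n_emitters),
                cycle_frames = cycle_frames, bleach_lifetime = bleach_lifetime)
}

#' Three closely spaced emitters
#'
#' A minimal cusp-artifact scene: three emitters in a row at sub-Rayleigh
#' spacing with chosen on-time ratios.
#'
#' @param spacing Center-to-center distance in pixels.
#' @param center Scene center `c(row, col)`.
#' @param on_ratio Length-3 vector of on-time ratios.
#' @inheritParams semicircle_field
#' @return An [emitter_field()].
#' @export
three_emitter_field <- function(spacing = 2, center = c(16, 16),
                                on_ratio = c(0.3, 0.5, 0.7), brightness = 100,
                                cycle_frames = 20, bleach_lifetime = NULL) {
  pos <- cbind(row = rep(center[1L], 3L),
               col = center[2L] + spacing * c(-1, 0, 1))
  emitter_field(pos, brightness = brightness, on_ratio = on_ratio,
                cycle_frames = cycle_frames, bleach_lifetime = bleach_lifetime)
}
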