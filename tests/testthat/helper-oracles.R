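# Independent oracles used across the suite. These are deliberately written
# as direct enumerations / brute-force loops, separate from the package's
# implementations.

# All integer partitions of n with parts <= max_part, as vectors of parts.
int_partitions <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (p in seq.int(min(n, max_part), 1L)) {
    for (rest in int_partitions(n - p, p))
      out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

# Moment -> cumulant conversion through the set-partition (Bell polynomial)
# expansion: kappa_n = sum over set partitions pi of [n] of
# (-1)^(|pi|-1) (|pi|-1)! prod_{B in pi} m_{|B|}, grouped by block-size
# profile. m is the vector of moments for orders 1..n.
bell_cumulants <- function(m) {
  n <- length(m)
  vapply(seq_len(n), function(ord) {
    tot <- 0
    for (lam in int_partitions(ord)) {
      l <- length(lam)
      counts <- table(lam)
      n_set_partitions <- factorial(ord) /
        (prod(factorial(lam)) * prod(factorial(counts)))
      tot <- tot + (-1)^(l - 1) * factorial(l - 1) * n_set_partitions * prod(m[lam])
    }
    tot
  }, numeric(1))
}

# Brute-force centered temporal moment of a series.
brute_moment <- function(x, order) mean((x - mean(x))^order)

# Brute-force 1-D convolution with explicit reflect (mirror, edge sample not
# repeated) padding.
brute_reflect_filter <- function(x, w) {
  m <- length(x); h <- (length(w) - 1L) %/% 2L
  vapply(seq_len(m), function(i) {
    s <- 0
    for (o in seq.int(-h, h)) {
      j <- i + o
      if (j < 1L) j <- 2L - j
      if (j > m) j <- 2L * m - j
      s <- s + w[o + h + 1L] * x[j]
    }
    s
  }, numeric(1))
}

# Brute-force local dynamic range compression over all stride-1 fully
# interior window positions; also returns the coverage counter.
brute_ldrc <- function(input_im, mask_im, window) {
  wr <- window[1L]; wc <- window[2L]
  h <- nrow(input_im); w <- ncol(input_im)
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (r in seq_len(h - wr + 1L)) for (c in seq_len(w - wc + 1L)) {
    ri <- r:(r + wr - 1L); ci <- c:(c + wc - 1L)
    win <- input_im[ri, ci]; ref <- mask_im[ri, ci]
    rng <- max(win) - min(win)
    scaled <- if (rng > 0) (win - min(win)) / rng * (max(ref) - min(ref)) + min(ref)
              else matrix(min(ref), wr, wc)
    acc[ri, ci] <- acc[ri, ci] + scaled
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  list(image = acc / cnt, coverage = cnt)
}

# Zero-padding Fourier interpolation oracle for odd-length vectors: pad the
# centered spectrum with zeros to length factor * n and inverse transform.
# Returns samples at x_p = p / factor, p = 0 .. factor * n - 1.
zeropad_interp <- function(v, factor) {
  n <- length(v)
  stopifnot(n %% 2L == 1L)
  m <- factor * n
  sp <- stats::fft(v)
  half <- (n - 1L) %/% 2L
  pad <- complex(m)
  pad[1:(half + 1L)] <- sp[1:(half + 1L)]
  pad[(m - half + 1L):m] <- sp[(n - half + 1L):n]
  Re(stats::fft(pad, inverse = TRUE)) / n
}

# Closed-form zero-lag blinking cumulants of a Bernoulli(rho) marginal.
omega_n <- function(n, rho) {
  switch(as.character(n),
         "2" = rho * (1 - rho),
         "3" = rho * (1 - rho) * (1 - 2 * rho),
         "4" = rho * (1 - rho) * (1 - 6 * rho + 6 * rho^2),
         stop("omega_n only implemented for orders 2-4"))
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.xmin)

random_movie <- function(frames, h, w, seed = 1, rdist = stats::rnorm) {
  set.seed(seed)
  array(rdist(frames * h * w), c(frames, h, w))
}
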