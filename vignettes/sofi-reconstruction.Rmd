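---
title: "Temporal cumulant reconstruction of blinking-fluorophore movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal cumulant reconstruction of blinking-fluorophore movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsofi)
```

## The signal model

Super-resolution optical fluctuation imaging (SOFI) starts from a wide-field
movie of `N` independently blinking emitters that are static over the
acquisition. The signal at pixel position `r` and frame `t` is

    F(r, t) = sum_k  eps_k * b_k(t) * U(r - r_k)

where `eps_k` is the on-state brightness of emitter `k`, `b_k(t)` is its 0/1
blinking trace and `U` is the point spread function (PSF). All statistics are
computed on the fluctuation `dF = F - <F>_t` around the per-pixel temporal
mean, so the analysis sees only what blinks.

The n-th order zero-lag cumulant image is

    C_n(r) = sum_k  eps_k^n * w_n(rho_k) * U^n(r - r_k)

with `w_n(rho)` the n-th cumulant of a Bernoulli(`rho`) variable and `rho_k`
the emitter's on-time ratio. Two consequences drive everything in this
package:

* **Resolution**: `U^n` is narrower than `U`; for a Gaussian PSF of width
  `sigma` the n-th cumulant peak has width `sigma / sqrt(n)`.
* **Signed virtual brightness**: `w_n(rho)` changes sign along the `rho`
  axis (`w_3 > 0` for `rho < 1/2`, `w_4` crosses zero at
  `rho = 1/2 ± 1/sqrt(12)`), so high-order images contain positive and
  negative "virtual emitters". Where emitters of opposite sign are adjacent,
  displaying the magnitude produces cusp artifacts.

## Moments, cumulants and the recursion

`calc_moments()` computes centered temporal moments `G_n = <dF^n>` in a
two-pass sweep (mean first, then powered deviations), in double precision,
dividing by the number of frames with no small-sample correction: the
quantities being estimated are population-style time averages, and biased
estimators keep the algebra below exact. The first moment is identically
zero by construction.

`cumulants_from_moments()` applies, pixel-wise and in ascending order,

    Cum_n = G_n - sum_{i=1}^{n-1} choose(n-1, i) * Cum_{n-i} * G_i

which is the classical moment-cumulant relation specialized to this
recursive form; `moments_from_cumulants()` is its exact inverse (the round
trip is the identity to floating-point precision). The test suite pins the
recursion against an independently implemented set-partition (Bell
polynomial) expansion up to order 8.

Because the input moments are centered, `Cum_2 = G_2` and `Cum_3 = G_3`
exactly; differences appear from order 4 on.

## Photobleaching correction

Bleaching is a switch into a permanent off state. Over a whole movie it
thins the apparent on-time ratio of each emitter, which moves virtual
brightnesses across their sign boundaries and corrupts high-order images.
The correction in `correct_bleaching()`:

1. `total_signal()`: the per-frame sum over all pixels, `I(t)`.
2. `smooth_monotone()`: a moving average with an odd window (edge windows
   are shortened), then a running minimum. The literature only requires "a
   smoothed, monotonically decreasing estimate of the bleaching profile";
   the moving average + running minimum pair is the simplest deterministic
   scheme with that guarantee, and the choice is pinned by tests.
3. `bleach_blocks()`: blocks end at the first frame where the smoothed
   curve drops below `(1 - fbc)` times its value at the block start, so
   each full block spans the same fractional decay `fbc`. The threshold is
   relative to the block start (geometric), not to the global initial
   value: that is the reading under which "the fractional signal decrease
   within each block is identical". A trailing remainder shorter than 2
   frames cannot support a variance and is merged into the previous block;
   longer remainders are kept as a final (shallower) block.
4. Per-block cumulants are averaged over blocks without weighting.

Within a block the signal is approximately stationary (only a fraction
`fbc` is lost), so each block sees every surviving emitter at its true
`rho`; emitters lost in earlier blocks contribute zeros, which dilute
magnitude but not sign. Defaults (`fbc = 0.04`, `smooth_kernel = 251`)
follow standard practice for movies of a few thousand frames.

## Fourier interpolation

`fourier_interp_image()` projects an image onto a grid refined by an
integer factor using trigonometric interpolation, applied separably along
rows and columns. The implementation is deliberately matrix-based: a
forward DFT matrix of the input size, and an inverse matrix evaluated
directly at the fractional positions `p / factor` — no frequency-domain
zero padding. Conventions that the literature leaves open, fixed here and
pinned by tests:

* **Grid**: `factor * (n - 1) + 1` points spanning the original extent,
  anchored at pixel centers with both endpoints included. Original samples
  are reproduced exactly; there is no extrapolation beyond the last pixel.
* **Nyquist term**: for even sizes the `±n/2` coefficient is split evenly
  (the term becomes `cos(pi x)`), the standard real trigonometric
  interpolant, so real input gives real output to machine precision.

For odd sizes this interpolant coincides with zero-padding interpolation,
which the tests verify. Band-limited signals are reproduced exactly between
nodes. When interpolation precedes an order-`n` reconstruction, a factor of
at least `2 n` is advisable (the cumulant image carries spatial frequencies
up to `n` times the optical cutoff); the command-line tool warns below
that, but does not refuse.

## Temporal noise filtering

For block-wise processing of long acquisitions, `noise_filter1d()`
convolves each pixel's series of per-block reconstruction values with a
unit-sum 1-D Gaussian (`gauss1d_kernel()`). Filtering along the block/time
axis assumes the structure is semi-static across blocks, and leaves spatial
resolution untouched — which is why no spatial smoothing is offered.
Series ends are padded by reflection with the edge sample not repeated;
with the default 21-tap kernel on a typical 20-block series the boundary
policy is material, and reflection avoids the darkening that truncated
kernels produce. Unit kernel sum makes constant series exact fixed points;
for white noise the interior variance shrinks by `sum(w^2)`.

## Local dynamic range compression

High-order images span an enormous intensity range (`eps^n` amplifies
bright emitters disproportionately). `ldrc()` rescales the input inside a
window that scans the image at stride 1, mapping each window's range
linearly onto the range of the corresponding window of a reference image
(typically the temporal mean or the second-order image), and averages each
pixel over all windows covering it. Choices the method description leaves
open:

* Windows are evaluated only fully inside the image; edge pixels simply
  receive fewer overlapping windows. Partial windows would compare ranges
  over different pixel sets.
* A window with constant input has no contrast to place within the
  reference range and maps to the reference window minimum — the zero of
  the normalized scale — so flat backgrounds rest on the reference floor
  rather than jumping to its midpoint.

Both choices are pinned against a brute-force oracle. The operation is
invariant under positive affine maps of its input, which is exactly the
point: only local contrast survives.

## The simulator

`simulate_movie()` renders the signal model directly: analytic Gaussian PSF
evaluated at pixel centers (peak amplitude 1, truncated beyond 4 `sigma`),
brightness-scaled blinking traces, optional Poisson shot noise, Gaussian
read noise and a camera baseline, all reproducible under a seed.

Blinking is a two-state Markov chain with geometric dwell times, started
stationary. Dwell means default to `mean_on = rho * D`,
`mean_off = (1 - rho) * D` with a cycle of `D = 20` frames. At extreme
ratios this parameterization would demand a mean dwell below one frame,
which a discrete chain cannot realize; the per-frame switching
probabilities are therefore rescaled jointly into the valid range while
preserving their ratio. The stationary marginal — the only thing zero-lag
cumulants depend on — equals `rho` exactly for every ratio; only the
correlation time saturates near one frame at the extremes. Geometric dwells
are memoryless, so the stationary start needs no residual-time correction.

Bleaching draws an exponential time per emitter and zeroes the trace from
that frame on. The standard test scenes are provided: a semicircle of 51
emitters with on-time ratios from 0.01 to 0.99 (spacing 0.0196) for
sign-structure and bleaching studies, a three-emitter sub-Rayleigh row for
cusp artifacts, and 20 consecutive blocks for the block-wise workflow.

What the simulator does **not** emulate: multi-state photophysics,
brightness heterogeneity within an emitter, drift or sample motion,
depth-dependent or vectorial PSFs, structured background, camera gain and
pixel non-uniformities. Tests passing on these movies validate the
estimators and algebra under the stated model, not robustness to every
property of real data.

## Workflow object

`sofi_dataset()` wraps a TIFF stack with cached results and a provenance
log. Frames are streamed from disk in configurable chunks, so order-n
moments of long movies never materialize the stack (memory is the binding
constraint once interpolation inflates frames). Repeating a step with
identical parameters returns the cache (visible as `cached = TRUE` in the
log); changing the frame range or interpolation settings creates a new
entry. The class-mediated path and the direct function calls produce
identical images, which the tests assert, and every intermediate can be
saved as a 32-bit float TIFF with a provenance suffix (`_m6`, `_k4`,
`_k4_bc`, `_filtered`, `_ldrc`, `_InterpNum2`). A deconvolution slot in
`run_sofi2()` is an explicit extension hook (a function applied between
filtering and compression); none ships with the package.

Float TIFF output uses a minimal built-in writer (uncompressed
little-endian IEEE floats): reconstruction images are signed with a huge
dynamic range and must not pass through a unit-range integer path. Reading
uses the `tiff` package; 16-bit camera-style output round-trips bit
exactly.

## Validation scales and numerical choices

The shipped checks run at desk scale, chosen so the whole suite finishes in
well under a minute of simulation-heavy work: recursion-vs-oracle on 200
pixels of 10^4 frames; virtual-brightness recovery on nine isolated
emitters of 2 * 10^4 frames; PSF narrowing on 5 * 10^3 frames; the
semicircle bleaching scene at its standard 2 * 10^3 frames; filter variance
on 10^4 blocks. Statistical assertions use 3-standard-error bands with the
telegraph autocorrelation factor `(1 + lambda) / (1 - lambda)` included —
for the default 20-frame cycle the effective sample size is several times
smaller than the frame count, and i.i.d. formulas would be misleadingly
tight.

One caveat the package states plainly: at the zero crossings of
`w_4(rho)` (`rho ≈ 0.21, 0.79`) the fourth-order virtual brightness is so
small that its sample estimate at 2 * 10^4 correlated frames carries a
relative error of order unity. Point-wise recovery there is a property of
the estimator's variance, not of the implementation; sign-pattern
statements across many emitters (as in the bleaching-correction check) are
the robust formulation.

## Known limitations

* Only zero-lag auto-cumulants are implemented: no cross-correlation
  cumulants, no nonzero time lags, no balancing of cumulant orders.
* No deconvolution is shipped; the `deconv` hook exists for one.
* `ldrc` is linear within each window by design; gamma/log compression and
  histogram equalization are out of scope.
* The bleaching correction assumes a monotone global decay; reversible
  large-scale intensity fluctuations (focus drift, illumination flicker)
  will be mistaken for bleaching and split blocks accordingly.
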