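# rsofi

Super-resolution optical fluctuation imaging (SOFI) reconstruction in R,
for microscopists analyzing wide-field movies of blinking fluorophores
(photoswitching dyes or proteins, blinking quantum dots) and for method
developers who want every processing step testable in isolation.

SOFI computes, per pixel, temporal cumulants of the fluctuation
`δF(r,t) = F(r,t) − ⟨F(r)⟩_t` of the camera signal

&nbsp;&nbsp;&nbsp;&nbsp;`F(r,t) = Σ_k ε_k b_k(t) U(r − r_k)`,

where `ε_k` is emitter `k`'s on-state brightness, `b_k(t)` its 0/1 blinking
trace and `U` the PSF. The n-th order zero-lag cumulant image is

&nbsp;&nbsp;&nbsp;&nbsp;`C_n(r) = Σ_k ε_k^n ω_n(ρ_k) U^n(r − r_k)`,

so it depicts the same emitters through the narrower PSF `U^n`
(width `σ/√n` for a Gaussian), with signed "virtual brightness"
`ε^n ω_n(ρ)` set by the on-time ratio `ρ`. Cumulants are obtained from
centered moments `G_n = ⟨δF^n⟩` via the recursion

&nbsp;&nbsp;&nbsp;&nbsp;`Cum_n = G_n − Σ_{i=1}^{n−1} C(n−1, i) · Cum_{n−i} · G_i`.

The package implements this reconstruction plus the supporting steps used
in practice — Fourier (trigonometric) interpolation onto finer grids,
pixel-wise temporal noise filtering across acquisition blocks, local
dynamic range compression (ldrc), and photobleaching correction by
splitting the movie into blocks of equal fractional signal decay — and a
blinking-emitter simulator (two-state telegraph switching, Gaussian PSF,
optional bleaching and camera noise) that provides ground truth for every
test. I/O is multi-page TIFF (16-bit integer in, 32-bit float out).

## Worked example: bleaching corrupts high-order images, block splitting repairs them

```r
library(rsofi)

# scene: 51 emitters on a semicircle, on-time ratios 0.01..0.99, bleaching
field <- semicircle_field(bleach_lifetime = 2000 / log(2))
sim <- simulate_movie(field, psf_model(sigma = 1.5), frames = 2000,
                      shape = c(64, 64), seed = 1)
print(sim)
#> Simulated movie: 2000 frames, 64 x 64 pixels, 51 emitter(s)

raw <- cumulants_from_moments(calc_moments(sim$movie, highest_order = 4))
bc  <- correct_bleaching(sim$movie, fbc = 0.04, smooth_kernel = 251,
                         highest_order = 4)
print(bc$schedule)
#> Bleaching schedule: 14 block(s), fbc = 0.04, 2000 frames

omega4 <- function(rho) rho * (1 - rho) * (1 - 6 * rho + 6 * rho^2)
px <- round(field$positions)
at <- function(k) k$order_to_image[[4]][cbind(px[, 1], px[, 2])]
agreement <- function(k) mean(sign(at(k)) == sign(omega4(field$on_ratio)))
cat(sprintf("4th-order sign agreement: raw %.0f%%, bleach-corrected %.0f%%\n",
            100 * agreement(raw), 100 * agreement(bc)))
#> 4th-order sign agreement: raw 82%, bleach-corrected 96%
```

The emitter's bleach lifetime makes the scene lose about half its signal
over the movie. Read: the uncorrected fourth-order image gets the *sign* of
the virtual brightness wrong for 18% of the emitters — bleaching thins the
apparent on-time ratio, dragging high-`ρ` emitters across the
`ω_4` zero crossing — while reconstructing 14 blocks of ~4% decay each and
averaging restores the correct sign pattern for 96% (the few remaining
misses sit at the `ω_4 ≈ 0` crossings, where the sign is genuinely
borderline at this movie length).

Block-wise live-cell processing (per-block sixth-order moments, temporal
noise filtering across blocks, ldrc against the per-block average) is one
call: `run_sofi2(datasets, order = 6)` on a list of `sofi_dataset()`
objects; `?run_sofi2` shows the chain and its extension hook.

A thin command-line wrapper over the same functions is installed at
`inst/cli/sofi.R`:

```sh
Rscript inst/cli/sofi.R simulate --scene semicircle --bleach-lifetime 2885 --out demo.tiff
Rscript inst/cli/sofi.R cumulants --input demo.tiff --highest-order 4 --bleach-correction
```

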