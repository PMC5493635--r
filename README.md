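# blinkcomp

Eigen-analysis of fluorescence image stacks of blinking emitters.

Computational super-resolution methods (SOFI, MUSICAL, SCORE, SRRF,
localization microscopy, ...) all start from the same raw material: a stack
of `K` camera frames of `M` independently blinking fluorophores imaged
through a diffraction-limited PSF onto `N` pixels. `blinkcomp` implements
the linear decomposition that separates, exactly, *where* the
super-resolution information in such a stack lives (in space) from *how
much* of it the blinking statistics deliver (in time) — and the diagnostics
and demonstrations that quantify both.

## The model

With `I` the `N x K` stack, the frame-correlation (Gram) matrix is
`J = I Iᵀ`. For emitters with i.i.d. per-frame photon counts of mean `μ`
and standard deviation `σ`, and `G` the `N x M` system matrix whose column
`ḡ_m` is the image of emitter `m` (so `G̃ = Σ_m ḡ_m` is the mean image),

```
J = K G O Gᵀ,      O = σ² I_M + μ² 1_{M×M}
```

which decomposes into purely spatial component matrices with purely
temporal weights:

```
J  =  c1 C1 + c2 (C2 − C3)

C1 = G̃ G̃ᵀ / M²                        rank 1: mean image  (contrast only)
C2 = Σ_m ḡ_m ḡ_mᵀ / M                  auto-emitter:  squared PSF, √2 sharper
C3 = Σ_{m'≠m} ḡ_m' ḡ_mᵀ / (M(M−1))     cross-emitter: sharper still
c1 = K M (σ² + M μ²),   c2 = K (M−1) σ²
```

Structural facts the package computes, tests and exploits: the exact
identity `M C1 = C2 + (M−1) C3`; `c2/c1 < 1` always (the mean image
dominates every stack, and small `μ²/σ²` is what makes a stack favourable);
and the eigenimages of `J` and of each component, which a MUSIC-style
pseudo-spectrum `f(r') = (d_PS/d_PN)^α` turns into super-resolved source
maps. Second-order SOFI (`F(r_n, κ)`, the per-pixel lagged auto-covariance)
is included as the moment-based counterpart.

All scenes are 1-D: emitters on a line, an Airy-slice PSF
(first zero at the Rayleigh radius, 222 nm by default, FWHM 187 nm), and
either an ideal (1-nm) or a finite-pixel (e.g. 100-nm) camera. A truncated
power-law on/off blinking simulator generates per-frame photon counts with
controllable bright/dark time scales.

## Worked example

Two emitters 100 nm apart (below the 222-nm Rayleigh limit), a 10-pixel
camera with 100-nm pixels, quantum-dot-like blinking at the frame time
scale:

```r
library(blinkcomp)

psf  <- psf_model("airy1d", rayleigh_radius = 222)
grid <- camera_grid(n_pixels = 10, pixel_size = 100)
G    <- normalize_columns(build_system_matrix(emitter_pair(100), grid, psf))

bp <- blink_params(tau_max_b = 10, tau_max_d = 10, frame_time = 10,
                   n_frames = 10000)
S  <- simulate_photon_counts(2, bp, seed = 1)
S
#> Photon counts: M = 2 emitters x K = 10000 frames
#>   mu = 199.36, sigma = 96.35, mu^2/sigma^2 = 4.281

st <- emission_stats(S)
cs <- compute_components(G, K = 10000, mu = st$mu, sigma = st$sigma)
cs
#> Component set: M = 2 emitters, N = 10 pixels
#>   c1 = 1.776e+09, c2 = 9.284e+07 (c2/c1 = 0.05229)
#>   magnitudes: C1 0.5553, C2 0.6203, C3 0.6203
```

`c2/c1 = 0.052`: only ~5% of the stack's correlation content carries
cross-emitter information — the rest is the mean image. The decomposition
is exact for the simulated stack:

```r
J_model <- reconstruct_J(cs)                      # c1 C1 + c2 (C2 - C3)
J_emp   <- empirical_J(simulate_stack(G, S))      # I I'
sqrt(sum((J_emp - J_model)^2)) / sqrt(sum(J_model^2))
#> [1] 0.0009
```

Resolution diagnostics on an ideal camera: the mean image resolves the pair
only from 174 nm on a 2-nm scan, while the diagonal of `C2` — whose
effective PSF is the squared optical PSF — already resolves at 120 nm:

```r
resolution_threshold("meanimg")$threshold   #> 174
resolution_threshold("C2")$threshold        #> 120
```

MUSIC on individual components (eight emitters at 10-nm spacing, 40 pixels
of 100 nm) recovers all eight from `C2` or `C3` but only one from the
rank-one `C1`:

```r
run_experiment("eight_emitters_10nm")$peak_counts
#> $C1 [1] 1   $C2 [1] 8   $C3 [1] 8
```

A thin command-line front end over the same functions ships in
`inst/cli/blinkcomp.R`:

```sh
Rscript inst/cli/blinkcomp.R --list
Rscript inst/cli/blinkcomp.R example2 --seed 1 --out out/
```

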