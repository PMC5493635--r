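---
title: "Eigen-components of blinking-fluorophore image stacks: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigen-components of blinking-fluorophore image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blinkcomp)
```

## The model and its assumptions

A stack of `K` frames records `M` point emitters at positions $r'_m$ on a
line, imaged through a diffraction-limited PSF onto `N` pixels at $r_n$.
Frame $k$ is $I(\cdot,k) = \sum_m \bar g_m\, S(m,k)$ where $\bar g_m$ is the
pixel image of emitter $m$ (column $m$ of the system matrix $G$) and
$S(m,k)$ its photon count in that frame. Four assumptions make the algebra
exact:

1. all emitters share one per-frame photon-count distribution, with mean
   $\mu$ and standard deviation $\sigma$;
2. emitters blink independently (zero cross-emitter count covariance);
3. $K$ is large enough that empirical count moments converge, and nothing
   photo-bleaches during acquisition;
4. the system is diffraction-limited and the PSF spans several pixels.

Under 1–3 the Gram matrix $J = II^{\mathrm T}$ of the stack satisfies
$J = K\,G\,O\,G^{\mathrm T}$ with
$O = \sigma^2 I_M + \mu^2 \mathbf{1}_{M\times M}$, and expands into
$J = c_1 C_1 + c_2 (C_2 - C_3)$ with the component matrices and weights
given on the package README. The decomposition cleanly separates spatial
content (the $C$ matrices depend only on geometry and the PSF) from
temporal content (the weights depend only on $K$, $M$, $\mu$, $\sigma$).
`reconstruct_J()` and `empirical_J()` realize both sides; their agreement
on long simulated stacks is a convergence check of assumption 3, exercised
in the test suite.

## The optical model

The main text of most treatments leaves the 1-D PSF shape open. We take
the central slice of the Airy pattern,
$A(x) = \left(2 J_1(v)/v\right)^2$, $v = j_{1,1}\,x/R_0$, peak-normalized
with its first zero exactly at the Rayleigh radius $R_0$ (default 222 nm).
This choice is pinned by two independent anchors that a Gaussian or a
$\mathrm{sinc}^2$ profile cannot satisfy simultaneously: the system FWHM of
187 nm at $R_0 = 222$ nm, and the $\sqrt 2$-sharpened width of
$\mathrm{diag}(C_2)$ of $\approx134$ nm for a near-coincident pair. A
Gaussian PSF (`psf_model("gaussian1d", fwhm = ...)`) is kept for
robustness studies.

Finite pixels integrate the PSF over their extent; we approximate the
integral by the midpoint rule with `subsamples = 21` in-pixel evaluations
(the 11-point version already agrees with a 1001-point quadrature to
better than $10^{-3}$; the test suite checks this). The ideal camera
(`pixel_size = 0`) point-samples at 1-nm centers over a window at least
six Rayleigh radii wide, so profile metrics are grid-converged.

## Magnitudes, thresholds, and inflection points: conventions

**Magnitude** of a matrix means its maximum entry. For magnitude
comparisons across separations each emitter image is first normalized to
unit peak (`normalize_columns()`); this is what makes the well-separated
asymptotes come out at $\max C_2 \to 0.5$ and $\max C_1 \to 0.25$ on a
100-nm-pixel camera, and it is the scale on which the three component
magnitudes coincide in the deeply unresolved regime.

**Minima-to-maxima ratio** $R$ of a symmetric two-emitter profile is the
value at the central dip over the global maximum, defined as 1 when the
center *is* the global maximum. `resolution_threshold()` scans the pair
separation on a 2-nm grid and reports the first separation with $R < 1$;
because of the grid step the reported threshold sits 0–2 nm above the true
crossing.

**Inflection points** of magnitude-versus-separation curves are detected on
the *logarithmic* value scale. The reason is structural: below the
resolution threshold of a matrix, its magnitude is attained at the scene
center and follows $A(\Delta y/2)^2$; at the threshold the argmax jumps to
the emitter positions and the curve changes branch. On the log scale this
branch change is the first sign change of the second difference, and it
lands at the same separations as the $R$-thresholds (near 118 nm for
$C_2/C_3$, near 172 nm for $C_1$ and the mean image — both computed by the
test suite). On the linear scale the smooth inflection of
$A(\Delta y/2)^2$ itself (near 118 nm) masks the $C_1$ branch point, which
is why the default is `log_scale = TRUE`; curves with non-positive values
fall back to the linear scale automatically. Curves are smoothed with a
5-sample Savitzky–Golay (local quadratic) filter at the 2-nm sweep step.

Two detection rules are exposed. `method = "crossing"` (default) is the
second-difference sign change described above and is the right tool for
noiseless curves. Noise-averaged curves retain realization jitter on their
plateaus that generates spurious local sign changes, so for them
`method = "steepest"` locates the global minimum of the smoothed first
derivative — the same point for a clean kink, and robust under jitter.

**The noise study** follows the protocol of applying Poisson noise to $G$
itself: scale so the peak expected count is $\mathrm{SNR}^2$ (256 at peak
SNR 16 — the package defines peak SNR as $\sqrt{\text{peak count}}$, the
Poisson-natural convention), draw, scale back; 100 independent executions
are averaged before analysis. We could not reproduce the $\approx$ +40 nm
outward shift of the inflection points quoted in the literature for this
noise level with any detector applied consistently to both the noiseless
and the averaged noisy curves; the steepest-descent detector measures a mean
absolute shift of roughly 10 nm (the acceptance script computes and
reports the exact value). The transition *end* of the noisy curves does
move outward by several tens of nm, which is plausibly what a visual
reading of mean-and-spread plots picks up; we report the
consistent-detector number rather than tune a rule to a target.

## The blinking generator

On/off intermittency is modeled as an alternating renewal process with
truncated power-law sojourns, $p(\tau)\propto\tau^{-a}$ on
$(\tau_{\min}, \tau_{\max})$ — the standard quantum-dot phenomenology.
Defaults: exponent $a = 1.5$, $\tau_{\min} = 0.01\,\tau_{\max}$, separate
$\tau_{\max,b}$ (bright) and $\tau_{\max,d}$ (dark), frame time
$T = 10$ ms, and an emission rate of 40 photons/ms so a fully bright frame
averages ~400 photons. Emission within bright intervals is Poisson at
constant rate. All randomness flows from explicit integer seeds; a master
seed fans out to per-emitter sub-seeds by fixed offsets.

The generator reproduces the qualitative photon-count regimes: long dark
states give zero-inflated, strongly super-Poissonian counts
($\mu^2/\sigma^2 \ll 1$, the localization-microscopy regime); comparable
time scales give broad count distributions; negligible dark states give
near-Poisson counts at the full rate. In the slow-blinking limit
($\tau_{\max,b} \gg T$) the ratio $\mu^2/\sigma^2$ sweeps roughly
duty/(1−duty) across bright/dark asymmetries, as expected.

One property quoted for the frame-time-scale regime of quantum dots —
$\mu^2/\sigma^2 < 0.1$ across all bright/dark asymmetries — is *not*
attainable in this model class, and we flag it rather than emulate it: with
$\tau_{\max,b}\approx T$, a binary on/off emitter has per-frame bright time
$X \in [0, T]$, so
$\mathrm{Var}(\text{count}) \le r^2\,\mathbb E[X](T-\mathbb E[X]) +
r\,\mathbb E[X]$ and hence
$\mu^2/\sigma^2 \gtrsim \text{duty}/(1-\text{duty})$ for bright counts.
Getting $\mu^2/\sigma^2 < 0.1$ at *all* bright/dark ratios therefore
requires within-bright-state intensity fluctuations (multi-level or
diffusion-controlled emission models), which a two-state model cannot
produce by construction. The corresponding acceptance expectation is left
failing for the equal and bright-dominated regimes, with the simulated
ratios computed by the test.

## MUSIC on component matrices

`eigenimages()` decomposes a symmetric matrix with singular values
$s_j = \sqrt{|\lambda_j|}$ (absolute values because $C_3$ is indefinite).
Subspace splitting supports three policies; the default `eigengap` places
the boundary at the largest ratio $s_j/s_{j+1}$ among values above a
relative floor of $10^{-10}$, with values past the retained set treated as
zero. The leading eigenimage — the mean image direction — is always
assigned to the signal side.

Two numerical points matter for strongly sub-diffraction scenes:

* **Conditioning.** Forming $C_2 = GG^{\mathrm T}/M$ squares the condition
  number of $G$. For eight emitters at 10-nm spacing the eighth eigenvalue
  of $C_2$ falls below machine epsilon relative to the first even though
  the direction is well represented in $G$. `eigenimages(A, basis = ...)`
  therefore accepts the component's *defining factor* — $G$ for
  $C_2/C_3$, the mean image for $C_1$ — and decomposes within its exact
  column space, which halves the decade span and keeps the full signal
  rank. The orthogonal complement then has exactly zero singular value.
* **Null projections.** $d_{PN}(r')$ is computed as the explicit residual
  norm $\|g(r') - U_S U_S^{\mathrm T} g(r')\|$, not by subtracting
  projection norms, so near-complete cancellation at true emitter
  positions resolves to machine precision. $d_{PS}$ and $d_{PN}$ are
  Euclidean norms of subspace projections, so
  $d_{PS}^2 + d_{PN}^2 = \|g(r')\|^2$ holds identically (a plain sum of
  per-eigenimage magnitudes would violate this identity and be
  basis-dependent on the null side). $d_{PN}$ is floored at $10^{-12}$ to
  keep $f$ finite; floored points are flagged.

The pseudo-spectrum uses $\alpha = 1$ in the component-level studies so
the exponent adds no extra nonlinearity. Peak counting reports strict
local maxima within the emitter-containing window that clear both a
relative height (5% of the window maximum) and a relative prominence
(5%): prominence is what distinguishes eight genuine spikes from ripples
riding on the broad rank-one $C_1$ hump.

For the noisy demonstration (eight emitters at 100-nm spacing, peak SNR
20 on $G$) a single noise realization recovers all eight peaks only about
half the time — neighbouring peaks occasionally merge. The packaged
protocol averages $\log f$ over 20 independent noise executions (a
geometric-mean pseudo-spectrum), in the same spirit as the 100-execution
averaging of the magnitude noise study, and then counts peaks; this is
stable across master seeds. The per-realization behaviour is accessible by
setting `n_realizations = 1`.

## SOFI

`sofi2()` implements the per-pixel lagged auto-covariance with the sum
over the $K-\kappa$ valid pairs and, by default, the conventional $1/K$
normalization ($1/(K-\kappa)$ is a toggle). For the zero-lag image two
model expressions circulate: the component-weighted
$c_2\,\mathrm{diag}(C_1 + C_2 - C_3)/K$ and the definitional variance
expectation $\sigma^2 \sum_m G(n,m)^2 = \sigma^2 M\,\mathrm{diag}(C_2)$.
Using the exact identity $M C_1 = C_2 + (M-1)C_3$, the former equals
$\sigma^2\,\mathrm{diag}(M C_2 - C_1)$ — i.e. the two differ by exactly
$\sigma^2\,\mathrm{diag}(C_1)$. `sofi_component_check()` computes both,
plus the empirical image, and reports all pairwise distances without
hard-coding a verdict; on simulated stacks the empirical image matches the
variance expectation (the test suite quantifies this at $K = 10^5$), so
the component-weighted formula should be read as dropping the
$\sigma^2\,\mathrm{diag}(C_1)$ term.

## Problem sizes and determinism

The shipped studies are desk-scale by design: $N \le 2001$ pixels,
$K \le 10^5$ frames, $M \le 8$ emitters, 100 noise executions for the
magnitude study and 20 for the MUSIC study, separations swept at 2 nm.
Every stochastic path takes an explicit integer seed, and experiment
bundles embed the seed and a config hash, so reruns are bit-identical.

## What the synthetic scenes do not cover

The generator emulates ideal conditions: identical emitters, no
photobleaching, no background fluorescence or camera read noise, no drift,
1-D geometry, and a shift-invariant in-focus PSF. Passing tests therefore
validate the algebraic structure, the resolution diagnostics, and the
relative behaviour of the components under controlled noise — not
performance on real 2-D data with heterogeneous photophysics. The
non-independent-emitter extension (relaxing assumption 2) and
higher-order/balanced/Fourier SOFI variants are out of scope.
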