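---
title: "Adaptive nonlocal means denoising of Monte Carlo fluence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive nonlocal means denoising of Monte Carlo fluence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdenoise)
```

## The problem

Monte Carlo (MC) photon-transport simulation estimates the light fluence
`u(x)` in a turbid medium (tissue) by averaging millions of random
photon-packet trajectories. At affordable packet counts the estimate
carries *shot noise*: the per-voxel standard deviation equals the square
root of the local photon visit count, so the noise is intensity-dependent
and spatially varying — strong in the dim far field, negligible near the
source. Fluence fields are smooth, strictly non-negative, and span many
orders of magnitude, which rules out denoisers built for low-bit-depth
imagery. `mcdenoise` implements a 3-D spatially adaptive nonlocal means
(ANLM) filter for such volumes, the synthetic data needed to exercise it,
and the repeated-realization metrics used to score it.

## The filter

One pass of the filter updates each voxel `xi` as a weighted average over
a cubic *search volume* `Vi` of radius `rV` (default 3, i.e.
`(2*3+1)^3 = 343` candidates):

    u'(xi) = sum_{xj in Vi} w(xi, xj) u(xj)

with weights driven by the similarity of the cubic *patches* `Pi`, `Pj`
of radius `rP` around the two voxels:

    w(xi, xj) = (1/Zi) exp( -d2(xi, xj) / h(xi)^2 ),
    d2(xi, xj) = ||u(Pi) - u(Pj)||^2 / (2*rP + 1)^3,

where `Zi` normalises the accepted weights to sum to one. The bandwidth
adapts to the local noise level through `h(xi)^2 = 2 * beta *
sigma2(xi)`; with the per-voxel-normalised distance above and an unbiased
`sigma2`, two pure-noise patches have `E[d2] = 2 sigma2`, so `beta = 1`
(the default) weights a pure-noise candidate by `exp(-1)` — the classical
normalisation of optimised NLM filters. `beta` is exposed because the
proportionality between bandwidth and noise variance is a convention, not
a derived quantity.

Three further design elements matter in practice:

* **Preselection.** A candidate is compared only if its local box mean
  and box variance (over the radius-`rB` box, default 1) are close to the
  centre voxel's: mean ratio within `[0.95, 1/0.95]`, variance ratio
  within `[0.5, 2]`. This removes dissimilar candidates cheaply and, on
  steep fluence slopes, restricts averaging to near-iso-fluence
  candidates, which is what keeps the filter's bias low. The thresholds
  follow the established NLM preselection lineage and are configurable.
  When both statistics in a ratio are at machine-zero scale (below
  `1e-12` of the volume maximum) the pair is treated as similar; when
  only one is, it is rejected.
* **Centre weight.** The centre voxel's own weight is set to the maximum
  accepted non-centre weight (1 if none), the classical NLM convention
  that prevents the trivial self-match from dominating. If nothing
  survives preselection, the voxel is returned unchanged.
* **Boundary handling.** The volume is mirror-padded by `rV + rP` before
  the weighting stage, so every search volume and patch is complete and
  no inner loop needs a special case. The exported `box_filter()` instead
  clips windows at the boundary (with a correspondingly reduced divisor),
  which is the natural convention for a standalone smoother.

### The adaptive noise-variance estimate

The local noise variance is estimated from the pseudo-residual
`R(x) = u(x) - boxmean(u)(x)`, the difference between the volume and its
radius-`rB` box filter. The estimator is

    sigma2(xi) = c(rV, rB) * gamma_B * min_{xj in Vi} boxmean(R^2)(xj)

built in three deliberate steps:

1. `gamma_B = NB / (NB - 1)` (with `NB = (2*rB+1)^3`) removes the
   small-sample bias of the squared residual: for i.i.d. noise of
   variance `s2`, `E[R^2] = s2 (NB-1)/NB`.
2. The squared residuals are *box-averaged before* the minimum is taken.
   A per-voxel squared residual is a one-degree-of-freedom variance
   estimate; the minimum of ~343 such values is vanishingly small
   (orders of magnitude below the true variance), which would collapse
   the bandwidth and switch the filter off. Averaging `R^2` over the box
   first gives each candidate estimate enough degrees of freedom that
   the minimum is a stable, structure-robust statistic. The minimum over
   the search volume is kept because that is what protects the estimate
   from inflation by edges and gradients, which contaminate residuals
   asymmetrically (upward only).
3. The minimum of many correlated local averages still undershoots the
   true variance by a predictable factor, so a calibration constant
   `c(rV, rB)` is applied, chosen once by simulation on i.i.d. standard
   Gaussian volumes so that `E[sigma2] = s2` for spatially white noise
   (`c(3, 1) = 2.61`). Factors for common radii are frozen in the
   package; other combinations are simulated on demand with a fixed
   internal seed, so the filter remains deterministic. See
   `sigma_calibration_factor()`.

`sigma2` is clamped below at `min_sigma^2` (default 0). Where it is
exactly zero — locally constant data — the voxel is passed through
unchanged, which makes constant volumes exact fixed points of the filter.

### Noise models

The default `gaussian` mode averages intensities directly, matching MC
shot noise in its Gaussian regime (and Poisson noise reasonably well at
low counts, where preselection and the adaptive bandwidth do the heavy
lifting). The `rician` mode, intended for magnitude MRI data, averages
squared magnitudes and applies the standard second-moment bias removal
`sqrt(max(m2 - 2*sigma2, 0))` afterwards. The Rician pathway uses the
conventional correction; nothing beyond the standard form is claimed
for it.

### Wavelet sub-band mixing

The full denoiser `anlm_denoise()` runs two passes, `rP = 1` and
`rP = 2`, and merges them in the wavelet domain: a single-level
orthonormal 3-D Haar decomposition, approximation band (`LLL`) from the
large-patch pass (smoother low frequencies), all seven detail bands from
the small-patch pass (better fine structure). Haar is the simplest
perfect-reconstruction choice; the assignment direction follows the
"hard mixing" convention of the sub-band mixing literature and is
configurable (`lll_from`). Odd extents are handled by replicating the
final slice before pairing and dropping it after inversion, so the round
trip stays exact. Mixing can leave tiny negative excursions on an
otherwise non-negative field; `anlm_denoise()` clamps its output at zero
since fluence is physically non-negative.

### Tiled execution

`tiled_filter()` partitions the volume into blocks and processes each
block from a subvolume extended by an apron of `rV + rP` voxels per side
— the margin needed so that every search volume and patch of a block
voxel is available (an interior block of `T^3` voxels loads
`(T + 2(rV+rP))^3`). The preprocessing statistics (box mean/variance,
residual, `sigma2`) are computed once globally, mirroring the two-stage
workflow the filter is designed around, and only the weighting stage is
tiled. All neighbourhood sums are evaluated as direct separable sums
with a fixed per-voxel operation order, so the tiled result is
*bit-identical* to the untiled one for any block shape, including blocks
that do not divide the volume.

## Synthetic data

Two generators cover the evaluation needs without external data:

* `mc_fluence()` is a minimal voxel photon-packet Monte Carlo:
  exponentially sampled scattering optical depth, DDA voxel traversal,
  continuous absorption weighting, Henyey–Greenstein scattering, Fresnel
  reflection/refraction at internal refractive-index steps, Russian
  roulette, and a path-length fluence estimator normalised per launched
  packet. The outer boundary is matched (packets escape); Fresnel physics
  is exercised by internal index contrasts. It is a fixture generator
  with the statistical structure the filter assumes, not a
  production transport code: no time gating, no detectors, no mesh
  geometries.
* `diffusion_fluence()` evaluates the infinite-medium point-source
  diffusion Green's function `exp(-mueff*r)/(4*pi*D*r)`, and
  `add_shot_noise()` converts any non-negative field into a Poisson
  realization with a prescribed effective photon budget (Gaussian
  approximation above 50 expected counts). This surrogate is what the
  quantitative experiments use: it has exactly the square-root
  noise-to-signal structure of MC fluence while being fast enough for
  hundreds of realizations.

Three benchmark media are provided at any grid scale: B1 homogeneous
(`mua = 0.02/mm`, `mus = 10/mm`, `g = 0.9`, `n = 1.37`), B2 with a
cubic five-fold absorber, B3 with a cubic five-fold refractive-index
contrast (spanning fractions 0.3–0.7, 0.3–0.7, 0.1–0.5 of the domain,
the 40 mm cube centred at (50, 50, 30) mm at full scale).

What the surrogate does *not* emulate: spatial noise correlations along
photon paths (real MC noise is correlated between neighbouring voxels on
the same trajectories; Poisson draws are independent), transport effects
near sources and boundaries, and heterogeneous media (the analytic
reference is homogeneous). Tests passing on the surrogate therefore
demonstrate the filter's behaviour under the assumed noise model, not
full equivalence on production MC output.

## Evaluation metrics

With `N` independently seeded realizations, the per-voxel SNR is
`20*log10(mean/sd)` (`snr_map()`); voxels with zero mean or zero
standard deviation are masked invalid rather than mapped to infinities.
`delta_snr()` subtracts two such maps on their jointly valid voxels,
forms the *effective region* `dSNR > 3 dB` (a heuristic threshold,
exposed as a parameter), and summarises by medians — medians, not means,
so that the unreliable SNR estimates of barely-visited voxels do not
bias the summary. Whole-volume medians are taken over valid voxels only.
The effective-region median converts to the *filter-equivalent photon
multiplier* `M_F = 10^(dSNR/10)`: the factor by which the photon count
would have to grow to buy the same improvement, since a `c`-fold photon
increase yields `10*log10(c)` dB under shot noise.

## Problem sizes and numerical choices

The quantitative experiments run at desk scale as the package's own
protocol: a 64-voxel cubic diffusion phantom (source at the centre of
one face, one transport mean free path deep), an effective budget of
`1e8` photons — chosen so the distal half of the volume sits below 10 dB
SNR, the regime the filter targets — with 100 realizations for the
denoising-gain experiment and 50 per budget for the scaling experiment.
Accumulators are double precision throughout; volumes quantise to
float32 only on raw-format I/O. The filter contains no randomness;
generators take explicit seeds (realization `i` uses `base_seed + i`)
and restore the caller's RNG state.

Known limitations: the Monte Carlo fixture is CPU-bound and intended for
small grids (up to ~1e6 packets in seconds); single-level Haar is the
only mixing wavelet; the adaptive variance calibration assumes roughly
white noise within the box scale — strongly correlated noise would be
under-estimated; and `filter_pass()` refuses log10-scale volumes rather
than silently filtering display data, since the filter's statistics
assume linear fluence.
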