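# mcdenoise

Adaptive nonlocal means (ANLM) denoising of 3-D Monte Carlo photon-fluence
volumes, for people who run voxel Monte Carlo light-transport simulations
(biophotonics, diffuse optics) and want the image quality of a large photon
budget without paying for it. MC fluence images carry *shot noise* — the
per-voxel standard deviation equals the square root of the local photon
visit count — so the noise is spatially varying: negligible near the
source, dominant in the dim far field. A fixed-strength smoother either
blurs edges or leaves the far field noisy; the ANLM filter adapts.

## The filter

Each voxel `xi` becomes a weighted average over its cubic search volume
`Vi` (radius `rV = 3`, 343 candidates):

    u'(xi) = sum_{xj in Vi} w(xi,xj) u(xj),
    w(xi,xj) = (1/Zi) exp( -||u(Pi) - u(Pj)||^2 / (|P| h(xi)^2) )

with patch radius `rP`, candidate preselection on local mean and variance
ratios, and a per-voxel bandwidth `h(xi)^2 = 2 beta sigma2(xi)` driven by
a noise-variance estimate built from pseudo-residuals
`R = u - boxmean(u)` (a calibrated minimum of box-averaged `R^2` over the
search volume). Two passes (`rP = 1` and `rP = 2`) are merged by 3-D Haar
wavelet sub-band mixing: low frequencies from the large-patch pass,
details from the small-patch pass. Gaussian and Rician noise models are
supported; a tiled execution path is bit-identical to the untiled filter.

Denoising quality is scored by repeated-realization SNR maps,
`SNR(r) = 20 log10(mean/sd)` over independently seeded runs; the median
improvement inside the effective region (`dSNR > 3 dB`) converts to the
filter-equivalent photon multiplier `M_F = 10^(dSNR/10)`.

The package also ships a minimal voxel Monte Carlo photon simulator
(Henyey–Greenstein scattering, continuous absorption, Fresnel refraction,
Russian roulette) and an analytic-diffusion + Poisson shot-noise surrogate,
so every experiment is generated in code.

## Worked example

Denoise shot-noise realizations of a homogeneous diffusion phantom and
measure the SNR gain:

```r
library(mcdenoise)

phantom  <- b1_diffusion_phantom(grid = 32)        # noise-free reference
noisy    <- add_shot_noise(phantom, 1e7, seed = 1) # one MC-like realization
denoised <- anlm_denoise(noisy)                    # rP = 1 & 2, mixed
print(denoised)
#> <volume3d> 32 x 32 x 32 voxels, 1 x 1 x 1 mm, linear scale
#>   range [0, 0.192], mean 0.0008864

raw <- lapply(1:25, function(i) add_shot_noise(phantom, 1e7, seed = i))
den <- lapply(raw, anlm_denoise)
rep <- delta_snr(snr_map(raw), snr_map(den))
print(rep)
#> <delta_snr_report> median dSNR 8.86 dB (all), 8.99 dB (effective > 3 dB), M_F = 7.92
#>   effective region: 31306 voxels
```

The report says: across 25 repeated realizations, the filter raised the
median per-voxel SNR by 8.9 dB in the voxels it affects — the same
improvement as running about 8 times more photons (`M_F`), at a fraction
of the cost.

Volumes read and write as headerless little-endian float32 (`.mc2`-style,
`read_raw_volume()`/`write_raw_volume()`) or NIfTI-1 (`read_nifti()`/
`write_nifti()`). A command-line front end with `simulate`, `denoise` and
`evaluate` subcommands is installed at `inst/cli/mcdenoise`.

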