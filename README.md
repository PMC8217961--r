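# wtmmaniso

Multiscale quantification of fiber alignment in grayscale microscopy
images with the 2D **wavelet transform modulus maxima (WTMM)
anisotropy** method, plus the synthetic fiber phantom, white-noise
robustness experiment and Fourier angular-amplitude baseline needed to
calibrate it entirely from simulation.

The motivating application is second-harmonic generation (SHG) imaging
of collagen (512×512 px over a 180 µm field of view), where changes in
fiber alignment across size scales separate normal from pathological
tissue. Everything works on any single-channel TIFF/PNG with a known
pixel size.

## The method in brief

The continuous wavelet transform with first-derivative-of-Gaussian
wavelets gives, at every scale *a*, the gradient of the
Gaussian-smoothed image:

    T[f](b, a) = ∇(φ_a ∗ f)(b),   modulus M(b,a), argument A(b,a)

WTMM points are pixels where the modulus is locally maximal along the
argument direction — multiscale edge detectors that organize into
maxima chains. The angles of all WTMM vectors at one scale form a
probability density P_a(A) over (−π, π]; for isotropic texture it is
flat at 1/2π. The **anisotropy factor**

    F_a = ∫ |P_a(A) − 1/2π| dA   ∈ [0, 2]

is 0 for isotropy and grows with alignment; computed across a scale
ladder it yields a multiscale anisotropy profile. The Fourier baseline
`r_computed()` scores the same images as the circular resultant length
of the angular spectral-amplitude distribution at doubled angles
(0 = random, 1 = perfect alignment).

## Worked example

Simulate a strongly aligned fiber phantom (50 fibers of 2 µm diameter,
orientations in [85°, 95°]) and an unaligned one, and compare their
anisotropy at the 2.5 µm scale:

```r
library(wtmmaniso)

aligned   <- simulate_fiber_image(fiber_sim_config(seed = 11,
               angle_range_deg = c(85, 95)))
unaligned <- simulate_fiber_image(fiber_sim_config(seed = 12,
               angle_range_deg = c(0, 180)))

cfg <- wavelet_config(scales = key_scales())   # 2.46 ... 39.4 um
multiscale_profile(aligned, cfg, label = "aligned")
#> <anisotropy_profile> aligned: 5 scales, 2.461 - 39.38 um
#>  scale_um     fa n_maxima
#>     2.461 1.2030     9368
#>     4.922 0.9008     5984
#>     9.844 0.5740     3000
#>    19.690 0.7151     1426
#>    39.380 0.9493      932

multiscale_profile(unaligned, cfg)$fa[1]  # 0.3784
r_computed(aligned)    # 0.582
r_computed(unaligned)  # 0.165
```

At the 2.5 µm scale the aligned phantom's WTMM angles pile up
perpendicular to the near-vertical fibers (bins around 0° and ±180°),
giving F_a ≈ 1.20 against ≈ 0.38 for the unaligned phantom; the
Fourier score ranks them the same way (0.58 vs 0.16). The maxima count
falls with scale because the border-exclusion margin grows with the
smoothing width, and per-image F_a at the largest scales carries a
positive finite-sample bias (both phantoms drift upward there), which
is why cohort workflows compare groups scale by scale instead of
reading single-image values absolutely.

Cohort workflows: `run_calibration()` (consecutive angle-range
discrimination counts by Wilcoxon rank-sum), `run_noise_experiment()`
(additive white noise at 1–20× the image mean), `analyze_cohorts()`
(labeled image sets vs a control, normalized profiles and crossover
scales). A thin CLI over the same functions is in `exec/wtmmaniso`
(subcommands `simulate`, `analyze`, `calibrate`, `noise-exp`,
`compare`).

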