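---
title: "Multiscale fiber anisotropy with wavelet modulus maxima: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale fiber anisotropy with wavelet modulus maxima: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtmmaniso)
```

## The method

Fibrillar structures in grayscale microscopy — the motivating case is
second-harmonic generation (SHG) imaging of collagen in skin — produce
intensity edges whose *directions* encode how strongly the fibers are
aligned. This package quantifies that alignment as a function of size
scale with the 2D wavelet transform modulus maxima (WTMM) machinery.

**Transform.** The analyzing wavelets are the two partial derivatives of
an isotropic 2D Gaussian, so the continuous wavelet transform of an
image $f$ at position $\mathbf b$ and scale $a$ is the gradient of the
Gaussian-smoothed image:
$$ T_{\psi}[f](\mathbf b, a) = \nabla\, (\phi_a * f)(\mathbf b), $$
computed with the $a^{-2}$ integral normalization so responses are
comparable across scales. We store the modulus
$\mathcal M(\mathbf b, a)$ and argument $\mathcal A(\mathbf b, a)$
(angle in $(-\pi, \pi]$) of that gradient vector.

**Maxima.** At each scale, WTMM points are pixels where the modulus is
locally maximal *along the argument direction* — the multiscale analogue
of a Canny edge test. These points organize into "maxima chains" tracing
the edges of structures of size $\sim a$ (`chain_maxima()` labels them by
8-connectivity).

**Anisotropy factor.** The angles of all WTMM vectors at one scale are
binned into a probability density $P_a(A)$ over $(-\pi, \pi]$. Perfectly
isotropic texture gives the flat density $1/2\pi$; alignment concentrates
angles perpendicular to the fiber axis. The anisotropy factor is the
$L^1$ departure from flatness,
$$ F_a = \int_{-\pi}^{\pi} \left| P_a(A) - \tfrac{1}{2\pi} \right| \, dA
  \in [0, 2], $$
evaluated exactly as a Riemann sum because the binned density is
piecewise constant. $F_a = 0$ iff the binned pdf is exactly flat; the
supremum 2 is approached by a delta-like pdf.

**Fourier baseline.** For comparison, `r_computed()` scores alignment
from the angular distribution of the 2D spectral amplitude: each angular
bin is an axial observation at doubled angle, and the score is the
normalized circular resultant length, 0 for random and 1 for perfect
alignment. It is a single-number, single-spatial-frequency-range summary,
whereas $F_a$ is a function of scale.

## Parameters that matter

* `pixel_size` (µm/px, default 180/512 ≈ 0.352): the SHG field of view
  this method was designed around — 512×512 px over 180 µm.
* `scales`: the scale $a$ is the standard deviation of the smoothing
  Gaussian in pixels (converted from µm). The dilation convention is not
  universal in the literature; this one is stated so results can be
  compared. `key_scales()` gives the five octave scales 7, 14, 28, 56,
  112 px (≈ 2.5, 4.9, 9.8, 19.7, 39.4 µm) at which headline results are
  reported; `scale_ladder()` gives a 40-point geometric ladder over the
  same four octaves for full profiles. The five octave scales are powers
  of two in pixels and are supplied as an explicit vector because no
  40-point geometric grid contains all of them.
* `n_bins` (default 72): 5° angle bins, matching the 5° granularity of
  the calibration angle ranges. The finite-sample baseline $F_a$ of an
  isotropic image grows with the bin count (roughly
  $\sqrt{2B/\pi n}$ for $n$ angles in $B$ bins), so reported $F_a$
  values are only comparable at a stated `n_bins`.
* `border_factor` (default 2) and `border_cap_frac` (default 1/8):
  convolution is FFT-based with periodic wrap-around, so maxima within
  `border_factor * a` pixels of an edge are discarded. The margin is
  capped at 1/8 of the shorter image side: without the cap, any scale
  beyond a quarter of the image side would lose every pixel, making the
  largest scales unmeasurable on 512 px images. Below the cap the margin
  fully covers the dominant wrap contamination; above it, large-scale
  estimates accept some residual contamination as the price of being
  defined at all — acceptable here because cohort comparisons apply the
  same treatment to every image.
* `modulus_floor` (default 1e-6 × max modulus): suppresses
  floating-point plateau "maxima" on flat backgrounds.
* `truncate` (default 4): the Gaussian is sampled on ±4a; the neglected
  tail mass is ~3×10⁻⁴ of the kernel.

Numerical tie-breaks: the directional maximum test interpolates the
modulus bilinearly at ±1 px along the argument direction and requires
strictly greater forward, non-strictly greater backward — a deterministic
resolution of plateaus that the "locally maximum" phrase leaves open.
Angles returned by `atan2` at exactly $-\pi$ (signed zeros) are mapped to
$+\pi$ so the pdf support is $(-\pi, \pi]$.

## The synthetic fiber simulator

`simulate_fiber_image()` renders the calibration phantom: 50 straight
fibers per 512² image, drawn as anti-aliased rotated rectangles
(fractional edge coverage; overlap composites by maximum), diameters of
2–8 µm, lengths uniform in 40–60 µm, centers uniform over the full frame
(silent clipping at the border), orientations uniform in a configurable
range with 90° = vertical. The rendered image is degraded by a
normalized pillbox (circular averaging) filter of radius 3 px followed
by a normalized 5 px linear motion-blur kernel whose direction is drawn
uniformly per image and recorded in the image attributes — the published
phantom defers motion-kernel specifics to its source, so length and
randomized direction are declared here and reproducible from the seed.
Foreground/background levels are 255/0; they are immaterial because
$F_a$ is invariant under intensity scaling and offsets (covariances
verified in the test suite).

The calibration design is 19 nested angle ranges centered on 90° — from
perfectly parallel `[90, 90]` through `[85, 95]` to the unaligned
`[0, 180]` in 5° half-width steps — times 4 diameters times 100 images:
7600 images. The published enumeration starts at `[85, 95]` but counts
19 ranges and 18 consecutive pairs, which forces the inclusion of the
degenerate parallel range; placing it at the narrow end preserves both
the stated count and the monotone narrow→wide ordering.

Additive noise for the robustness experiment is pixelwise uniform on
$[0, 2k\mu]$, where $\mu$ is the clean-image mean and $k \in \{1, 2, 5,
10, 20\}$ — a non-negative white noise field whose mean is the stated
multiple of the image mean without any clipping bias. (The distribution
family is a declared choice; only "white noise" with a given mean is
specified by the design.)

What the simulator does **not** emulate: fiber curvature and waviness,
3D projection effects, photon (Poisson) noise, detector PSF anisotropy,
and intensity variation along fibers. Passing calibration tests
therefore demonstrates sensitivity to *orientation dispersion of
straight fibers under mild blur*, not performance on every real-tissue
complication.

## Statistical workflows

`run_calibration()` scores every simulated image and counts, per
diameter and scale, how many of the 18 consecutive-range pairs a method
separates at $p < 0.05$ by a two-sided Wilcoxon rank-sum test on
per-image scores (exact permutation distribution for combined $n \le
20$ without ties, normal approximation with tie correction otherwise).
No multiple-testing correction is applied — the count of uncorrected
rejections *is* the sensitivity readout being replicated, not a
recommended inferential procedure. The sampling unit is always the
per-image score, never pooled maxima.

`run_noise_experiment()` builds the seven groups of the robustness
study (clean [60°, 120°] fibers, five noise multiples, pure noise) and
compares the heaviest-noise group against pure noise at the largest
scale, where smoothing suppresses the (small-scale) noise but not the
fiber anisotropy.

`analyze_cohorts()` generalizes the tissue workflow to any labeled
image sets: per-scale rank-sum comparisons for all cohort pairs,
control-normalized median profiles, and detection of crossover scales
where two cohorts' normalized profiles swap order. Cohort medians at a
scale use only images with a defined $F_a$ there (scales whose maxima
set is empty are *missing*, not zero, to avoid biasing medians toward
zero).

## Design choices where the procedure was open

* **Gradient orientation.** WTMM vectors point toward increasing
  intensity (ascending gradient), so fiber-perpendicular angles
  dominate the pdf — e.g. near-vertical fibers concentrate angles near
  0° and ±180°.
* **All maxima enter the pdf, unweighted.** No per-chain subsampling
  and no modulus weighting (a `weight_by_modulus` flag exists but is
  off by default): the pdf is of "the angles associated to each WTMM
  vector", taken literally.
* **Group pdfs** are averaged as the mean of per-image densities.
* **Fourier baseline windowing.** The angular amplitude is computed
  after mean removal and 2D Hann apodization. Without a window, the
  spectral leakage of frame-clipped fibers concentrates amplitude in a
  cross along the frequency axes; for near-vertical fibers that
  artifact is orthogonal to the true signal and inverts the score's
  ranking of aligned vs unaligned images. Apodization is standard
  practice for FFT orientation analysis; `window = "none"` disables it.
  Amplitude is integrated over all radii by default (`radial_band`
  restricts it), and 180 bins of 1° are used.
* **Missing 19th range.** See the simulator section: the degenerate
  `[90, 90]` range completes the 19-range design.

## Problem sizes in the tests

The test suite exercises reduced designs chosen to keep the full run
in the tens of minutes on one core while preserving each qualitative
claim: oracle equivalence on 64² images; the consecutive-range
discrimination comparison at 25 images/group for all four diameters;
the noise experiment at its full 100 images/group (its headline
p-value needs the full sample size); the 19-range monotonicity check
at 50 images/group for 2 µm fibers; and constructed 512² cohorts of
12 images for the cohort-comparison patterns. The acceptance script
reruns the calibration at the full 100 images/group for the 2 µm and
4 µm diameters.

## Known limitations

* Periodic convolution plus a capped exclusion margin means $F_a$ at
  scales above 1/4 of the image side mixes in residual wrap-around
  contamination; profiles from images smaller than ~256 px should be
  read qualitatively at their largest scales.
* $F_a$ has a positive finite-sample bias that grows as maxima counts
  fall (large scales, small images) and with `n_bins`; compare cohorts
  only at matched scale, image size and bin count.
* The sparse-maxima regime (large scale on a small interior) makes
  per-image $F_a$ noisy; the workflows report per-scale medians and
  quartiles rather than means for this reason.
* The Fourier baseline is implemented as one published interpretation
  (doubled-angle circular resultant of the windowed angular amplitude);
  other variants integrate different radial bands and can score
  differently in absolute terms.
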