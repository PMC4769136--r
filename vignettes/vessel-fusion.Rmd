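---
title: "Fusing vessel-enhancement filters for unsupervised retinal segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing vessel-enhancement filters for unsupervised retinal segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinafuse)
```

## The problem and the model

Blood vessels in a color fundus photograph are thin, dark, curvilinear
structures on a bright, unevenly illuminated background, visible mostly in
the green channel. No single enhancement filter captures them reliably:
the oriented matched filter responds strongly to straight mid-width
segments, Hessian-eigenvalue vesselness is robust to noise but attenuates
junctions, and the Gabor wavelet transform picks up the thinnest vessels
at the cost of background texture. This package implements an
unsupervised segmentation system built on the observation that these
responses are *complementary*: fusing them beats each one alone.

Processing runs in three stages.

1. **Preprocessing.** The green channel is extracted and
   contrast-stretched to $[0,1]$ by the affine map
   $p_{\mathrm{out}} = (p-\beta_1)(\alpha_2-\alpha_1)/(\beta_2-\beta_1)+\alpha_1$,
   where $\beta_1,\beta_2$ are the extreme intensities *inside the field
   of view* (FOV). Using FOV-only extremes is a deliberate choice: the
   black frame outside the FOV would otherwise dominate the range and
   flatten the stretch. All downstream statistics, thresholds and scores
   are FOV-restricted for the same reason.

2. **Enhancement and fusion.** Three filters (tags `MF`, `FR`, `GW`),
   plus optionally the inverted normalized image itself (`IN`), produce
   responses min–max normalized over the FOV with vessels bright. Two
   fusion rules are provided:
   * *Weighted mean*: $F = 1 - \sum_k g_k w_k$ with non-negative weights
     summing to one. The inversion is kept, so weighted-mean fusions
     carry vessels **dark**; the convexity keeps $F \in [0,1]$. Weights
     are learned by a genetic algorithm whose fitness is
     $f = 1 - \frac{1}{M}\sum_i \mathrm{ACC}_i$, where each candidate's
     fused training images are segmented by Otsu's threshold and scored
     against ground truth.
   * *Median ranking*: each response is converted to a rank map (FOV
     pixels ranked by intensity, highest intensity = rank `top`, ties
     averaged) and the per-pixel median of the rank maps is renormalized.
     Ranks discard the incompatible score scales of the three filters,
     which is exactly the regime (Pearson correlations well below 1,
     see `pearson_matrix()`) where score averaging is unreliable.

3. **Segmentation and post-processing.** Median-ranking fusions are cut
   by a global threshold learned by the same GA machinery; weighted-mean
   fusions are segmented either by fuzzy C-means on the 1-D intensity
   feature or by an oriented region-scalable-fitting (ORSF) level set.
   Finally every 8-connected blob with isoperimetric elongation
   $E = P^2/(4\pi a) < l$ is discarded ($E$ is 1 for a disc and large
   for elongated structures).

## Filter parameters

The fusion architecture does not prescribe the filters' internal
parameters, so the defaults follow the classical operating points of each
method and remain configurable through `enhance(..., params = )`:

| filter | parameter | default | meaning |
|---|---|---|---|
| MF | `sigma` | 2 px | Gaussian cross-profile scale |
| MF | `delta` | 9 px | template length along the vessel |
| MF | `step_deg` | 15° | orientation spacing (12 kernels) |
| FR | `scales` | 1–3 px (step 0.5) | Hessian smoothing scales |
| FR | `beta` | 0.5 | blob-suppression sensitivity |
| FR | `c` | half max Hessian norm | structure-ness sensitivity |
| GW | `scales` | 2–5 px | wavelet dilations |
| GW | `elongation` | 4 | envelope axis ratio |
| GW | `step_deg` | 10° | orientation spacing |

The matched-filter kernels are zero-mean over their support, making the
response invariant to constant offsets. Vesselness selects the dark-ridge
eigenvalue sign ($\lambda_2 > 0$ on the raw green channel) and uses
scale-normalized ($s^2$-weighted) second derivatives. The Gabor wavelet
is corrected to exact zero mean so a constant image yields a zero
response; its modulus is maximized over orientations and scales, and the
large elongated stencils are correlated in the Fourier domain.

## The oriented region-scalable fitting level set

The ORSF energy is
$$\xi(C,f_1,f_2)=\sum_{i=1}^{2}\lambda_i\int\Big(\int_{\Omega_i}
K(x-y)\,|I(y)-f_i(x)|^2\,dy\Big)dx+\nu|C|,$$
with $\Omega_1$/$\Omega_2$ the outside/inside of the contour $C$ (the
zero level of $\phi$, interior $\phi>0$) and $f_1,f_2$ kernel-weighted
local intensity fits. The isotropic Gaussian window of the classical
model is replaced by a bank of rotated anisotropic windows (support
$|u|\le 3\sigma$, $|v|\le \delta/2$, 12 orientations at 15° steps), each
mass-normalized so $f_1,f_2$ stay proper weighted means. Each pixel uses
the orientation whose window yields the maximal smoothing response on the
vessel-bright input; this orientation map is computed once per evolution,
which both matches the "retain the maximum response" rule of the
underlying filter model and keeps one iteration at a single
selected-kernel convolution set. The gradient at a pixel applies its own
selected window to the neighboring fits — the standard localization
approximation for smoothly varying orientation fields.

Numerical choices, all exposed in `orsf_config()`:

* intensities are mapped to 0–255 inside the evolution; the published
  operating points $\lambda_1=\lambda_2=3$ (or 2) and $\nu=130$ are
  meaningful on that scale;
* regularized Heaviside/Dirac of width $\varepsilon=1.5$, explicit time
  step 0.1, distance regularization $\mu (\nabla^2\phi - \kappa)$ with
  $\mu=1$ (stable since $\mu\,\Delta t < 0.25$);
* window scale `sigma = 3` px — the standard kernel scale of the
  region-scalable-fitting literature; smaller windows make the local fits
  track background noise and speckle the partition — and window length
  `delta = 9` px, the matched-filter template length;
* binary-step initialization $\phi = \pm 2$ on the 1-px-dilated skeleton
  of the Otsu segmentation of the input. The published system used an
  external centerline detector here; skeleton-of-Otsu is our
  deterministic, unsupervised stand-in with the same centerline
  character;
* stop when the fraction of sign-changed pixels per iteration falls
  below `convergence_tol` ($10^{-4}$) or after `max_iter` (300)
  iterations.

Two cautions, verified by the test suite. First, the energy descends
reliably only for small explicit steps; the default 0.1 trades strict
monotonicity for speed, as is customary. Second, the length penalty
$\nu$ controls boundary smoothness, *not* vessel area: on noisy
phantoms, raising $\nu$ lowers the boundary density (perimeter per unit
area) and removes speckle components, but can fatten thin strips, so
area itself is not monotone in $\nu$.

## Other open choices

* **Otsu**: 256 uniform bins on the FOV histogram. When the two modes
  are separated by empty bins every cut in the gap maximizes the
  between-class variance; the middle cut is returned.
* **FCM**: fuzziness $m=2$, deterministic centroid initialization at the
  FOV intensity quantiles $k/(c+1)$, $c=2$ clusters by default; the
  darkest cluster is the vessel class for weighted-mean fusions, the
  brightest otherwise.
* **Rank ties** share the mean of their covered positions; the median of
  an even number of rank maps is the mean of the two middle values.
* **`IN` fusion input**: the contrast-stretched image carries vessels
  dark, while the fused combination expects bright-vessel inputs; `IN`
  is therefore the *inverted* stretched image. On structure-free
  synthetic backgrounds `IN` separates classes so well that the GA loads
  it heavily, which does not transfer to clinical material; the default
  fusion subset is consequently `MF`,`FR`,`GW`.
* **MCC** uses the product form $TP \cdot TN - FP \cdot FN$ in the
  numerator with the zero-denominator convention MCC $=0$.
* **CAL**: 8-connected component counts; dilations use strict Euclidean
  disc structuring elements (radius 2 by default); the skeleton is
  Zhang–Suen thinning, pinned by a golden-fixture test because the
  length factor depends on the skeletonization choice.
* **Elongation post-filter**: crack-boundary perimeter (count of exposed
  pixel edges) over 8-connected blobs; default threshold $l=2$, and
  $l=3$ after ORSF, the two published operating points.
* **Genetic algorithm**: real-coded, population 50, tournament selection
  (size 3), blend crossover (rate 0.9), Gaussian mutation (rate 0.1,
  sd 0.1), elitism of one, simplex projection by clipping and
  renormalization, stop after 50 non-improving generations (cap 500).
  Seeded and bit-reproducible; the global RNG stream is left untouched.

## The synthetic phantom

`generate_phantom()` emulates the image properties the pipeline relies
on: a circular FOV (radius 0.48 of the frame), a bright background
(level 0.7) with mild radial shading (amplitude 0.1, brighter center)
emulating illumination nonuniformity, and dark vessels rendered as
smooth random-walk centerlines with Gaussian cross-profiles; ground
truth is the half-maximum support of the noise-free ridge. Defaults —
300×300 frame, six vessels of width 2–6 px, contrast 0.5, additive
Gaussian noise 0.05 — model a DRIVE-like acquisition scaled down from
its 540-px FOV; training runs in the tests and the acceptance script use
160×160 phantoms to keep the whole suite inside a few CPU-minutes.

What the phantom does *not* model: the optic disc and macula, pathology
(exudates, hemorrhages), vessel branching and crossing statistics,
width-dependent contrast, and camera vignetting beyond radial shading.
Passing phantom tests therefore demonstrates the machinery — filters,
fusion, optimization, segmentation, scoring — not clinical-grade
accuracy; on real databases the published weights differ (matched filter
dominant) and raw intensity is far less informative than on a
structure-free background. One measured consequence of the phantom's
Gaussian profiles: a plain Otsu cut on the noiseless inverted green
channel scores ACC ≈ 0.987 rather than 1.0, because the half-maximum
truth boundary band sits in the profile tail; an ideal global threshold
reaches ≈ 0.996.

## Worked example

```{r example, eval = FALSE}
train <- lapply(1:3, function(i)
  generate_phantom(phantom_spec(size = c(160, 160), rng_seed = 30 + i)))
test  <- generate_phantom(phantom_spec(rng_seed = 1))

cfg <- train_pipeline(train, cfg = pipeline_config(
  "median_ranking", filters = c("MF", "FR", "GW"),
  ga = ga_config(rng_seed = 1)))
res <- run_pipeline(test, cfg = cfg)
res$metrics
```

The analogous weighted-mean variants are `"weighted_mean_fcm"` and
`"weighted_mean_orsf"`; `scripts/acceptance.R` in the source repository
runs all three end to end and writes the scores as JSON.

## Known limitations

* The ORSF evolution is a local optimizer; with the published
  $\lambda,\nu$ the result depends on the initialization quality, and
  badly mixed fusion inputs (e.g. a noise-dominated weighted mean) can
  make the local fits chase noise.
* GIF rasters are not decodable; PNG, TIFF and PPM/PGM are.
* Weight learning uses Otsu inside the fitness loop even when the final
  segmentation is FCM or ORSF — the design of the original system — so
  the learned weights are optimal for thresholding, only empirically
  good for the other segmenters.
* On fitness plateaus (e.g. a perfectly separable training set) the GA
  returns an arbitrary point of the optimal region; only dominance of
  the informative input, not its exact weight, is guaranteed.
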