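---
title: "Convolution comparison patterns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolution comparison patterns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind the package, the
choices that had to be made where the procedure admits more than one
reasonable reading, and what the synthetic test bed does and does not show
about real fingerprint data.

## The descriptor

Fingerprint liveness detection asks whether an image presented to a sensor
was captured from living skin or from a replica (gelatin, wood glue,
silicone, ...). Materials leave their signature in the fine texture of the
ridge-valley pattern, so a texture descriptor that is insensitive to
nuisance geometry — where the finger touched the sensor, and at what angle —
but sensitive to local spectral content is a natural fit.

The convolution comparison pattern (CCP) descriptor encodes each foreground
pixel's neighborhood as a short binary word:

1. **Orientation normalization.** A per-pixel orientation field
   $\theta(x,y) \in [0^\circ, 180^\circ)$ is estimated by averaging squared
   Sobel gradients over a Gaussian-weighted $33\times 33$ window
   ($\sigma^2 = 10\,\mathrm{px}^2$). The $n\times n$ patch at a pixel
   (default $n = 9$) is resampled by bilinear interpolation so that the
   local ridge direction lies along the patch x-axis. Orientation is an
   axis, not a direction; the remaining $180^\circ$ ambiguity is neutralized
   in step 3.
2. **Spectral representation.** The orthonormal 2-D type-II DCT of the patch
   gives $n^2$ coefficients $d_i$, indexed row-major with the DC coefficient
   at $i = 1$.
3. **Normalized magnitudes.** With $a_i = |d_i|$ and pooled training moments
   $\bar a_i$, $\sigma_i$ (population variance over all training patches of
   both classes), the normalized coefficients are
   $c_i = (a_i - \bar a_i)/\sigma_i$. Using magnitudes makes the code
   invariant to the $180^\circ$ patch ambiguity, since a half-turn only
   flips coefficient signs.
4. **Learned comparisons.** A comparison is the indicator
   $q(i, j, \delta) = \mathbf 1\{(c_i + \delta) > c_j\}$ with $i \neq j$.
   The learning stage scores every ordered pair of distinct indices
   ($n^2(n^2-1) = 6480$ pairs for $n = 9$) at every offset $\delta$ on the
   grid $-1, -0.98, \dots, 1$, by the absolute difference of the event's
   relative frequency between live and spoof training patches, and keeps the
   top $G \cdot b$ pairs in rank order.
5. **Patterns and histograms.** Bits $x = 0, \dots, b-1$ of a patch's bin
   number $y = \sum_x 2^x q(i_x, j_x, \delta_x)$ come from rules
   $x+1, \dots$ of a rank block of $b$ rules. Each of the $G$ blocks yields
   a $2^b$-bin histogram over all eligible foreground pixels, normalized by
   the patch count so the descriptor does not depend on how much finger
   surface touched the sensor. The concatenated feature vector has length
   $G \cdot 2^b$: the layouts `1x8` and `4x6` give 256 features, `2x8` and
   `8x6` give 512.
6. **Classification.** Features are affinely rescaled to $[-1, 1]$ on the
   training range (constant features to 0, test values unclipped) and a
   linear SVM with $C = 1$ separates live ($y=1$) from spoof ($y=0$).
   Performance is reported as accuracy $a = D/N$, NPCER (live called spoof),
   APCER (spoof called live) and $\mathrm{HTER} = (\mathrm{NPCER} +
   \mathrm{APCER})/2$; on balanced test sets $a = 1 - \mathrm{HTER}$.

```{r}
library(ccp)
dir <- tempfile()
train <- synth_dataset(dir, n_live = 100, n_spoof = 100, seed = 1,
                       prefix = "tr")
test <- synth_dataset(dir, n_live = 100, n_spoof = 100, seed = 2,
                      prefix = "te")
fit <- ccp_fit(train, variant = "1x8", seed = 1)
liveness_metrics(predict(fit, test), test$label)
```

## Choices the procedure leaves open

Several details are under-determined by the usual description of this kind
of pipeline; the package fixes them as follows.

* **Angle convention.** $0^\circ$ is the x-axis and angles increase
  clockwise with the y-axis pointing down (raster convention). Orientation
  fields on disk use exactly this encoding, in degrees.
* **DCT normalization and indexing.** The transform is orthonormal, so
  Parseval's identity holds; any fixed rescaling would be absorbed by the
  coefficient normalization in step 3 anyway. The index map
  $i = u \cdot n + v + 1$ is recorded in every model file, because learned
  rule indices are only meaningful relative to it.
* **Ordered versus unordered pairs.** $(i, j)$ and $(j, i)$ are distinct
  candidates: with $\delta \neq 0$ the two events are not complements, so
  both may carry information. The uniqueness constraint on selected rules
  applies to ordered pairs.
* **Ties.** Strict inequality in $q$: exact ties contribute 0. Score ties
  during the search are broken toward the offset nearest 0 (negative before
  positive), then smaller $i$, then smaller $j$ — determinism across
  platforms matters more than which equally-scored rule wins.
* **Borders.** Gradient and window sums use reflective padding. Patch
  centers must be at least $\lceil n\sqrt2/2\rceil + 1$ pixels from every
  border so that any rotated footprint stays inside the image; patches are
  rejected, never padded, since padding would inject artificial spectra.
  "Every foreground pixel" therefore means every *eligible* foreground
  pixel.
* **Sampling.** The $p = 2000$ training centers per image are drawn
  uniformly *with replacement* from the eligible foreground. Per-image
  sampling seeds are drawn up-front from the global seed, so results do not
  depend on per-image patch counts and are exactly reproducible.
* **Degenerate inputs.** Zero-variance coefficient indices are excluded
  from the search; a constant image yields $\theta = 0$ with coherence 0
  and a message; an image with no eligible patches is an error, never a
  zero descriptor.
* **Scaling interaction.** Histograms are normalized per group first, and
  the SVM scaler is fitted on those normalized features — the only order
  consistent with a protocol that rescales final feature vectors.

## The synthetic test bed

Real liveness benchmarks (the LivDet series) are license-restricted, so the
package ships a generator of fingerprint-like images that reproduces exactly
the properties the descriptor exploits:

* an oriented ridge-valley texture, wavelength $\lambda = 8$ px (the typical
  4–12 px range), on a $128\times128$ canvas with a disk foreground of
  radius $0.4 \cdot \mathrm{size}$;
* a smooth, analytically known orientation field (a random base direction
  plus a quadratic phase distortion of roughly $\pm 15^\circ$; no singular
  points, which would violate the single-orientation assumption);
* two classes differing only in local spectral content: live images are a
  pure sinusoidal ridge profile with additive Gaussian noise
  ($\sigma = 8$ intensity levels), spoof images add 2nd and 3rd harmonics
  (weights 0.5 and 0.3) and extra noise ($\sigma = 12$), mimicking the
  material-texture differences between skin and replica. A single
  `contrast` multiplier scales these differences; `contrast = 0` makes the
  classes identically distributed and is the null control.

These sizes keep a full 200-train/200-test experiment with $p = 2000$
training patches per image within a couple of minutes on one core, while
exercising every stage at realistic patch counts (about 400,000 training
patches, about 8,000 descriptor patches per image).

What passing tests on this generator show: the orientation estimator
recovers a planted field to a couple of degrees; the exhaustive search finds
planted discriminative coefficient pairs; the full pipeline separates
classes whose spectra differ and collapses to chance when they do not; the
descriptor is insensitive to rotation and to foreground area. What they do
*not* show: robustness to sensor noise models, wet/dry fingers, skin
distortion, singular points (cores/deltas), segmentation failure on real
backgrounds, or the actual live/spoof separability of any real material —
those require real benchmark data.

## Numerical notes and limitations

* The DCT is computed as $C P C^\top$ with a precomputed orthonormal basis
  matrix — exact and fastest at $n = 9$; a brute-force $O(n^4)$ cosine sum
  serves as the independent oracle in the tests (agreement to $10^{-10}$).
* The exhaustive search bins the per-patch differences $c_j - c_i$ once per
  pair and reads all 101 offsets from the cumulative counts, making the
  full $6480 \times 101$ grid search over 400,000 patches a matter of
  seconds; an R triple-loop reference implementation is kept in the test
  suite and must agree exactly on small problems.
* Model files store floating-point values as `%.17g` strings so a reloaded
  model reproduces decisions bit for bit.
* Rotation invariance is interpolation-limited: descriptors of an image and
  its 30°-rotated copy agree to L1 distance well below 0.05, but individual
  near-zero DCT coefficients of noiseless textures are dominated by
  interpolation error — comparisons are only meaningful between
  coefficients with genuine variance, which is what the learned search
  selects.
* The fallback segmentation (block-variance Otsu with a homogeneity guard)
  is intended for flat backgrounds such as the generator's; real sensor
  backgrounds warrant an externally computed mask, passed via the manifest's
  `mask` column.
* Learned rule indices are tied to this package's DCT index layout and are
  not comparable across layouts; the layout tag travels with the model file.
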