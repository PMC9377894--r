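---
title: "Confidence-region contour detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-region contour detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enhancing brain tumours on MRI have bright cores whose boundary intensities
blend gradually into normal tissue, so a single global threshold either
misses the faint growing rim or swallows surrounding brain. `crcd`
implements a region-extraction pipeline that addresses this by combining
evidence across slices and then refining the region with two complementary
mechanisms: a region-scalable-fitting (RSF) level set for the boundary, and
a confidence-interval transform of pixel intensities for the region
interior.

The pipeline, as run by `crcd()`, is:

1. **Intensity adjustment.** Each slice is passed through a linear window
   stretch `clip(alpha * x + beta, 0, 1)` with `alpha = 1/(high_in -
   low_in)`, `beta = -low_in * alpha`. The default window (0.36, 0.78) is
   where enhancing-tumour intensities concentrate on T1-weighted
   acquisitions; everything below the window is crushed to 0, which is what
   makes the tumour separable from normal tissue by a histogram threshold.
2. **Biggest blob per slice.** The adjusted slice is binarized (Otsu by
   default), 8-connected components are labelled in raster order, and the
   maximal-area component — the biggest blob — is kept as the slice's tumour
   candidate.
3. **Pattern fusion.** Consecutive slices with similar tumour appearance
   form a *pattern* (user-supplied ranges; the phantom uses two groups of
   5). Per pattern, the slice blobs are unioned; the per-pattern blobs are
   then unioned into the *resultant blob*, each pattern keeping a
   provenance colour in an RGB overlay. The resultant blob's pixel count is
   the *confidence score*.
4. **RSF contour.** A level set initialized at the resultant blob's
   bounding box evolves under the region-scalable fitting energy to settle
   on the tumour boundary.
5. **Confidence region.** The score image is remapped with a per-quadrant
   ±1.96σ confidence interval, optionally Haar-smoothed, classified by
   multi-level Otsu, and the top intensity class inside a dilation of the
   resultant blob becomes the final mask.

Stages 2–5 operate in a single 2-D plane: slices are assumed co-registered
(true of BraTS-style data), and fusion is a pixelwise union, not a 3-D
merge. The image that the contour and confidence stages see is the
pixelwise **maximum of the adjusted slices** — the brightest evidence for
tumour at each pixel across the stack. This is the natural 2-D companion of
the union mask: a pixel belongs to the resultant blob if it was bright on
*some* slice, and the projection records exactly how bright.

## The RSF level set

The contour is the zero crossing of a signed function $\varphi$, negative
inside. With the smoothed Heaviside
$H_\varepsilon(t) = \tfrac12\big(1 + \tfrac{2}{\pi}\arctan(t/\varepsilon)\big)$
and inside indicator $M_{in} = H_\varepsilon(-\varphi)$, the fitted means

$$f_{in} = \frac{K * (M_{in} I)}{K * M_{in}}, \qquad
  f_{out} = \frac{K * ((1 - M_{in}) I)}{K * (1 - M_{in})}$$

localise the intensity on either side of the contour through a Gaussian
kernel $K$ (13×13, σ = 3 by default; convolution uses reflected-boundary
padding, so $K * 1 = 1$ and constant images are fixed points). The energy is
the kernel-weighted squared residual of each pixel against the local fitted
mean of its side, plus ν times the contour-length surrogate
$\sum \delta_\varepsilon(\varphi)\,|\nabla\varphi|$. Gradient descent gives
the update

$$\varphi \leftarrow \varphi + \Delta t\,\Big[
  \delta_\varepsilon(\varphi)\,(\lambda_{in} e_{in} - \lambda_{out} e_{out})
  + \nu\,\delta_\varepsilon(\varphi)\,\kappa(\varphi)
  + \mu\,(\nabla^2\varphi - \kappa(\varphi)) \Big]$$

with curvature $\kappa = \mathrm{div}(\nabla\varphi/|\nabla\varphi|)$. The
sign of the data force follows from descending the energy with the
inside-negative convention: where a pixel fits the inside statistics better
($e_{in} < e_{out}$), $\varphi$ decreases. The last term is the standard
distance regularization, which removes the need to re-initialize $\varphi$
to a signed distance function.

Numerical choices:

* **Intensity scale.** The data residuals are evaluated on intensities
  mapped to 0–255, the scale the conventional default ν = 0.003·255² is
  calibrated to; package images stay in [0, 1] everywhere else. (The
  exported `rsf_fitted_means()` works in input units, as its contracts
  require.)
* **Stability.** Explicit Euler with Δt = 0.1 and μ = 1 satisfies the
  diffusion stability bound (μΔt < 1/4). Fitted-mean denominators are
  floored at 1e-10; non-finite φ mid-run raises a divergence error naming
  the iteration.
* **Cropping.** Evolution runs on the slice restricted to a margin of twice
  the kernel radius around the interior region and is pasted back, which
  keeps 300–500 iterations of a 128×128 slice to a couple of seconds
  without changing the result (forces decay with the kernel).
* **Contour convention.** The extracted contour is the set of interior
  pixels (φ < 0) with a non-negative 4-neighbour — the inner boundary ring.
  At initialization the contour is the bounding-box perimeter by
  construction.
* **Iterations.** Default 300; the inner and outer intensities of a
  well-contrasted tumour separate within a few hundred steps, and the
  energy trace (recorded every 10 iterations) lets users confirm
  convergence.

## The confidence-interval transform

The transform sharpens the score image before classification. The
whole-image population standard deviation σ is combined with four local
(quadrant) means $\bar a_q$; the image is split at `floor(n/2)` in each
dimension, with odd remainders going to the bottom/right. Around each
quadrant mean the interval $[A1_q, A2_q] = [\bar a_q - 1.96\sigma,\ \bar a_q
+ 1.96\sigma]$ is the two-sided 95% normal band (`z` is adjustable). Each
pixel $p$ is then remapped by a three-band rule:

* $p \ge \bar a_q$: kept unchanged (already tumour-bright for its region);
* $A1_q \le p < \bar a_q$: brightened to $\min(1, p + \bar a_q)$ — these
  are the ambiguous "growing region" intensities the interval is meant to
  recover;
* $p < A1_q$: assigned the quadrant mean (background flattened to a common
  level).

The rule uses the lower bound $A1$ as the boundary between *brighten* and
*flatten*; the upper bound $A2$ is not a remap boundary — above-mean pixels
are kept regardless — because brightening already-bright pixels would only
saturate them. The remap never decreases a pixel below `min(p, mean)`, is
idempotent on above-mean pixels, and stays in [0, 1].

A single Haar level (2×2 block means, details zeroed; edge padding for odd
dimensions) smooths speckle before multi-level Otsu (default 3 classes:
background, normal tissue, tumour; thresholds maximize between-class
variance by exhaustive search over the 256-bin histogram, first maximizer
on ties). The final mask is the top class intersected with a disc dilation
(radius = kernel radius, 6 px) of the resultant blob: the multi-Otsu
decides *what is tumour-bright*, the blob constraint decides *where the
tumour is*, and an empty blob yields an empty mask.

Two ambiguities were resolved as design choices: the remap's middle band is
anchored at $A1$ (the only other threshold the interval defines), and the
transform is applied to the adjusted score projection restricted by the
blob — not to the raw slice — since the score image is what the preceding
stages produce.

## The synthetic phantom

`make_phantom()` generates the study conditions every end-to-end test runs
under: a 10-slice stack of 128×128 slices mimicking the tumour-visible
portion of an axial acquisition (source numbers 65–74, two pattern groups
65–69 and 70–74). Each slice holds a dark background (0.05), an elliptical
"brain" of tissue intensity 0.45, and a tumour disc of core intensity 0.85
and radius 15 px with a 3 px rim falling linearly to the tissue level — a
thin enhancing rim relative to the core, as in contrast-enhanced T1.
The tumour centre drifts 1 px per slice, along the columns in the first
group and along the rows in the second; the direction flip makes the fused
resultant blob a strict superset of every single-slice blob, so fusion is
exercised meaningfully. Additive Gaussian noise (σ = 0.02, clipped to
[0, 1]) is seeded and restores the caller's RNG state, making volumes
bit-reproducible. The per-slice truth mask is the disc plus rim
(radius 18 px).

Because the fusion plane is 2-D, the reference for the final mask is the
**union of the per-slice truth discs** (`phantom_truth_union()`).

What the phantom does *not* emulate: Rician noise statistics, bias fields,
skull and CSF anatomy, partial-volume rims wider than a few pixels, and
multi-sequence (flair/T1/T2/T1CE) contrast differences. Passing tests
therefore demonstrate the pipeline's correctness and its behaviour under
controlled drift and noise, not clinical-grade accuracy on real BraTS
volumes.

The default problem sizes used throughout the tests — 128×128 slices,
100×100 disc images for the level-set checks, 16×16 masks for the labelling
oracles — are the package's chosen balance between covering realistic
geometry and keeping the whole validation suite quick to run on one core.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `low_in`, `high_in` | 0.36, 0.78 | normalized intensity | enhancing-tumour window on T1; below-window tissue maps to 0 |
| `threshold` | `"auto"` (Otsu) | intensity | deterministic, parameter-free, suits the bimodal adjusted histogram |
| `connectivity` | 8 | — | diagonal contact counts when growing blobs |
| `kernel_size`, `kernel_sigma` | 13, 3 | px | locality of the RSF fitted means |
| `nu` | 0.003·255² | intensity² | contour-length penalty on the 0–255 data scale |
| `mu`, `timestep` | 1, 0.1 | — | distance regularization within the explicit-Euler stability bound |
| `iterations` | 300 | — | boundary separation needs a few hundred steps |
| `z` | 1.96 | σ units | two-sided 95% normal interval |
| `classes` | 3 | — | background / tissue / tumour |
| `dilate_radius` | 6 | px | lets the confidence mask extend one kernel radius past the blob |

## Known limitations

* Pattern membership is user-supplied; no automatic pattern discovery is
  performed (slice ranges are typically chosen by visual inspection).
* Fusion assumes co-registered slices; there is no inter-slice
  registration, and fusion is 2-D by design.
* The Otsu-based binarization assumes the adjusted slice is effectively
  bimodal; tumours darker than the adjustment window are invisible to the
  pipeline.
* Evaluation metrics treat masks canonically (MSE/PSNR on 0/1 images at
  peak 1 by default); no surface-distance metrics are provided.

## A worked miniature

`make_worked_example()` ships an 8×8 slice with every intermediate frozen
from independent brute-force computations (flood fill, coordinate scans,
direct arithmetic): binarize at 0.5 → three components of areas 9, 4, 1
labelled in raster order → biggest blob of area 9 → quadrant means (0.55,
0.1375, 0.11875, 0.275), σ ≈ 0.3131, the ±1.96σ bounds, the remapped
image, and Dice = 18/21 against a 12-px truth block. It is both a test
fixture and the quickest way to see each stage's contract on paper.
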