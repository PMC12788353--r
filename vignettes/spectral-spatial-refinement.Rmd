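---
title: "Spectral-spatial refinement: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-spatial refinement: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsirefine)
```

## The model and its assumptions

`hsirefine` classifies a hyperspectral cube `I` of shape `M x N x D` into
`K` land-cover classes from a small labeled sample. The pipeline has two
stages with very different statistical character:

1. **A supervised pixel-wise seed.** Spectra are reduced by principal
   components and a kernel classifier produces per-pixel probabilities
   `P_i(k)` over the training classes. This stage sees labels but no
   spatial context, so its maps are speckled wherever classes overlap
   spectrally.
2. **An unsupervised neighborhood refinement.** The conditional
   distribution of the final label given the seed map is factorized over
   each pixel's neighborhood (conditional independence of neighbors given
   the reference pixel), potentials are written as `exp(-E)`, and the
   energy couples three signals per neighbor `j` of pixel `i`: the
   neighbor's class probability `P_j(k)`, a Gaussian **spatial nearness**
   weight `S_ij`, a Gaussian **spectral similarity** weight `W_ij`, and a
   label-agreement indicator `I(k, w_j) = +1/-1`. Iterated conditional
   modes (ICM) minimizes the energy pixel by pixel; a softmax of the
   negated energies refreshes the probabilities; the outer loop repeats
   to convergence.

The key assumption is local: nearby pixels that are also spectrally
similar tend to share a class. Nothing global is estimated, which is why
the refinement parameters transfer across sensors and scenes while only
the seed classifier needs per-scene attention.

## The two potential forms

The published description of the energy is algebraically inconsistent
between its three equation variants (a sign flips on the spatial term and
the leading minus is dropped when the trade-off is re-parameterized), so
the package implements both readings and names the choice explicitly:

* `potential_form = "eq11_grouped"` (default):
  `E_i(k) = -sum_j [(1-b) W_ij P_j(k) + b (S_ij P_j(k) + I(k, w_j))]`.
  The indicator sits inside the spatially weighted group; total support is
  negated so that the ICM rule "pick the lowest energy" selects the
  best-supported class, consistent with the stated reward/penalize
  behavior.
* `potential_form = "eq9"`:
  `E_i(k) = -sum_j [(1-b)(W_ij + S_ij) P_j(k) + b I(k, w_j)]`,
  the un-grouped variant.

Both forms share every fixed point with constant-label one-hot scenes and
both are exercised by the oracle-equivalence tests; the default is the
grouped form because it keeps the spatial kernel attached to both the
probability and the agreement signal.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `r` | neighborhood radius (pixels) | 4 | window `(2r+1)^2`; larger values over-smooth field boundaries, smaller ones leave speckle |
| `sigma_s` | spatial kernel width (pixel offsets) | 1.3 | operates on raw pixel offsets, not offsets normalized by `r` |
| `sigma_w` | spectral kernel width | 1.3 | on min-max normalized PCA scores, so one width fits all components |
| `beta` | spatial/spectral trade-off, `[0, 1]` | 0.4 | `beta = 0` is pure spectral support |
| `epsilon` | convergence threshold | `1e-4` | absolute, on the summed L1 probability change per outer iteration |
| `max_outer` | outer iteration cap | 20 | non-convergence is reported, never raised |
| `evr_threshold` | explained-variance target | 0.92 | the smallest `d` reaching it is retained |
| `d_cap` | component cap | 18 | classifier accuracy plateaus before the variance curve does |
| `C`, `gamma` | classifier cost and RBF width | 32, 7 | the only scene-specific knobs; 5-fold grid search available |
| `fraction`, `min_per_class` | sampling rule | 0.1, 10 | per class: `min(max(ceil(f*n_c), min), floor(n_c/2))`, small classes split in half |

The defaults `r = 4`, `sigma_w = sigma_s = 1.3`, `beta = 0.4`, `gamma = 7`
form the fixed transfer set: `transfer_run()` refuses any attempt to
change them and re-tunes only `C` (optionally `gamma`).

## The seed classifier backend

The runtime this package targets ships no SVM implementation, so the seed
stage realizes the decision function `argmax_k w_k' Phi(z) + b_k` as
RBF-kernel multinomial logistic regression: the feature map is the kernel
expansion against the training pixels and the weights are fit by
ridge-penalized multinomial regression (`glmnet`), with the familiar cost
semantics `lambda = 1/(C n)`. This keeps the published contract — `C` and
`gamma` with grid search under 5-fold cross-validated accuracy — and
yields naturally normalized probability rows, which is the only property
the refinement consumes. Any other producer of softmax probabilities
(random forest, CNN) can be substituted through `probability_map()`.

## What the synthetic scenes emulate (and what they don't)

`make_scene()` draws per-class reflectance signatures as low-order random
cosine mixtures (smooth across bands, as real reflectance spectra are),
lays classes out as contiguous strips or Voronoi cells, adds independent
per-band Gaussian noise, optionally mixes spectra linearly along region
boundaries, scatters an exact fraction of background pixels, and can
append open-set classes excluded from training. Signatures are rescaled so
the minimum pairwise distance is `class_separation * noise_sd` (with a
floor of 0.01 reflectance units when `noise_sd = 0`): at the default
separation of 10 noise-SDs, nearest-signature classification of interior
pixels is essentially error-free by construction, so seed-classifier
failures in tests indicate bugs, not hard data.

Deliberately **not** modeled: sensor point-spread functions and striping,
wavelength-dependent SNR, atmospheric residuals, within-class biological
variability and phenology, and spatially correlated noise. A green
denoising test therefore establishes that the refinement recovers
spatially coherent labels from a corrupted seed under honest noise — not
that benchmark-scale accuracies are reproduced. The published headline
accuracies depend on external benchmark downloads and unspecified
sampling details, and are documented as an external validation mode
rather than asserted by this suite.

## Numerical choices

* **Softmax stabilization:** probabilities are computed as
  `exp(-(E - min_k E))` before normalization, so energies of any
  magnitude cannot overflow. On homogeneous one-hot scenes the wrong-class
  exponentials underflow to numerical zero and the scene is an exact
  fixed point (delta `0` at the first outer iteration).
* **Sweep order:** raster order with in-place (Gauss–Seidel) label
  updates; the published description fixes no order. Energy ties break
  toward the smallest class id, making sweeps fully deterministic.
* **Probabilities inside the energy** are the current outer iteration's
  map (the seed at iteration 0), since convergence is tracked on the
  probability map across iterations.
* **Boundary handling:** symmetric reflection with edge duplication
  (`[a,b,c]` padded by 2 gives `[b,a,a,b,c,c,b]`), applied identically to
  the feature raster (for `W`) and to neighbor label/probability lookups,
  so border energies equal an oracle that reflects indices explicitly.
* **Background pixels** (label 0) are excluded from every neighborhood
  sum, never updated, and never imputed.
* **Convergence norm:** L1 over classes summed over non-background
  pixels, compared to an absolute `epsilon`.
* **Degenerate inputs:** constant bands min-max normalize to 0; an
  all-background label map yields an empty pixel table; `kappa` with unit
  chance agreement is reported as `NA` with a warning rather than
  propagated as `NaN`.

## Design decisions where the design was open

* **Coordinates** are 1-based `(row, col)` — idiomatic R — while band
  indices stay 1-based to match published water-absorption band lists
  verbatim. The printed 224-band exclusion lists each remove 20 bands;
  the conventional "200 of 224" variant is shipped as the separate preset
  `indian_pines_full`, and the reader reports retained counts instead of
  asserting a total.
* **Order of preprocessing:** band exclusion, then per-band min-max
  normalization (excluding a band after normalization would leave the
  remaining bands' scales untouched anyway, but excluding first avoids
  normalizing data that is about to be discarded).
* **Projection fit** is transductive — on all non-background pixels of
  the scene, not just training pixels — matching the pixel-wise mapping
  of the whole image; pass a training-only table to `fit_projection()`
  to opt out.
* **Spectral features in `W`** are the PCA-reduced, per-component
  min-max normalized scores; raw normalized spectra can be supplied to
  `kernel_stack()` instead.
* **`sigma_s` acts on raw pixel offsets** (not offsets normalized by
  `r`); with min-max normalized features both kernel widths are then
  resolution-comparable across scenes.
* **Ensemble subsets are subsets of bands**, not of samples: each of the
  4 random disjoint band groups runs the full pipeline (own PCA, seed,
  refinement) and the maps are majority-voted with probability-based tie
  breaks. Splitting the tiny training sample instead would starve rare
  classes under 1% labels.
* **Known training labels are clamped** during sweeps when provided
  (weak supervision); `clamp = FALSE` disables this.
* **Run configuration files are JSON** (`jsonlite`), not YAML: the
  guaranteed runtime package set includes a JSON parser but no YAML
  parser, and the config is machine-written anyway.
* **Serialization** of projections, cubes and models uses R's native RDS
  as the "portable archive" format; ENVI and MAT v5 cover interchange
  with other toolchains.
* A **synchronous (Jacobi) sweep** variant — suggested by a literal
  reading of "the variables remain unchanged during this time" — is not
  implemented; the sequential ICM reading is standard and is the one the
  convergence behavior of the method relies on.

## Known limitations

* ICM is a coordinate-descent heuristic: it converges to a local optimum
  that depends on the sweep order, and on scenes whose seed is badly
  wrong in large contiguous blocks it will confidently keep the wrong
  label (the agreement indicator rewards consensus, right or wrong).
* Spectrally near-identical classes (same crop, different tillage) are
  separated only insofar as the seed separates them; the refinement adds
  spatial coherence, not new spectral evidence.
* Scenes are processed in memory; tiling for very large rasters is out
  of scope.
* The MAT reader covers real numeric arrays (the benchmark layout), not
  structs, cells, sparse or complex data.
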