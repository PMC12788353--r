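# hsirefine

Weakly supervised spectral–spatial refinement for hyperspectral land-cover
and crop classification.

## The problem

Hyperspectral sensors deliver hundreds of narrow reflectance bands per
pixel, enough to discriminate crop types, tillage practice and land cover —
but labeled ground truth is scarce and expensive, and a pixel-wise
(spectral-only) classifier trained on 1–10% of the pixels produces noisy,
fragmented maps. `hsirefine` implements a lightweight pipeline for exactly
this regime: a probabilistic seed classifier trained on a small stratified
sample, followed by an iterative unsupervised refinement that trades off
**spectral similarity** against **spatial nearness** inside each pixel's
neighborhood. The refinement parameters transfer across scenes unchanged,
so only the classifier cost needs re-tuning on a new image.

## The model

Pixels are projected onto the leading principal components (retaining a
cumulative explained-variance ratio of 0.92, capped at 18 components). A
kernel classifier on the reduced spectra yields per-pixel class
probabilities `P_i(k)` that seed the refinement. For each pixel `i` and
each neighbor `j` in a `(2r+1) x (2r+1)` window (`j != i`), two Gaussian
kernels weight the interaction:

    S_ij = exp(-||j - i||^2 / (2 sigma_s^2))        spatial nearness
    W_ij = exp(-||f_i - f_j||^2 / (2 sigma_w^2))    spectral similarity

with `f` the min-max normalized component scores. The energy of assigning
class `k` to pixel `i` (default potential form) is

    E_i(k) = - sum_j [ (1-beta) W_ij P_j(k) + beta ( S_ij P_j(k) + I(k, w_j) ) ]

where `I(k, w_j)` is `+1` if neighbor `j` currently carries label `k` and
`-1` otherwise, and `beta` in `[0, 1]` balances the spectral and spatial
terms. An iterated-conditional-modes sweep assigns each pixel (in raster
order, with in-place updates) to its minimum-energy class; probabilities
are then refreshed by a stabilized softmax `P_i(k) ∝ exp(-E_i(k))`; the
outer loop repeats until the summed L1 probability change falls below
`epsilon` (default `1e-4`). Mirror padding gives border pixels full
neighborhoods. Performance is reported as overall accuracy (OA), average
accuracy (AA) and Cohen's kappa on held-out pixels.

The fixed cross-scene transfer set is `r = 4`,
`sigma_w = sigma_s = 1.3`, `beta = 0.4` (and classifier `gamma = 7`);
`transfer_run()` enforces it. Optional extras: band-subset ensemble voting
(4 disjoint random band groups, majority vote) and weak-label feedback
(the refined map re-enters as the seed).

## Worked example

Simulate a 60 x 60 scene with 50 bands, 4 classes, 20% unlabeled
background and mixed boundary pixels; train on 10% of the labeled pixels;
refine with the transfer parameter set:

```r
library(hsirefine)
spec <- scene_spec(M = 60, N = 60, D = 50, K = 4, background_fraction = 0.2,
                   mixed_boundary_width = 1, seed = 501)
cfg <- run_config(scene = spec, C = 32, gamma = 7, fraction = 0.1, seed = 1)
res <- run_pipeline(cfg)
print(res$seed_eval)     # spectral-only baseline
print(res$refined_eval)  # after refinement
print(res$state)
```

Output:

```
EvalReport (2590 pixels): OA 95.37%  AA 95.38%  kappa 0.9382
  class 1: 94.53%
  class 2: 97.85%
  class 3: 90.84%
  class 4: 98.29%
EvalReport (2590 pixels): OA 96.80%  AA 96.80%  kappa 0.9573
  class 1: 96.72%
  class 2: 98.31%
  class 3: 94.96%
  class 4: 97.20%
RefineState: 19 outer iteration(s), converged (last delta 5.62e-05)
```

The seed classifier already separates the synthetic classes well (they are
drawn 10 noise-SDs apart); refinement removes the remaining speckle —
most of the gain concentrates in the weakest class (class 3, 90.8% →
95.0%) whose errors sit along mixed boundaries. Against real benchmark
scenes the same mechanism is what lifts a noisy spectral-only map by
several OA points.

Real rasters load the same way: `read_cube()` accepts ENVI (`.hdr` +
binary, BSQ/BIL/BIP), MAT v5 containers as distributed for the classic
airborne benchmarks, and RDS archives; `band_exclusion_preset()` carries
the published water-absorption band lists.

## Command line

```sh
Rscript inst/scripts/hsi run --config cfg.json --out outdir
Rscript inst/scripts/hsi transfer --config cfg.json
Rscript inst/scripts/hsi evaluate --truth gt.dat --pred map.dat
```

`cfg.json` mirrors the `run_config()` arguments (nested `scene` /
`refine` objects allowed). Every run writes the seed and refined maps
(ENVI integer rasters), per-iteration convergence deltas, a JSON metrics
report and a JSON record of all effective parameters.

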