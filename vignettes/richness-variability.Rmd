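---
title: "Richness and variability of convolutional filter responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Richness and variability of convolutional filter responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richvar)
```

## The model

A recurring observation in computational aesthetics is that traditional
visual artworks, across cultures, tend to combine two statistical
properties: their subregions are *filled* with pictorial structure to which
many diverse low-level visual filters respond (**richness**), and the
responses of individual filters *vary* considerably from one subregion to
the next (**variability**), unlike the monotonous repetition seen in plant
patterns or vegetation. `richvar` implements a variance-based feature
family that quantifies both properties from the responses of a
convolution-only filter bank, together with the classification protocol
used to test how well those features discriminate art-like from non-art
images.

The pipeline is:

1. An RGB image is rescaled to a square input (512 px by default, bilinear,
   no cropping) and passed through a bank of first-layer convolutional
   filters — oriented luminance edges and opponent-color gradients. The
   fully connected machinery of a recognition network is irrelevant here
   and is dropped; only filter-response maps are kept.
2. For a grid size $n$, every filter-response map is partitioned into
   $n \times n$ near-equally sized subregions and the maximum response of
   each filter in each subregion is recorded, giving a max-pooling map
   $M_{l,n}$ of shape $n \times n \times k$ for layer $l$ with $k$ filters.
3. Each subregion's $k$-vector of maxima is L1-normalized so it sums to
   one. This makes everything downstream invariant to global response (and
   hence image-contrast) scaling.
4. Three variances are computed per grid size:
   - $p_a(M_{l,n}) = \operatorname{var}(M_{l,n})$ — the total variance over
     **a**ll entries of all histograms. High values mean concentrated
     histograms (few filters dominate each subregion, as in a large empty
     sky); the value approaches zero when all filters respond equally
     everywhere, so *low* $p_a$ indicates richness.
   - $p_g$ — the median over the $n^2$ subregions of the variance within
     each subregion's histogram (**g**rid).
   - $p_f$ — the median over the $k$ filters of the variance of each
     **f**ilter's value across subregions. This is the variability measure
     and behaves as the inverse of self-similarity.

   Grid sizes run from 2 to 30 in steps of 2, giving $3 \times 15 = 45$
   features per layer, named `Pa_2 ... Pa_30, Pg_2 ... Pg_30, Pf_2 ...
   Pf_30` in that fixed order.
5. An RBF-kernel SVM with stratified 5-fold cross-validation evaluates
   feature subsets of sizes 1–3 (15,225 candidates from the pool of 45)
   for art vs non-art discrimination; linear SVMs on raw pixels
   (227×227×3 = 154,587 dimensions) and on raw response maps (96×55×55 =
   290,400 at the original geometry) serve as baselines. The canonical
   two-feature plane is richness at grid 22 against variability at grid 12
   (`Pa_22`, `Pf_12`).

A companion **self-similarity** score compares the whole-image ("ground
level") normalized histogram against the 64 histograms of an 8×8 partition
and averages their histogram intersections
$\sum_i \min(g_i, h_i) \in [0, 1]$. Across image sets, self-similarity and
`Pf_12` are negatively rank-correlated — variability is the flip side of
self-similarity.

## Assumptions and numerical choices

- **Variance estimator.** The variance in all three measures is the
  population estimator (divide by the count), matching the bare
  $\operatorname{var}(\cdot)$ in their definitions; `estimator = "sample"`
  switches to the $n-1$ denominator if desired. All documented worked
  examples use the population form.
- **Rectification.** Variances are measured on post-ReLU (half-wave
  rectified) responses, the conventional reading of "filter responses";
  `apply_relu = FALSE` exposes the raw linear responses for sensitivity
  analyses. Local response normalization is omitted.
- **Uneven grids.** When a map side $H$ is not divisible by $n$, subregion
  edges fall at $\mathrm{round}(jH/n)$: bins differ by at most one pixel
  and no pixels are dropped.
- **Degenerate subregions.** A subregion in which no filter responded at
  all (possible after rectification of a perfectly flat region) cannot be
  L1-normalized; it is filled with the uniform histogram $1/k$, which
  keeps the sum-to-one invariant and contributes zero within-histogram
  variance. The number of fills is recorded on the returned objects.
- **Medians of even counts** are the mean of the two central values.
- **Ties in the subset ranking** are broken toward smaller subsets, then
  lexicographically on feature names, so rankings are reproducible.
- **Histogram comparison.** The self-similarity comparator is histogram
  intersection of normalized vectors. The comparison function here is a
  design choice from the histogram-similarity family rather than a fixed
  convention; intersection was chosen for its boundedness ($[0,1]$ with 1
  iff equal) and insensitivity to empty bins.
- **SVM hyperparameters.** Defaults are $C = 1$, $\gamma = 1/d$; an inner
  3-fold grid search over $C \in \{0.1, 1, 10, 100\}$,
  $\gamma \in \{0.01, 0.1, 1, 10\}$ (training folds only) is available via
  `tune = TRUE`. Features are z-scored with training-fold statistics only;
  the exhaustive subset search uses the untuned default so that 15,225
  evaluations stay tractable. Because the search selects on the same CV
  scores it reports, `nested_subset_estimate()` provides the
  selection-bias-free companion estimate.

## Filter banks without downloads

Pretrained first-layer weights can be supplied as a plain-text matrix
(`weight_source = "pretrained"`, 96 filters, one row each). For fully
self-contained use the package ships two builtin banks:

- `"gabor"` (default for analyses here): 30 analytic filters — 16 oriented
  even/odd Gabors on luminance (4 orientations × 2 wavelengths of 4 and 8
  px × 2 phases), 6 centre-surround difference-of-Gaussians on luminance
  and the red–green and blue–yellow opponent channels (scales 1→2 and
  2→4 px), and 8 oriented first-derivative-of-Gaussian color-edge filters
  on the two opponent channels. This mirrors, qualitatively, the
  oriented-edge plus opponent-color structure a trained first layer is
  known to develop.
- `"random"`: seeded zero-mean, unit-norm Gaussian filters, any layer
  count.

All builtin filters have exactly zero DC response, so constant image
regions produce zero (rectified) responses and shading gradients excite
only the odd-symmetric filters of matching orientation — which is what
makes homogeneous fields register as "sparse" in $p_a$.

## The synthetic image classes

Real corpora of artworks and photographs cannot ship with a package, so
`richvar` generates seeded synthetic classes whose *relative* statistics
emulate the category structure the measures are meant to resolve:

- `art_like`: a canvas of 64-px tiles, each tile holding a two-color
  gradient background plus ~8 oriented bars and disks; with probability
  0.9 a tile's motif is resampled, so content is dense *and* varies across
  the canvas (rich, variable).
- `pattern_like`: the same motif machinery with tile-deviation probability
  0.02 — one motif repeated everywhere (rich, self-similar), the analogue
  of plant patterns.
- `sparse_like`: one smoothly shaded homogeneous field (a single dominant
  color with a gentle large-scale gradient, like a sky or a plain
  backdrop) with at most `element_density` (default 5%) of the area
  covered by isolated elements; `element_density = 0` degenerates to a
  constant-color image.
- `noise`: i.i.d. uniform RGB pixels — maximally stationary, a useful
  extreme of self-similarity.

Motifs use oriented bars, disks and color gradients at 2–4 scales, drawn
from a seeded palette of 6 colors, precisely so that first-layer
edge/color filters respond differentially. Defaults (512 px canvas, 64-px
tile, palette 6, density 0.05, class-specific variability) were fixed as
part of the class contracts and are not tuned per analysis. On these
classes, with the gabor bank, mean `Pa_22` is several-fold higher for
`sparse_like` than for `art_like` and `pattern_like` (which are
comparable), mean `Pf_12` is higher for `art_like` than `pattern_like`,
and self-similarity rank-correlates negatively with `Pf_12` — the
qualitative geometry of the real image categories.

What the synthetic classes do **not** emulate: natural-scene power
spectra, painterly texture such as brush strokes, semantic content,
camera noise and optics, or the within-category diversity of real art
corpora. Passing tests on these classes therefore validate the
*implementation and the qualitative mechanics* of the measures, not any
claim about classification accuracy on real artworks — published
accuracies on real corpora (e.g. ~0.93 for the two-feature plane) are not
reproducible without those image sets and are out of scope here.

## Problem sizes used in the shipped checks

The test suite exercises the full study conditions at deliberately modest
counts: the ordering battery uses 5 seeds × 10 images per class; the
classification check uses 3 seeds × 300 images (75 art-like vs 225
non-art across the three non-art classes), on which the `(Pa_22, Pf_12)`
pair reaches ≥ 0.90 CV accuracy; the rank-correlation check reuses the
300-image set. The oracle-equivalence property compares vectorized
measures against naive loop references on 1000 random 6×6×5 maps at
1e-10. `scripts/acceptance.R` regenerates 50 images per class and reruns
the whole pipeline, including an exhaustive two-feature subset search.

## Known limitations

- Only first-layer pretrained weights are supported from file; deeper
  pretrained layers would require the full original network, which is
  deliberately out of scope. Builtin multi-layer analyses use the random
  bank with optional 2×2 inter-layer pooling.
- Whether variances should be taken pre- or post-rectification is not
  fixed by the measures' definitions; both are available, post-ReLU is the
  default, and all shipped results use it.
- The per-category metric convention (each art category scored against all
  non-art images, art positive) is one reasonable formalization; others
  (e.g. category-only accuracy) would give different numbers.
- Histogram max-pooling uses a partition; overlapping pooling windows are
  not implemented.
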