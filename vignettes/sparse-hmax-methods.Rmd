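---
title: "Sparse HMAX: model, design choices, and what the synthetic experiments show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse HMAX: model, design choices, and what the synthetic experiments show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Sparse HMAX alternates two operations along a feed-forward hierarchy:

* **S layers (template matching).** A window of side $p$ slides over the
  $n_{\text{prev}}$ maps of the previous stage (valid region, no padding;
  the same window is cut from every map and concatenated, so a patch has
  dimension $p^2 n_{\text{prev}}$). At each position a code vector is
  inferred under a generative model $x \approx B s$ whose dictionary $B$
  was learned, without labels, from patches sampled at random locations
  of that same stage.
* **C layers (pooling).** Each S map is reduced by a pooling window of
  side $c$ advanced by `step` (default $c$: non-overlapping; trailing
  partial windows are dropped). Intermediate C layers use the *signed*
  maximum; the terminal layer pools the *absolute* responses, either
  globally per map or over a spatial pyramid (grids $\{4,2,1\}$ give
  $21$ features per basis). A flag allows abs-max at intermediate layers
  too.

Two dictionary learners implement the sparse-coding idea:

* **ICA.** The patch dimension is first reduced to $k$ by PCA concurrent
  with whitening; maximum-likelihood ICA with a log-cosh sparse prior
  then finds filters $W$ with orthonormal rows in the whitened space
  (symmetric fixed-point iteration, orthonormality enforced exactly by
  symmetric decorrelation at each step). Inference is linear,
  $s = W P (x - \mu)$, so an ICA S layer is one matrix product per
  image. ICA cannot be overcomplete: $k$ must equal the number of
  filters, which is why the whitening dimension defaults to `n_bases`.
* **SSC.** Standard sparse coding,
  $\min_{B,S} \|X - BS\|_F^2 + \lambda\|S\|_1$ with $\|b_j\|_2 = 1$,
  solved by alternating (i) coordinate-descent lasso inference (exact
  soft-threshold coordinate updates, all patch columns advanced jointly
  one coordinate at a time) and (ii) exact per-column basis minimization
  $b_j \propto R_j s_j^{\top}$. The objective is non-increasing across
  alternations by construction. Plain alternation has a well-known
  collapsed local minimum in which two columns model the same generator
  while another generator goes unrepresented; after each alternation,
  unused columns and near-duplicates (inter-column $|\cos| > 0.999$) are
  re-seeded from the worst-reconstructed patches, and the re-seed is kept
  only if re-inference lowers the objective, preserving monotonicity.

Baselines reproduce the classic HMAX alternatives: random patches as
bases with Gaussian-distance responses
$\exp(-\|x-b_i\|^2 / 2\sigma^2)$ ($\sigma$ defaults to the median
inter-basis distance — the reference formulation states only that shorter
distance means higher response), and L2-regularized coding with the
closed-form ridge inference $s = (B^\top B + \gamma I)^{-1} B^\top x$.

Training is greedy and layerwise: compute the previous stage's C maps for
the training images, sample `n_patches_per_layer` windows, fit whitening
(ICA path) and the dictionary, move up. Nothing is back-propagated and no
labels are consumed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_side` per S layer | 10 (S1), 4 (S2, S3) | patch side in previous-stage map pixels |
| pooling ratios | 3 (C1), 2 (C2) | pooling window side; `step` defaults to the ratio |
| `n_bases` | 36 / 100 / 40 (five-layer preset) | dictionary sizes per S layer |
| `lambda` | 0.15 (SSC presets) | L1 weight; calibrated on synthetic patches so 5–15% of coefficients are active |
| `whitening_k` | `n_bases` (ICA) | retained PCA dimension |
| `subtract_mean` | `FALSE` | keep the patch mean so a DC-like basis can emerge (useful for surface brightness; flag provided because common practice differs) |
| `normalize` | off for ICA presets, on for SSC presets | unit-norm, clip at 0.2, renormalize — the SIFT-style illumination normalization, applied to S2+ codes only |
| terminal `grids` | {4, 2, 1} | spatial-pyramid resolutions |

The five-layer ICA preset (`exp1-5layer`) ends in a global abs-max (one
feature per top basis) because its purpose is unit-level probing; the
SSC classification presets (`archI-4layer`, `archII-6layer`, the latter
with overlapping step-2 pooling at C2) end in the pyramid.

## Synthetic data: what it emulates, what it does not

The package is exercised entirely on generated images; each generator
isolates one property of the real datasets it stands in for.

**Sparse composites** (`synth_sparse_images`) tile an image with patches
drawn as `actives_per_patch` bases times Laplace coefficients. They exist
for recovery experiments: the ground-truth codes reconstruct the images
exactly at zero noise, and a learner applied to aligned patches should
return the planted dictionary (matched $|\cos| > 0.99$ for SSC; Amari
index $< 0.05$ for ICA on planted mixtures). Recovery through the full
training path samples windows at *random* positions, so those tests use
one-patch-per-image composites — a window that straddles tile boundaries
sees shifted basis fragments that no patch-based model should be expected
to un-mix.

**Noise fields** (`synth_noise_images`) provide white or $1/f$ spectra.
By default the field is multiplied by a smooth log-normal contrast
envelope (sd 1 on the log scale, spatial correlation length
$3 \cdot \text{side}/8$). The reason is structural: a purely Gaussian
$1/f$ field has *no* statistical dependencies beyond second order, so
after PCA whitening its filter responses are jointly Gaussian and no
pooling nonlinearity can manufacture the different-location correlations
that natural images show — we verified that with the envelope disabled,
max pooling and average pooling are indistinguishable in the two
different-location pairing cases. The envelope supplies precisely the
spatially varying local contrast (variance modulation) that natural
scenes have and that max pooling converts into linear correlation.
`contrast_sd = 0` recovers the stationary Gaussian field for baseline
checks. The generator does not emulate oriented structure, occlusion
boundaries, or phase alignment, so learned "filters" on these fields are
not Gabor-like; conclusions about *filter shape* require natural images.

**Shape categories** (`synth_category_images`) render a fixed template
per category (vertical bar, diagonal X-cross, disk, ring) at jittered
positions with additive Gaussian noise. The templates are deliberately
mutually distinctive — in an early design the bar was a sub-pattern of an
upright cross, which makes one-vs-rest separation of the bar category
impossible in principle (every bar detector fires for crosses), a
situation the object categories of the reference experiments do not
present. What these images do *not* emulate: within-category shape
variation, clutter, scale changes, or texture; a passing selectivity test
shows that the hierarchy can discover position-tolerant category
structure without labels, not that it handles real object variability.

## The pooling-correlation study

`correlation_study()` samples paired locations on the S1 maps and on
pooled C1 maps and reports Pearson coefficients for three pairings:
different filters at the same location ($n(n-1)$ coefficients), the same
filter at locations offset diagonally ($n$), and different filters at
different locations ($n(n-1)$). Two geometry decisions, both exposed as
parameters:

* **Offset 16.** On C1 the offset is divided by the pooling ratio
  (minimum 1) so the image-plane separation stays comparable across
  layers. With the ratio sweep {2, 4, 8, 16}, only a multiple of 16
  keeps that separation *exactly* equal at every ratio; 16 also exceeds
  the 10-pixel filter side, so paired windows never overlap and the S1
  baseline is pure sampling noise.
* **Reference ratio 2 for mode contrasts.** At ratios comparable to the
  offset, box-averaging becomes a strong low-pass filter and the
  long-range *linear* correlation of $1/f$ input re-enters the
  average-pooled responses; that is physics, not a pooling effect. The
  max-vs-average contrast is therefore assessed at the smallest ratio,
  while the growth-with-ratio trend is assessed along the whole sweep
  for max pooling (with a 0.02 slack on mean-|coefficient| estimates
  from roughly 20k samples).

## Numerical choices

* Whitening adds a variance floor $\varepsilon = 10^{-8}$ before the
  $1/\sqrt{\lambda}$ scaling; the back-projection uses the same floored
  values, so forward∘backward is the identity on the retained subspace to
  machine precision. Requests beyond the numerical rank error out naming
  the achievable rank.
* ICA converges when every filter row's alignment with its previous
  iterate is within $10^{-5}$ (sign-insensitive); cap 400 iterations,
  non-convergence returns the last iterate with a warning and a metadata
  flag. On data with no super-Gaussian structure the iteration
  legitimately oscillates — expected, and harmless for studies that only
  need *some* orthonormal whitened-space filter set.
* Coordinate-descent lasso stops when the largest coefficient change in a
  sweep is below $10^{-10}$; solutions satisfy the L1 subgradient
  conditions within $10^{-6}$ (tested).
* Basis sign is canonicalized (largest-magnitude entry positive), with
  filters flipped in step, so serialized models and visualizations are
  reproducible across runs.
* Ties: most-selective-unit and max-response readout take the lowest unit
  index; threshold selection takes the lowest maximizing threshold;
  category assignment takes the first category in sorted order.
* Degenerate inputs: zero code vectors pass through normalization
  unchanged; constant activation ranges collapse the threshold grid to a
  single value; images smaller than a layer's window are skipped during
  training with a warning (error if none remain).
* Pearson correlation is used throughout the correlation study (the
  probe's definition does not specify a correlation flavor; responses are
  continuous and approximately elliptical, where Pearson is standard).

## Problem sizes

The bundled experiments are sized for a single CPU: the selectivity
experiment trains the five-layer preset (36/100/160 bases — the top layer
widened from the preset's 40 because mixed-category training needs more
high-level units than single-set training) on 160 images of 64×64 with
20,000 patches per layer, about two minutes; the correlation study uses
40 contrast-modulated $1/f$ images of 128×128, 36 ICA filters of 10×10,
and 500 paired locations per image per collection, under a minute. Both
are re-run from scratch by `scripts/acceptance.R`.

## Known limitations

* No multi-scale filter bank and no pooling over scale bands; scale
  tolerance comes only from the distortion probes, not the architecture.
* ICA layers require $k = n$ (no overcomplete ICA); overcompleteness is
  SSC's job.
* Sparse S layers solve a lasso per window position; for large images
  and dictionaries this is the dominant cost (the ICA path is a single
  matrix product and is preferred for probing experiments).
* The linear SVM harness is one-vs-rest on precomputed features; no
  kernel methods, no calibration of decision values.
* Back-projection visualization distributes a pooled activation uniformly
  over its pooling window — informative for display, but not an inverse
  of max pooling.
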