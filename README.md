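# sparsehmax

Sparse HMAX in R: a cortex-inspired hierarchical recognition model that
alternates template-matching **S layers**, whose bases are *learned* by
sparse-coding techniques, with spatial max-pooling **C layers**. The
package is for computational-neuroscience and vision researchers who want
to study how sparse, invariant selectivity — of the kind recorded in
inferior temporal cortex and the medial temporal lobe — can emerge from
purely unsupervised, layerwise learning, and to use the same features for
image classification.

## The model

Patches sampled from a layer's maps are modeled as sparse linear
combinations of a dictionary, `X ≈ B S` with most of `S` near zero. Two
learners are provided for the S-layer bases:

* **ICA** — maximum-likelihood independent component analysis under a
  log-cosh sparse prior, with filter rows `W` orthonormal in the
  PCA-whitened space. Inference is a single linear map, `s = W x`, so an
  S layer is just filtering.
* **SSC** (standard sparse coding) — minimize
  `‖X − BS‖²_F + λ‖S‖₁` with unit-norm basis columns, by alternating
  coordinate-descent lasso inference and exact per-column basis updates.
  Dictionaries may be overcomplete.

Baselines: L2-regularized coding (closed-form ridge inference), random
patch extraction with distance-based (Gaussian-kernel) responses — the
classic HMAX S2 rule — and any combination of the two.

Each C layer down-samples its S maps by max pooling (average and square
pooling are available for the statistics below). The terminal layer pools
absolute responses over a spatial pyramid (grids {4, 2, 1} give 21
features per basis) or globally. Why can a *linear* sparse-coding model
learn anything at higher layers? Because max pooling converts the
higher-order (variance) dependencies of filter outputs into plain linear
correlations — the package's `correlation_study()` measures exactly this
effect, before and after pooling, for three pairing cases of filters and
locations.

Analysis tools mirror the physiology-style probes: max-abs unit responses,
tie-aware ROC/AUC selectivity, AUC-based category assignment with
max-response prediction, 20-threshold detector units,
distortion-invariance curves, and basis visualization by recursive
back-projection through pooling windows and the whitening transform.

## Worked example

Train the five-layer preset (S1-ICA / C1 / S2-ICA / C2 / S3-ICA) on
synthetic four-category shape images — bars, crosses, disks, rings at
jittered positions — with no labels, then probe the top-layer units:

```r
library(sparsehmax)

train <- synth_category_images(n_per_category = 40, image_side = 64,
                               noise_sd = 0.05, jitter = 3, seed = 160)
test  <- synth_category_images(n_per_category = 40, image_side = 64,
                               noise_sd = 0.05, jitter = 3, seed = 161)

spec  <- hmax_preset("exp1-5layer", n_bases = c(36, 100, 160))
model <- train_unsupervised(spec, train$images,
                            n_patches_per_layer = 20000, seed = 162)

r_train <- layer_responses(model, "S3", train$images)
r_test  <- layer_responses(model, "S3", test$images)
for (cat in unique(test$labels))
  print(most_selective_unit(r_test, test$labels, cat))
assign_and_predict(r_train, train$labels, r_test, test$labels)$accuracy
```

```
<unit_selectivity unit 127: AUC 1.0000>
<unit_selectivity unit 17: AUC 1.0000>
<unit_selectivity unit 131: AUC 1.0000>
<unit_selectivity unit 8: AUC 1.0000>
[1] 0.875
```

Every category acquires a perfectly selective top-layer unit (one-vs-rest
AUC 1.0) although training never saw a label, and the two-stage readout —
assign each unit its max-AUC category on the training set, predict each
test image by its max-response unit — reaches 87.5% against a 25% chance
level. `visualize_basis(model, 3, 127)` back-projects unit 127 to the
pixel plane to show what it prefers; `extract_features()` yields the
terminal feature vectors for classification with
`evaluate_protocol()` (random balanced splits, one-vs-rest linear SVM,
mean ± sd accuracy).

A shell front end wrapping the same functions lives at
`inst/cli/sparsehmax` (`train`, `extract`, `visualize`, `poolstats`,
`selectivity`, `classify` subcommands over a YAML config).

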