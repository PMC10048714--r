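---
title: "Feature-level fusion of NIR spectra and fruit images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-level fusion of NIR spectra and fruit images: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pearfusion)
```

## The problem

The pear woolliness response is a physiological disorder — mealy, chaffing
flesh linked to boron/calcium deficiency and water loss — that is hard to
judge from the outside alone. Two cheap, non-destructive sensing routes see
complementary parts of it: near-infrared reflectance spectroscopy (NIRS,
900–1700 nm) reflects the chemistry of hydrogen-bonded constituents (water,
sugars), while an RGB photograph captures the external symptoms (dull,
darker-yellow colour, rim-spreading lesions). `pearfusion` implements the
feature-level fusion of the two: each modality is first turned into a
learned feature vector by its own branch, the two vectors are concatenated,
and a single prediction layer classifies the fused vector.

## The model

**Acquisition.** A raw luminance scan $I$ is calibrated against white and
dark reference scans, $R = (I - B)/(W - B)$, and the five scans of a
measured region are averaged into one modelling spectrum. Reflectance is
stored as a fraction throughout; percentages are formatted only for
display, which avoids silent 100× scale mismatches between branches.

**Spectral branch.** A multilayer perceptron with exactly one hidden layer:
rectified-linear hidden units, a single sigmoid output unit, uniform weight
initialisation, Adam on binary cross-entropy. The post-activation hidden
layer $F_b \in \mathbb{R}^{n_\text{hidden}}$ is the spectral feature
vector; features are taken after the rectifier because that is the
representation the fused head consumes. The hidden width is a structural
hyperparameter swept over $10, 20, \dots, 100$. Five classical baselines
(PLS-DA, polynomial SVM, random forest, AdaBoost, XGBoost) ship with their
published preset hyperparameters; the AdaBoost and XGBoost presets are
printed identically at source (an apparent copy error) and are kept as
printed.

**Image branch.** Six convolutional backbone families (VGG16/19-,
ResNet50/101-, Xception- and DenseNet201-style) are re-implemented from
their published block patterns with named tap points
(`layer1…layer5`, `block1…block5`, `entry_flow`/`middle_flow`/`exit_flow`).
At `width_scale = 1` and input 224 the resnet-style stages reproduce the
canonical spatial sizes 112, 56, 28, 14, 7 and the xception-style exit flow
pools to a 2048-length vector. Pretrained weights are deliberately not
used: the claims under test concern tap depth and fusion, not transfer
from an external corpus, and the package must run fully offline. Training
is from scratch at reduced scale — the desk defaults (input 64 px,
`width_scale` 0.25, single-repeat stages, two middle-flow blocks) preserve
each family's per-stage halving pattern while training in seconds on one
CPU. The networks use no normalisation layers; at desk scale, He-uniform
initialisation with Adam is sufficient and keeps the forward pass exactly
deterministic.

**Fusion.** A tap's activation grid (Height × Width × Channel) is
flattened row-major — height slowest, channel fastest, a fixed documented
order so features are reproducible — and the fused vector is the exact
concatenation $F_f = \text{Append}(F_a, F_b)$, image features first, with
no rescaling. The prediction head is a single dense layer to two class
scores with an argmax decision. Both branches stay frozen while the head
trains (two-stage training): this matches the extract-then-fuse narrative
of the method, makes tap ablations comparable (identical branch weights
across rows), and lets extracted features be cached. Joint fine-tuning of
the branches during fusion is not offered; with frozen deterministic
branches, caching and re-extraction are equivalent. An optional
standardisation flag (off by default) can z-score the fused features —
scale mismatch between branches is a known hazard the plain-concatenation
definition is silent on.

**Evaluation.** All results are 2×2 confusion matrices plus accuracy,
precision, recall and F1. Precision/recall/F1 are computed per class (each
class in turn as positive) and macro-averaged. Macro averaging is a
deliberate design decision: it uniquely reproduces every reconstructible
published value from the worked-example confusion counts (e.g. 0.614
precision from counts 50/38/34/22, 0.879 from 72/49/23/0, 0.956 from
65/72/0/7), whereas per-class values do not match and weighted averaging
only coincides because the classes are balanced. Degenerate denominators:
a class with zero predicted positives has precision 0 unless it also has
zero actual positives; recall of an absent class is 1; F1 is 0 when
precision + recall is 0. Display rounding is half-up at three decimals.
On any class-balanced set, accuracy equals macro recall exactly; one
published recall value (0.951 for the ResNet101 layer-5 fusion model)
violates this identity, and the package reports the identity-consistent
reconstruction (0.917) while tabulating the deviation instead of matching
the likely typo.

## The synthetic generator

The real 480-pear collection is not publicly deposited, so the package
ships a seeded generator whose defaults define the study conditions every
test runs under: 240 + 240 samples at full scale (desk runs use 100 + 100),
228 bands over 900–1700 nm, five raw scans per region synthesised so that
calibration and averaging recover the noise-free spectrum exactly when
noise is zero, and one 128 px RGB image per sample.

Spectra are a smooth quadratic baseline minus two Gaussian absorption dips
(1200 nm and 1450 nm, the water-association region); the diseased class
deepens the 1450 nm dip by `spectral_effect_size` (default 0.08, half of
it at 1200 nm). Three nuisance processes make the branch realistically
imperfect: per-sample multiplicative scatter (`scatter_sd = 0.05`, the
classic diffuse-reflectance nuisance), per-sample dip-depth variability
(`dip_depth_sd = 0.05`, biological heterogeneity — without it the class
depths are deterministic and the branch saturates at 100%), and additive
per-scan band noise (`spectral_noise_sd = 0.02`). Images are a shaded
ellipse on a near-white background; the diseased class shifts the base
colour toward a darker, duller yellow (`image_effect_size = 0.2`) and
receives rim-concentrated dark blotches; per-sample colour jitter and
per-pixel noise keep the image branch imperfect too. The defaults were
fixed once so that each branch alone is informative but imperfect and
their errors are partly independent — the regime in which concatenation
fusion can demonstrably help and the qualitative ordering
(fusion ≥ image-only > spectra-only) emerges; they were not tuned further
afterwards.

What the generator does *not* emulate: photorealistic fruit, instrument
line shapes or the 5000:1 SNR specification, boron/calcium chemistry, or
correlated (shared-cause) errors between the modalities. Passing tests
therefore show that the pipeline's machinery is correct and that fusion
behaves as claimed under these controlled conditions — not that the
specific published accuracies transfer to real pears.

## Numerical and procedural choices

* **Splits** are stratified by class (70% per class to training,
  `round(0.7 n_c)`), a seeded shuffle; 480 balanced samples give
  336 = 168 + 168 training and 144 = 72 + 72 validation — the only reading
  under which the published worked-example counts reproduce the published
  macro metrics.
* **No spectral preprocessing** (no SNV, no derivatives): raw averaged
  reflectance feeds the network, matching the end-to-end design.
* **Seeds.** Every stochastic step takes a seed; the experiment harness
  derives stage seeds from one master seed by a counter scheme
  (`(seed + 1000003 k) mod (2^31 - 19)`), so any stage can be re-run
  independently and the whole run is bit-reproducible.
* **Unstated training details** (the source does not give epochs, batch
  size, learning rate or loss): binary cross-entropy, Adam at its
  conventional 10^-3 rate, batch 32, 200 epochs with early stopping
  (patience 20) for the spectral branch when a validation set is supplied;
  15 epochs for desk-scale image training; 60 epochs for the head.
* **Ties** in model selection go to the smaller hidden width; the argmax
  decision takes the first maximum.
* **Problem sizes.** The shipped test-suite and acceptance runs use
  desk-scale conditions — 100 samples per class, 64 px inputs, quarter
  width, single-repeat stages — chosen so a full run of every experiment
  finishes in minutes on a single CPU while preserving the architecture
  patterns under test; full-width geometry is exercised by a forward-pass
  shape suite rather than full-scale training.

## Known limitations

* The backbones are pattern-faithful, not parameter-faithful: no batch
  normalisation, reduced depth/width at desk scale, and no pretrained
  representations, so absolute image-branch accuracies are not comparable
  to fine-tuned full-scale networks.
* The published absolute accuracies for spectra-only baselines (Table-3
  analogues) depend on the private pear data and are not reproduction
  targets; only the worked-example confusion reconstructions are exact.
* PLS-DA requires the component count not to exceed the data rank; the
  preset (8 components) therefore needs at least 9 training samples and
  8 bands.
* The generator's class structure is a stand-in: no distributional
  description of real healthy vs woolly pear spectra was available to
  calibrate against.
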