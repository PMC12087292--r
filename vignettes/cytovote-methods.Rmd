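---
title: "CytoVote: methods and design notes"
author: "CytoVote authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CytoVote: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Some biologically important cell populations — leukaemia stem cells among
normal haematopoietic stem cells are the motivating example — carry
morphological differences that are too subtle for visual inspection of
stained smears. The approach implemented here classifies single-cell crop
images by fine-tuning a roster of convolutional networks independently and
fusing their per-image predictions by plurality ("majority-rule") voting.
The ensemble tends to be more accurate than any individual member, and it
removes the need to guess in advance which single architecture will perform
best on a given cell-classification task.

This vignette records the models, the tunable parameters, the synthetic
benchmark data, and the design decisions taken where more than one
reasonable choice existed.

# Preprocessing

Colour carries staining variation (batch-to-batch differences in
Giemsa–Wright intensity and hue) that is irrelevant to morphology, so
images are reduced to 8-bit grayscale using the NTSC luminance formula

$$ Y = 0.299\,R + 0.587\,G + 0.114\,B , $$

rounded to the nearest integer (half away from zero). The coefficients are
configurable (`PreprocessConfig`) but default to the NTSC weights, which
approximate perceived brightness.

Contrast enhancement is a **percentile linear stretch**: the 1st-percentile
intensity maps to 0, the 99th to 255, values outside clip. We chose this
among the many possible "contrast enhancement functions" because it is
robust to single-pixel outliers, closed-form testable, and idempotent up to
rounding (re-applying it moves no pixel by more than one intensity step).
The percentiles are exposed in the configuration. A constant image has no
contrast to stretch; it maps to all-zero with a warning rather than
dividing by zero.

The datastore (`buildDatastore`) labels images by their directory name,
orders records deterministically (sorted paths), skips unreadable files
with a logged warning, and errors on empty class directories. Crop size is
not constrained — cells are resized at training time, per backbone — because
upstream cropping conventions vary.

# Synthetic single-cell generator

Real curated single-cell image collections of this kind are not publicly
archived, so the package ships a generator
(`syntheticSpec`/`generateDataset`) that emulates their structure: one
roughly round Giemsa–Wright-style mononuclear cell per image — pink-grey
cytoplasm, darker purple-blue nucleus with band-limited chromatin texture —
on a pale background, with per-image jitter in size, eccentricity,
orientation, position, stain hue and sensor noise.

Two phenotype axes carry the class signal, both classic cytomorphology
discriminators: the **nucleus-to-cell area ratio** and the **chromatin
texture correlation length**. Class means sit on a circle around a shared
baseline at radius proportional to `separationDelta` (0.08 area-ratio units
and 1 px of texture scale per unit delta). At `separationDelta = 0` all
classes are identically distributed — the exchangeability null used for
calibration tests. At delta = 1 the two extreme classes differ by about
three within-class standard deviations of area ratio, which is learnable
but far from trivial at these image sizes. Baseline values (radius 17 ± 1.8
px on a 64-px canvas, area ratio 0.55 ± 0.05, eccentricity 0.3 ± 0.1,
texture scale 2.5 px, background 235) are plausibility choices for
cytospin-prepared mononuclear cells, not fits to any measured dataset.

Reproducibility contract: a master seed derives one seed per image through
a fixed counter scheme, so any single image can be regenerated without
replaying the whole dataset, and `drawPhenotypes` reproduces the manifest
draws without rendering pixels. Identical specs produce byte-identical PNG
trees.

What the generator does **not** model: multi-cell fields and touching
cells, debris, focus gradients, scanner optics, and the long-tailed
morphological heterogeneity of real marrow populations. Passing tests on
synthetic data therefore demonstrate that the pipeline's machinery is
correct and calibrated — not that any particular accuracy transfers to real
slides.

# Backbones and fine-tuning

The registry lists the seventeen published ImageNet-scale architectures of
the full-scale ensemble (AlexNet through NASNet-Large, including the
Places365 variant of GoogLeNet) plus desk-scale **surrogate CNNs**
(`scnnA`–`scnnE`): trunks of two or three 3×3-convolution + ReLU + 2×2
mean-pool blocks with distinct widths, depths, input sizes (32 or 64 px)
and weight seeds. Published entries require their pretrained trunk weights
as an artifact (the package does not perform ImageNet pretraining);
surrogates materialise deterministic random-initialised trunks, so tests
and benchmarks run anywhere. The two remaining roster slots of the
published nineteen-member ensemble have no named architecture and are left
configurable via `makeSurrogateBackbone`.

Fine-tuning (`fineTuneBackbone`) follows the standard small-data transfer
regime: the convolutional trunk is **frozen** and used once per image as a
feature extractor (bilinear resize to the backbone's input size, grayscale
replicated to three channels, features cached); a dense block and softmax
classification head on top are trained by mini-batch optimisation. The
`frozenDepth` fraction selects how much trains: at its default (the trunk
boundary) the dense block and head both train; set to 1, only the head
trains. Requests to unfreeze convolutional stages are clamped with a
warning — backpropagating through the trunk buys little on datasets of this
size and would dominate runtime, and the frozen-trunk design is what keeps
a multi-network ensemble practical on one CPU.

Optimisers: SGDM (momentum 0.9), Adam and RMSProp, hand-implemented over
the dense parameters. Defaults — Adam, constant learning rate $10^{-3}$, 30
epochs, batch 32, early-stopping patience 10 — sit inside the customary
ranges for this kind of task (learning rate $10^{-4}$–$10^{-3}$, 20–100
epochs, batches of 32–64). Momentum, the absence of weight decay and the
constant schedule are fixed documented defaults. Model selection keeps the
weights of the epoch with the **best validation accuracy** (earliest epoch
on ties); with an empty validation fold, training accuracy substitutes.
Features are standardised per dimension using training-fold statistics. A
non-finite loss aborts with a diagnostic rather than returning a broken
model. Class weighting (inverse frequency) exists but is **off** by
default: imbalanced one-vs-rest designs are evaluated as-is, with balanced
accuracy reported alongside plain accuracy so the optimism of the latter
under imbalance stays visible.

# Splitting

`SplitSpec` defaults to 0.6 : 0.2 : 0.2 train : validate : test with
per-class stratification. Published descriptions of this protocol vary
between 0.6/0.2/0.2, 0.8/0.2 and 0.8/0.1/0.1 depending on the experiment;
all are expressible, and the default follows the most specific statement
of the training options. Within each class, validation and test receive
`floor(fraction * n)` records and the remainder goes to training — so
validation and test are always within one image of their target and the
training fold, absorbing both remainders, within two. Accuracy is always
computed on the test fold only; validation is used solely for epoch
selection.

# Voting

"Majority rule" is implemented as **plurality**: the class with the
maximum number of votes wins, an absolute majority is not required (with
ten classes and nineteen voters the modal class routinely holds well under
half the votes). Each model casts exactly one unweighted vote per image;
models stay architecturally independent. Ties are possible with three or
more classes; since no published tie rule exists for this protocol, the
package breaks ties by **highest mean normalised score** across models,
then lexicographically by class name, and flags every tie-broken record
(`tieBroken`) so downstream analysis can audit them. Score averaging is
only ever a tie-breaker, never the primary rule.

# Evaluation

`confusionChart` cross-tabulates true against predicted classes with
strict record alignment; overall accuracy is `100 * trace / total`, and the
support-weighted mean of per-class accuracies reproduces it to numerical
precision — an identity asserted on every evaluation run in the test suite.
Experiment drivers cover the published designs: binary two-population
comparison, one-vs-rest identification with pooled remainder (imbalance
ratio logged), and multi-class classification with single-versus-ensemble
comparison. Reports serialise to JSON with a configuration hash and no
timestamps, so identically seeded runs are byte-identical. Rendered
figures (confusion heatmap, accuracy bars) are side outputs only.

# Verification strategy and problem sizes

Every stage is tested against an independent oracle where one exists:
direct arithmetic for the luminance formula and the stretch map, a
brute-force vote counter for the fusion rule (1,000 random vote tables
spanning 1–19 models and 2–10 classes, ties included), the generator's own
ground-truth masks for rendered morphology, and closed-form binomial
expectations for the Condorcet simulation.

The end-to-end properties use synthetic experiments sized to run
comfortably on one CPU: null calibration at `separationDelta = 0` with
three surrogates and 200 test images per seed over 20 seeds (ensemble
accuracy must stay inside the 99% binomial band around chance);
a separation grid (0.3/0.6/1.0/1.5, 120 images per class, five surrogates)
on which accuracy rises monotonically, exceeds 90% at delta 1.5, and the
ensemble matches or beats the median single model in at least 80% of 20
moderate-separation replicates. These delta values were fixed at design
time from the generator's effect-size calibration (three within-class
standard deviations at delta 1, near-Bayes-separable at 1.5). The
`scripts/acceptance.R` script recomputes scaled-down versions of the same
quantities (10 null seeds, 10 replicates, 3 strong-separation runs) from
scratch at any seed.

# Known limitations

* Surrogate trunks are random-initialised, not pretrained; they stand in
  for transfer learning's *frozen-representation* regime, not for the
  quality of ImageNet features. Plugging in real pretrained weights
  requires supplying trunk artifacts in the documented layer layout.
* The generator's two signal axes make the synthetic task intentionally
  low-dimensional; real morphological class structure is richer, and real
  accuracies will differ.
* Plurality voting with few models and many classes tie-breaks more often;
  the flag makes this visible but cannot remove the arbitrariness of any
  tie rule.
* Training is single-threaded by design; wall-clock scales linearly in
  models × images.
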