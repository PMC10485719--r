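---
title: "Saliency-enhanced content-based image retrieval for dermoscopy: methods and design notes"
author: "secbir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-enhanced content-based image retrieval for dermoscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(secbir)
```

## The problem

Content-based image retrieval (CBIR) supports dermoscopic diagnosis by
showing the clinician the most similar labeled reference lesions for a query
image, mimicking a bibliography search. Modern CBIR embeds each image with a
convolutional classifier and compares embeddings, but the embedding attends
to everything in the frame — rulers, skin texture, illumination — not only
the lesion. The saliency-enhanced variant (SE-CBIR) implemented here adds a
fine-tuning stage in which each image is paired with its own
vanilla-gradient saliency map as a fourth input channel, nudging feature
extraction toward the regions the classifier itself found decisive, and
making the retrieval process inspectable through those maps.

The pipeline has five steps:

1. train a 7-class lesion classifier on RGB images;
2. extract a vanilla-gradient saliency map per image from the frozen
   classifier;
3. expand the classifier to a 4-channel input (RGB + saliency) and
   fine-tune it;
4. extract deep features — the pooled activations after the last
   convolutional layer — for every image in the labeled retrieval set;
5. rank retrieval candidates by cosine similarity to the query's features.

Conventional CBIR is steps 1, 4 and 5 with the stage-1 model; SE-CBIR is all
five with the stage-2 model. `run_pipeline()` executes both so they can be
compared head to head on the same data and split.

## Classifier and feature tap

Both backbones are stride-2 convolutional stacks topped by the same head:
global average pooling, batch normalization, then two dropout + dense
blocks ending in a softmax over the 7 diagnosis codes (`akiec`, `bcc`,
`bkl`, `df`, `mel`, `nv`, `vasc`). The retrieval embedding is tapped at the
pooled activations, after the last convolution and before any
classification layer.

* `reference_b4` is the full-scale reference: 380 × 380 input and a
  1792-wide feature tap (the feature width of the EfficientNet-B4 family
  commonly used for dermoscopy), ending in a 1×1 convolution to 1792
  channels. It is built and run, never trained, in the test suite.
* `tiny_test` (64 × 64 input, four 3×3 blocks, 64-wide features, head width
  32) is the desk-scale backbone used for all training experiments.

The package contains its own CNN engine (im2col convolutions with
RcppArmadillo kernels, exact backpropagation to the input, Adam): gradients
are verified against central finite differences in the test suite.

Head hyperparameters the architecture leaves open: dropout rates default to
0.3 and 0.2 and the hidden dense width to 512 (reference) / 32 (tiny) —
ordinary transfer-learning head sizes, configurable in `build_classifier()`.

### Four-channel expansion

`expand_input_channels()` appends one input-channel block of rows to the
first convolution's weight matrix and copies every other parameter
verbatim. The new channel's kernel initialisation is open by design; three
modes are provided:

* `rgb_mean` (default): the mean of the three copied RGB kernels, so the
  saliency channel starts with a moderate, non-disruptive influence;
* `zero`: the new channel is exactly inert — the 4-channel model reproduces
  the 3-channel logits bit-for-bit regardless of the saliency content,
  which doubles as a conservation test;
* `random`: He-scaled random weights.

### Batch-normalization inference statistics

Pooled ReLU features have small per-feature variance, and their
distribution drifts quickly while the backbone trains. A conventional
momentum-based running average of batch statistics proved far too stale to
evaluate with: inference-mode logits diverged wildly from training-mode
behaviour. The engine therefore recalibrates the inference moments exactly —
feature mean and variance over the unaugmented training subset — at the end
of every epoch. This costs one extra forward pass per training image per
epoch and makes inference deterministic and consistent with what the
validation loop measures.

## Training

### Focal loss

Class imbalance (about 67% nevi vs 1% dermatofibroma) is countered with the
multiclass focal loss

$$\mathcal{L} = -\alpha_t\,(1 - p_t)^{\gamma}\,\log p_t,$$

where $p_t$ is the softmax probability of the true class, $\gamma$ (default
2) down-weights easy examples, and $\alpha_t$ is a per-class weight. $p_t$
is clamped at $10^{-12}$ before the logarithm. With $\gamma = 0$ and unit
$\alpha$ the loss is exactly categorical cross-entropy (asserted to
$10^{-9}$ in the suite).

For $\alpha$ the package defaults to **square-root inverse-frequency**
weights normalised to mean 1 (`alpha_from_frequencies(power = 0.5)`). Raw
inverse frequency (`power = 1`) is available but was found to destabilise
desk-scale training: with a 67:1 imbalance and a few hundred images, rare
classes receive weights so large that the optimum drifts off the majority
class and overall accuracy collapses. The square root keeps the rebalancing
effective but bounded.

### Learning-rate schedule

Each parameter group — backbone ("pretrained") vs head ("new"/adapted
layers) — follows a linear ramp from 10% of its base rate to the base rate
over `rampup_epochs`, then exponential decay
`base * decay^(epoch - rampup)`. The two stages carry the conventional
transfer-learning defaults (stage 1: backbone 5e-5, head 1e-2; stage 2:
backbone 1e-5, adapted layers 1e-3, i.e. 100× the stage-1 backbone rate).
Those rates presume a pretrained backbone. Because this package never
downloads weights, the desk-scale pipeline trains from random
initialisation and `pipeline_config()` substitutes rates suited to that
regime (3e-3/3e-3 for stage 1; 2e-4/1e-3 for stage 2; decay 0.93, ramp 2,
20 epochs). The optimizer is Adam throughout — the standard choice for
fine-tuning at small rates.

Stage 2 reuses the stage-1 epoch count, and saliency maps are computed once
from the frozen stage-1 model and reused for every epoch: saliency
extraction is a discrete pipeline step, not part of the training loop.

### Augmentation

Stage 1 applies, on the fly and seeded: the 8 dihedral symmetries, a mild
sinusoidal row distortion, Gaussian noise, brightness/contrast jitter,
per-channel colour scaling, resize to 115% followed by a random crop back
to the input resolution, and coarse dropout (mean-filled rectangles).
Stage 2 restricts augmentation to random flips/rotations plus resize, so
the composed saliency channel stays geometrically aligned with its image.
All pixel values are clamped to [0, 1] afterwards.

### Splits

`stratified_split()` is stratified by diagnosis *and* grouped by lesion:
all images of one lesion (follow-up acquisitions) land in the same subset.
Grouping prevents near-duplicate leakage between train and test and
parallels the retrieval-time rule that excludes same-lesion images from a
query's candidates. Subset ratios default to 80:10:10; with grouping, each
class's subset counts can deviate from the exact ratios by at most one
lesion group. A class with fewer images than subsets is kept whole in
train, with a warning.

## Saliency

`vanilla_gradient()` computes the gradient of a class score with respect to
the input pixels, reduces over colour channels, and min–max normalises to
[0, 1]. Four decisions were open and are resolved as defaults with
alternatives selectable:

* **Target class**: the model's predicted class (a retrieval query has no
  ground truth); `true` and explicit classes are available.
* **Score**: the pre-softmax logit rather than the softmax probability —
  probability gradients vanish at confident predictions.
* **Channel reduction**: maximum of absolute values (`max_abs`), the common
  vanilla-gradient convention; `mean_abs` available.
* **Normalisation**: per-image min–max, because the map is consumed as a
  bounded input channel; a constant (e.g. all-zero) raw gradient maps to an
  all-zero map rather than dividing by zero.

Maps are computed at the model input resolution and bilinearly resized at
composition time if needed.

## Retrieval

Similarity is the cosine $S_c = A \cdot B / (\lVert A\rVert\,\lVert
B\rVert)$ between feature vectors. Candidates are ranked by **descending**
$S_c$ — most similar first; descriptions of "lower is closer" refer to the
cosine *distance* $1 - S_c$. Ties break by ascending image id so rankings
are reproducible. The query's own image and every index entry sharing the
query's lesion id are excluded before ranking, maximising diversity of the
retrieved set. The retrieval set defaults to the training split (it plays
the role of the labeled reference archive); this is configurable. Ranking
is asserted equal to an exhaustive brute-force sort over 1000 random
configurations in the suite.

## Evaluation

* **P@k**: per query, the fraction of the top-k retrieved images sharing
  the query's class; per class, the mean over that class's queries.
  Queries with truncated candidate lists are excluded with a warning, not
  padded (padding would bias the estimate).
* **AP@k**: the unweighted (macro) mean of the per-class P@k over the
  M = 7 classes. The macro reading is validated in the suite by
  reproducing the printed averages of the published benchmark table
  shipped in `inst/extdata/` (`retrieval_precision_benchmark()`).
* **Majority vote**: the most frequent label among the top-k (default 6)
  retrieved images; frequency ties break by the larger similarity sum,
  then ascending class code.

Precisions are kept at full precision internally and rounded only for
presentation.

## Reader-study analytics

Records are `(rater, task, image, diagnosis, confidence 1–5, truth)` rows;
task 1 is unaided diagnosis, task 2 the same images re-diagnosed with
retrieved references. `study_summary()` aggregates per-rater accuracy and
confidence (absolute and stratified by correctness), per-task 7×7 confusion
matrices summed over raters, melanoma overdiagnosis (non-melanoma truths
labeled `mel`) and underdiagnosis (melanoma truths labeled otherwise) with
task-2/task-1 relative reductions, and diagnosis-change counts joined on
(rater, image).

Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ is computed **per rater against
the ground truth**, and "average $\kappa$" is the unweighted mean over
raters. Rater-vs-rater agreement is not computable in this design because
each participant sees a different random image set; rater-vs-truth is the
only consistent reading, and it is flagged here as an interpretation.
Cross-rater spreads use the sample standard deviation.

Because real rater data cannot ship with a package, `simulate_readers()`
provides a confusable-class error model (errors land in plausible sibling
classes, e.g. melanoma ↔ nevus) with confidence correlated with
correctness. The suite checks parameter recovery: per-class correct rates
recovered from the aggregated confusion matrices fall within 95% binomial
intervals of the generating rates.

## Synthetic data: what it does and does not emulate

`generate_dataset()` reproduces the *structure* of a dermoscopy archive:
the metadata dialect (`image_id`, `lesion_id`, `dx`), a configurable class
imbalance (default ≈ 67% nv, 11% mel), follow-up images sharing a lesion id
(re-rendered with small spatial jitter and brightness shift), 8-bit PNG
storage, and — unlike real archives — an exact per-image lesion mask for
scoring saliency localisation.

Each class is a phenotype tuple (base colour, shape eccentricity, border
irregularity amplitude, internal texture frequency) rendered as a softly
blended, sinusoidally perturbed ellipse on noisy skin-toned background. The
three brownish classes (`bkl`, `df`, `nv`) deliberately overlap so that
classifiers and retrieval make realistic errors. What is *not* modeled:
photorealistic dermoscopic texture, hair and ruler artifacts, illumination
fields, acquisition variability across clinics. Consequently, passing the
scaled-down pipeline checks demonstrates that the machinery — training,
saliency, fine-tuning, indexing, ranking, metrics — is correct and that
saliency localises to the discriminative region; it does not certify
clinical-scale retrieval precision on real dermoscopy.

## Numerical choices and degenerate inputs

* Focal loss clamps $p_t$ (and $1 - p_t$) at $10^{-12}$.
* Cosine similarity of a zero vector is undefined: an explicit `NA` with a
  warning, never a silent `NaN`; a zero query vector is an error.
* A constant raw gradient yields an all-zero saliency map; normalisation is
  idempotent.
* Softmax subtracts the row maximum before exponentiation.
* Minibatches of size 1 are skipped (batch statistics undefined);
  divergence (non-finite loss) aborts training with a diagnostic.
* Every stochastic step (weight init, multinomial class draw, augmentation,
  dropout, shuffling, simulators) flows from explicit integer seeds through
  isolated RNG scopes, so identical configurations reproduce identical
  artifacts byte for byte.

## Problem sizes

The desk-scale study conditions used by the test suite and the acceptance
script: 700 synthetic images at 64 × 64 with the default imbalance and a
10% follow-up rate, an 80:10:10 lesion-grouped stratified split, the
`tiny_test` backbone, 20 epochs per stage, batch size 32. The reference
backbone is exercised as a single forward pass at 380 × 380. The published
benchmark tables are evaluated at their native sizes (7 classes × 4
cut-offs; 9 raters).

## Known limitations

* The CNN engine is single-threaded and CPU-bound; it is sized for the
  desk-scale backbone, not for training the reference backbone.
* No pretrained initialisation is shipped, so the paper-scale learning
  rates (which presume transfer learning) are defaults of the schedule
  functions but not of the desk-scale pipeline.
* Saliency is vanilla gradient only — by design; smoothed or integrated
  gradients are out of scope.
* Approximate nearest-neighbour indexing is out of scope; queries scan the
  full index.
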