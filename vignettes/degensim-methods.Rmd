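---
title: "Modelling progressive neurodegeneration in feed-forward classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling progressive neurodegeneration in feed-forward classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Posterior cortical atrophy (PCA) is an atypical, visual-variant presentation
of Alzheimer's disease: progressive atrophy of posterior visual cortex with
visual agnosia as a leading symptom. `degensim` implements an *in silico*
analogue of this disease course in trained feed-forward convolutional
classifiers. The injury model is cumulative random synaptic loss: a nominal
fraction $f$ of the network's inter-neuron connection weights is set to
exactly zero, and as $f$ grows along a fine schedule every previously
severed connection stays severed while an additional uniformly random set is
ablated. Each replicate network draws its own private random course of
degeneration.

Two families of readouts are tracked over the injury course:

* **Behavioural.** Classification accuracy on a held-out test set at every
  schedule increment, against the analytic chance level $1/C$ for $C$
  balanced classes; and the *within-superclass error rate* — among
  misclassified stimuli, the fraction whose predicted class belongs to the
  true class's superclass. The networks are trained only on fine class
  labels, so any superclass structure in their errors is emergent.
* **Representational.** Representational dissimilarity matrices (RDMs) over
  a fixed stimulus set, built from the penultimate dense layer's
  post-activation outputs with dissimilarity $1 - r$ (Pearson). The injured
  network's RDM is compared to the *same* replicate's uninjured reference
  RDM with Kendall's $\tau_A$ — the tau variant that keeps tied pairs in the
  denominator, the standard choice for RDM comparison. A scrambled-RDM
  noise floor (mean $\tau_A$ between the reference RDM and
  entry-permuted copies of itself) anchors "no remaining structure".
  Superclass-level RDMs are obtained by block-averaging the stimulus-level
  RDM within and between superclasses.

## Assumptions

* Injury is static: no retraining, rewiring or compensation occurs between
  increments (synaptic plasticity is explicitly out of scope).
* Synapses, not neurons, are the default lesion target: biases are per-
  neuron offsets rather than inter-neuron connections and are never ablated.
  Node ablation (lesioning whole conv channels / hidden dense neurons,
  zeroing all their incoming and outgoing weights) and weight randomisation
  (resetting selected weights to zero-mean draws scaled by their layer's
  current weight SD) are provided as variant modes.
* Selection is global: one uniform draw over the whole weight catalog, not
  stratified per layer. The catalog orders weights by layer, then
  column-major within each tensor, so it is reproducible given the model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `increment` | 0.001 (0.1%) | injury step as a fraction of all weights |
| `max_fraction` | 0.5 (desk runs) | end of the injury course |
| `rsa_checkpoints` | 7 fractions | where RDMs and $\tau_A$ are computed |
| `n_replicates` | 5 (desk) / 25 (replication) | independently trained networks |
| `dropout_rate` | 0.3 | training-only regularisation on dense layers |
| `learning_rate` | 1e-3 (small-cnn) / 3e-5 (vgg19) | RMSprop step size |
| `epochs` | 30 (small-cnn) / 40 (vgg19) | training length |
| `rsa_stimuli_per_class` | 10 | balanced RDM condition subset |

The `vgg19-cifar100` training profile records the full replication recipe
(RMSprop at $3\times10^{-5}$ for 40 epochs, 30% dropout after each of the two
1000-unit dense layers, 32×32 inputs upscaled 4× to 128×128, convolutional
stacks initialised from user-supplied pretrained weights, dense and output
layers re-initialised per replicate). Batch size (64) and the categorical
cross-entropy loss are package choices, exposed in `training_config()`,
since the replication recipe does not pin them down. Executing that profile
needs GPU-scale resources and a pretrained weight file; the package's tests
exercise its architecture contract and the desk-scale `small-cnn` profile
end to end.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emulates the *statistical skeleton* of a CIFAR-100-like
dataset: $C = S \times K$ balanced classes nested in $S$ balanced
superclasses, with within-superclass visual similarity exceeding
between-superclass similarity. Each superclass draws a prototype image (a
white-noise field box-blurred with radius 2 so convolutions have local
structure to exploit, scale $\sigma_{sup} = 0.5$); each class perturbs its
superclass prototype by an independent blurred field
($\sigma_{cls} = 0.15 < \sigma_{sup}$, making superclass structure dominate);
each image adds i.i.d. pixel noise ($\sigma_{noise} = 0.1$) and is clipped
to $[0,1]$. Defaults are 5 superclasses × 4 classes, 16×16 single-channel
images, 100 training and 50 test images per class — a size chosen so a full
five-replicate degeneration study runs on one desk CPU in minutes. One root
seed derives the prototype, train and test streams by the counter rule
root, root+1, root+2, so splits are disjoint, independent and reproducible.

What it does *not* emulate: photographic content, multi-scale category
structure, or any systematic relations *among* superclasses. The
superclass prototypes are exchangeable i.i.d. draws, whereas natural image
taxonomies also carry macro-organisation (animate vs inanimate, natural vs
artificial) that orders categories relative to one another. This matters
for one readout — see "Known limitations" below. Passing desk-scale tests
therefore demonstrates that the machinery (training, ablation, RDM
construction, $\tau_A$, error conversion) behaves correctly and that the
class/superclass asymmetry in *within-superclass* structure is picked up;
it does not certify that every finding on natural images is reproduced in
miniature.

## Numerical choices

* **Rounding.** The injured count at fraction $f$ is
  `round_half_away(f * N)`: nearest integer, half away from zero. This
  makes a stepped cumulative schedule and a direct jump to the same
  fraction injure identical counts.
* **Arg-max ties** in prediction break toward the lowest class id, so fully
  ablated (constant-score) models are deterministic.
* **Degenerate rows.** Heavily injured networks routinely produce
  zero-variance activation rows; Pearson correlation is undefined there.
  Such rows get dissimilarity 1 (the "uncorrelated" value) against every
  other row, with a logged message — erroring would truncate every
  late-stage degeneration curve.
* **$\tau_A$ routes.** Below $10^4$ pairs a vectorised $O(n^2)$ pair count
  is used; above, a merge-sort-based $O(n \log n)$ counter (C++). Tests
  require agreement to $10^{-12}$ on the overlap, against an independent
  enumeration oracle.
* **Undefined error structure.** With no misclassifications the
  within-superclass error rate has an empty denominator and is reported as
  `NA`, never 0 — uninjured near-perfect models would otherwise fabricate a
  value. Summaries exclude `NA` from that metric's n.
* **Dropout** is inverted (activations scaled by $1/(1-p)$ during training),
  so inference needs no rescaling and two inference passes are bit-identical.
* **Determinism.** All stochastic elements (init, shuffling, dropout masks,
  injury selection, scrambles) derive from explicit seeds; with
  single-threaded numerics two runs of the same config are bit-identical at
  the records level.

## Design decisions on genuinely open points

* **Are biases "weights"?** The injury targets connections between neurons,
  mimicking synapses; biases are not inter-neuron connections, so they are
  excluded from the catalog. The node-ablation variant also leaves biases
  in place (a lesioned neuron's output is silenced through its weights).
* **Global vs per-layer selection.** The simulated atrophy draws uniformly
  over all network weights; a stratified per-layer pool is not the default
  reading of "x% of the network weights" and is left to layer-targeted
  extensions.
* **Scrambling.** The noise floor permutes the RDM's upper-triangle entries
  (destroying all structure), matching the purpose of a pure-noise
  reference; joint row/column permutation — which preserves the metric
  constraints among entries — is available as an option.
* **Superclass RDM construction.** Block averaging of the stimulus-level
  RDM: off-diagonal entries are means over between-superclass stimulus
  pairs; the diagonal keeps the within-superclass mean and is excluded from
  $\tau_A$ comparisons by the strict-upper-triangle vectorisation.
  Alternatives (RDMs over superclass-mean activation patterns) are not
  implemented.
* **Post-activation.** RSA reads the penultimate layer's outputs after the
  nonlinearity — the neuron's output, i.e. what downstream neurons see.
* **Superclass chance conventions.** The conventional reference for the
  within-superclass error rate is the marginal $1/S$ (5% for 20
  superclasses). The exact expectation for a uniform guesser restricted to
  wrong classes is $(K-1)/(C-1)$ (4/99 ≈ 4.04% for CIFAR-100's shape) —
  both are exposed via `superclass_chance()`; the marginal convention is
  the default, the discrepancy documented rather than resolved.
* **Noise-floor units.** The scrambled floor is reported as a raw
  $\tau_A$. For large condition sets the null SD is about
  $\sqrt{4/(9 n_{pairs})}$, so means over 25 scrambles sit well inside
  ±0.005.
* **Tabular, pipeable surface.** Degeneration records and summaries are
  tibbles; fitted experiments support `tidy()`/`glance()` and
  `autoplot()`. Models, stimulus sets, RDMs and injury states are plain S3
  objects, since images and weight tensors are not tabular.

## Problem sizes used by tests and the acceptance script

The desk-scale study runs 5 replicates of the small-cnn (two conv layers of
8 and 16 3×3 filters with 2×2 max-pooling, dense 64, dense 32 penultimate,
20-way softmax; ~20k ablatable weights) on the default 5×4 synthetic
dataset (2000 train / 1000 test images), injured in 0.005 steps to 0.5 with
RSA at fractions {0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5} over a balanced
200-condition test subset. This completes in a few minutes on one CPU.
Larger schedules (0.001 increments), more replicates, three-channel images
and the vgg19 profile are configuration away.

## Known limitations

* The hand-rolled network engine is CPU-bound base R; it is meant for
  desk-scale experiments, not for training large networks.
* Superclass-level $\tau_A$ under the desk configuration rests on only
  $S(S-1)/2 = 10$ between-superclass block means. Because the generator's
  superclass prototypes are exchangeable i.i.d. fields, those ten means are
  nearly tied, and their ranking is fragile under injury. In desk runs the
  superclass-level $\tau_A$ curve therefore decays *at least as fast* as
  the object-level curve — the opposite ordering from natural-image
  experiments, where macro-structure among categories (animacy, naturalness
  gradients) stabilises between-category ranks. The within-superclass
  *error* analysis, which does not depend on ordering superclasses among
  themselves, does show the expected hierarchy effect (errors stay within
  the correct superclass far above chance early in the injury course).
  Reproducing the superclass-$\tau_A$ robustness finding in miniature would
  require a generator with structured relations among superclasses, which
  the current model deliberately omits.
* Full-scale replication (VGG-19 on CIFAR-100, 25 replicates, 0.001
  increments) is supported by configuration but far outside desk-scale
  test budgets.
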