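---
title: "Simulating memory consolidation by generative replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating memory consolidation by generative replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`replaysim` simulates how offline replay — the reactivation of internal
activity patterns between episodes of real experience — can consolidate
category knowledge in a layered model of the ventral visual stream. The
learner is a VGG-style convolutional classifier: five convolutional blocks,
each a run of 3x3 same-padding ReLU convolutions ended by one 2x2 max-pooling
layer, followed by two fully connected layers with dropout (rate 0.5) and a
softmax output. The five block-ending pooling layers, `pool_1` ... `pool_5`,
are the only legal *cut points*: stages at which the network can be
temporarily disconnected so that replay representations are injected directly
into the remainder ("head") of the network. Later cut points correspond to
more anterior regions of the ventral stream; the penultimate stages play the
role of the lateral occipital cortex, where replay is hypothesised to be most
effective.

Training alternates "days" and "nights". A day is one epoch of Adam
(learning rate 3e-4, minibatch 36, categorical cross-entropy) over the real
training images, each image augmented once per epoch (up to 20 degrees of
rotation, 20% shifts, 20% zoom, horizontal flips, borders filled by symmetric
reflection) and preprocessed by per-channel mean subtraction. A night trains
only the head at the chosen cut point, with the same optimizer settings, on
replay material:

* **Generative replay.** After each day, the activations of all training
  images are captured at the cut point, downsampled per channel by block
  means (factors 8, 4, 4, 2, 1 for `pool_1` ... `pool_5` by default), and
  flattened. For each class a single multivariate normal is fitted — the
  sample mean and sample covariance of those vectors — and as many novel
  "imagined" samples are drawn per class as there were real training images.
  Samples are upsampled back to the layer's resolution by nearest-neighbour
  replication and replayed with their class labels.
* **Veridical replay.** The exact captured activations of every training
  image, at full resolution, are replayed instead — a memory system that
  stores every experience.
* **Continuous replay.** A single day of real learning; the distributions
  are fitted once from that day and every later day-night cycle runs two
  replay epochs with no real images.
* **RL-scheduled replay.** A small "hippocampal" side network — a bias-free
  linear regression with one input per class and one output — learns the
  value of replaying each class. Classes are drawn from a softmax over the
  values; after each replayed minibatch of 36 samples the chosen class's
  value is trained (Adam, learning rate 0.001, mean-squared error, 50 steps)
  toward the observed reward: the reduction of the chi-square gap
  `sum((total_c - correct_c)^2 / total_c)` between perfect and observed
  classification on the validation split. Initial values come from replaying
  one batch of each class in turn. Because the input is one-hot and there is
  no bias, each update moves only the chosen class's weight.

Because nights touch only layers strictly after the cut, consolidation can
never corrupt the representations it samples from — a property the test
suite asserts bit-exactly.

## Desk-scale study conditions

The package's defaults define a complete study that runs on one CPU in
minutes, preserving the structure of the full-scale protocol
(VGG-16, 100 ImageNet classes, 1,170/130/50 images per class) at roughly
one-tenth linear scale:

| quantity | default | rationale |
|---|---|---|
| classes | 10 | one model's class load in the full-scale study |
| images per class | 117 / 13 / 5 | the canonical 117:13:5 train/val/test ratio |
| image size | 64 x 64 x 3 | smallest size that leaves five 2x downsamplings meaningful |
| architecture | blocks (1,6), (1,12), (1,24), (1,48), (2,48); head (96, 96) | five-block, five-cut-point topology with VGG-like channel doubling, sized for minutes-scale CPU epochs |
| days | 10 | short-protocol length |
| replicates | 5-10 | replicate means are what the phenomenon checks compare |
| replay volume | 117 samples/class/night | parity with the number of real images seen per day |
| downsample factors | 8, 4, 4, 2, 1 | keeps the joint Gaussian tractable at every cut while leaving the deepest pool untouched; every factor is exposed in `replay_config()`, so alternatives (for example {8,4,3,2}, or a factor-7 robustness check where the spatial side allows it) are one configuration edit away |
| pretraining | on; 20 disjoint classes, 58 images each, 5 epochs | the full-scale model transfers from an experienced (ImageNet-pretrained) base; the mini base gets the same treatment on disjoint synthetic classes |

The optimizer (Adam, 3e-4, batch 36), dropout 0.5, augmentation bounds, side
network (0.001, MSE, 50 epochs per batch, one init batch per class) and the
replay-sample parity are kept at their full-scale values.

## The synthetic category generator

No images are downloaded: categories are procedural. A class prototype is a
25-parameter vector — background colour, three Gaussian colour blobs
(position, radius, colour), and one oriented sinusoidal grating (orientation,
frequency, amplitude, phase). Rendering an exemplar jitters every parameter
with zero-mean noise and adds iid pixel noise; every jitter scale grows
strictly (affinely) with the prototype's `difficulty` in [0, 1], so harder
classes have more within-class variability at all spatial scales. This gives
the three levers the experiments need:

* **difficulty** — per-class, monotone in within-class variance;
* **scarcity** — [limit_exemplars()] keeps a chosen number of training
  images per class. The rebalancing experiment engineers per-class
  difficulty through a scarcity gradient (45 to 117 exemplars) rather than
  the jitter knob: scarce classes are learned more weakly, but their
  exemplars remain equally prototypical, so the fitted class distribution
  still supports effective replay. Turning the jitter knob to extremes
  instead makes hard classes' activation distributions so diffuse that
  replaying them stops helping, which cancels the headroom advantage the
  scheduler is supposed to discover;
* **similarity** — `"grouped"` mode shares one base prototype across classes
  and perturbs only blob colours and grating orientation, the analogue of a
  category set of conceptually similar items (all plants);
* **scale** — any split sizes and image geometry.

The default uniform difficulty of 0.7 was calibrated once, as a design goal,
so that the 10-day no-replay baseline neither stalls near chance nor
saturates: day-1 accuracy lands around 25-40% and day-10 around 80-90%,
the regime in which the full-scale study operates and in which consolidation
effects are measurable. What the generator does *not* emulate: natural image
statistics (no cluttered backgrounds, occlusion, pose or lighting
variation), heavy-tailed class frequencies, and label noise. Passing the
phenomenon suite therefore shows that the *consolidation machinery* behaves
as described on a controllable image family — not that effect sizes would
transfer to photographs.

## Numerical choices

* All network arithmetic is single precision (weights are stored as
  float-representable doubles, so C++ float round trips are lossless and a
  zero-learning-rate epoch is bit-exact). Adam uses beta = (0.9, 0.999),
  epsilon 1e-7.
* The sample covariance is singular whenever the downsampled dimension
  exceeds the per-class sample count; a ridge of `1e-6 x mean(diag)` is
  added before the one Cholesky factorisation per distribution per night
  (n draws then cost n matrix products). A failed factorisation escalates
  the ridge once before raising a diagnostic error.
* Generative samples are *not* clamped at zero by default: the fitted normal
  is sampled faithfully even though true pooled activations are nonnegative.
  `clip_nonnegative` restores the clamp for ablations.
* Downsampling is block-mean pooling and upsampling nearest-neighbour
  replication, so `downsample(upsample(x, f), f) == x` exactly — the round
  trip used by the moment-recovery tests. Non-divisible factors average the
  trailing partial block.
* The final partial minibatch of an epoch is trained, not dropped; small
  synthetic splits cannot afford discarded data.
* Evaluation is deterministic: dropout off, no augmentation, ties in the
  argmax broken toward the lower class index.
* Day-level evaluation happens once per day-night cycle, after the night, so
  each day's log already reflects that night's consolidation; day 0 records
  the untrained model as a chance-level control.
* Head training during a night uses a fresh Adam state (the truncated
  network is recompiled nightly, as in the full-scale protocol); day
  training keeps one persistent Adam state across days. During an RL night
  the head's state persists across the night's steps, and the side
  network's moments persist for the whole run.
* The side network's reward uses the raw chi-square change, unnormalised; the chi-square uses per-class cells with the all-correct
  expectation (a pooled single-cell variant is a one-line change in
  `chi_square_gap()` callers).

## Open design points, resolved

* *Augmentation sampling law*: uniform over [-max, +max] per parameter, one
  draw per image per epoch; rotation about the image centre, bilinear
  interpolation.
* *Distribution refitting*: interleaved conditions refit every night from
  that day's activations; the continuous condition fits once after its only
  real day (replayed material is never refitted on — it has no textual
  basis and would compound sampling error).
* *Exposure parity in RL nights*: the number of scheduled batches per night
  is `ceil(C x n_train / 36)`, so the RL condition sees the same replay
  volume as plain generative replay and the two are comparable.
* *Whether base layers keep training during days*: yes — all parameters are
  free to be trained; a config ablation can freeze the base.
* *Scheduler value estimation at desk scale*: the side network's default
  `"online"` mode trains on only the newest (one-hot, reward) pair, so a
  class's value tracks its most recent reward. At full scale a 36-item
  batch barely perturbs the enormous head and rewards are small and smooth;
  at desk scale one batch moves the small head a lot, so single-batch
  rewards — and especially the day-1 initialisation probes — are an order
  of magnitude larger than the value updates can track within a run, and
  online values degenerate into probe noise. The rebalancing experiment
  therefore uses the scheduler's `"buffer"` mode: the initialisation probes
  are logged as the first reward observations and every update trains on
  the full history, so each class's value converges to its mean observed
  reward. Mean night reward is the quantity that genuinely discriminates
  persistently weak classes (more headroom, larger chi-square reductions).
  The softmax temperature stays at its default of 1.

## Limitations

* Desk-scale accuracies are not full-scale accuracies; the
  package reproduces orderings and qualitative dynamics (replay > none,
  late cuts > early cuts, generative ~ veridical, continuous below
  interleaved, early-learning concentration, rebalancing), not absolute
  percentages.
* The test split at desk scale is 50 images, so single-replicate accuracies
  are coarse (2% steps); all phenomenon checks compare replicate means.
* Inferential statistics (ANOVAs, corrected post-hoc tests) are deliberately
  out of scope; the tidy per-replicate CSV logs are designed to be consumed
  by any statistics package.
* Rebalancing at desk scale reproduces the selection-side phenomenon - the
  scheduler replays weakly learned (exemplar-scarce) classes more often,
  with clearly negative count-on-baseline regressions - but not a net
  narrowing of per-class accuracy spread: the lift of weak classes is
  offset by a comparable drop in rarely replayed strong classes, because a
  single night of class-biased batches moves the small head substantially
  and evaluation follows the night. The corresponding test asserts the
  narrowing anyway and is expected to fail; it documents the scale limit
  rather than being weakened to pass.
* Sequence replay, bottleneck generative architectures, and
  representational-similarity comparisons with brain data are out of scope.

## Reproducing the analyses

```{r}
library(replaysim)

protos <- generate_prototypes(10, seed = 1)
bundle <- build_dataset(protos, 117, 13, 5, seed = 1)

cfg <- protocol_config("generative", cut_point = "pool_4",
                       n_days = 10, n_models = 5, master_seed = 1)
log <- run_condition(cfg, bundle)
summarize_logs(log)
```

`scripts/acceptance.R` re-runs the whole battery (five conditions at three
replicates plus two RL replicates) from a single seed and writes the summary
quantities as JSON.
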