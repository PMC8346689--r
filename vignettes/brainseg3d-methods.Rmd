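---
title: "Methods: spatial-prior-augmented 3D U-Net brain tissue segmentation"
author: "brainseg3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-prior-augmented 3D U-Net brain tissue segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Automated segmentation of brain tissue on clinical T1-weighted MRI is hard
because acquisition parameters vary widely and focal lesions distort both
signal and anatomy. `brainseg3d` implements a fully automated pipeline that
segments six tissue classes — cerebrospinal fluid (1), cortical gray matter
(2), white matter (3), deep gray matter (4), brainstem (5) and cerebellum
(6), with 0 as background — using a 3D encoder–decoder network whose second
input channel is a patient-specific *spatial prior* obtained by registering
the subject to a template and propagating the template's tissue labels.

The pipeline stages, in order, are: skull stripping (a binary instance of
the same network, or an intensity-threshold mask), foreground cropping,
resampling to an isotropic cube (128³ by default), z-score normalization,
prior construction on the network grid, network inference, the
background-threshold decision rule, and exact inversion of the geometry back
to the native voxel grid. `segment()` composes these stages and is
bit-identical to invoking them manually.

## Network

The network follows the context/localization encoder–decoder design: four
downsampling blocks (3×3×3 strided convolution + a residual context module
of two 3×3×3 convolutions with dropout between), four upsampling blocks
(nearest-neighbour upscale + 3×3×3 convolution, skip concatenation, then a
localization module: 3×3×3 convolution followed by a 1×1×1 channel-halving
convolution), instance normalization and leaky ReLU (slope 0.01) after every
convolution, and deep supervision: 1×1×1 side outputs of the final three
upsampling blocks are upsampled to the input shape, summed, and passed
through the final activation. Base filter count doubles per level
(`base_filters` at full resolution).

Two output-head conventions are supported, tied to the loss:

* **soft Dice** — sigmoid activation, 6 tissue channels, no background
  channel; a voxel is assigned to the arg-max channel, but becomes
  background when no channel's probability *exceeds* 0.5 (strict
  inequality; exact ties break to the lowest channel index);
* **(weighted) categorical cross-entropy** — softmax activation over 7
  channels with explicit background; the label is the voxelwise arg-max.

Median-frequency weights for the weighted cross-entropy are
`w_i = median(n_b) / median(n_i)` over per-subject voxel counts of the
training set, so the background weight is 1 and rare classes are upweighted.

The forward and backward passes are implemented in C++ (im2col + GEMM
convolutions, single precision internally, double at the R interface);
gradients are verified against finite differences in the test suite. There
is no deep-learning framework dependency.

## Training schedule

Adam with batch size 1 from a seeded He-normal initialization; initial
learning rate 5e-4, halved after 10 epochs without improvement of the inner
validation loss, stopped after 50 epochs without improvement; the inner
validation set is a seeded subject-level 90/10 split, and the retained
checkpoint is the best-validation-loss epoch. "Improvement" means strictly
below the best loss so far minus 1e-5. These schedule semantics are
implemented in a pure function (`schedule_trace()`) and exercised directly
by the tests.

Two additions matter at desk scale (small cohorts, CPU minutes rather than
GPU days), and are exposed in `train_config()`:

* **L2 weight regularization** (`weight_decay`, default 1e-5 following the
  network's source architecture). With sigmoid soft-Dice training and very
  few subjects, unregularized logits grow until several channels saturate
  to a probability of exactly 1.0 in floating point, at which point the
  decision rule degenerates into tie-breaking. Our small-cohort experiments
  use 3e-3, which keeps probabilities calibrated so the arg-max stays
  informative; with hundreds of training subjects the source setting is
  appropriate.
* **learning rate.** The published rate (5e-4) is tuned for a regime of
  tens of thousands of optimizer steps. Adam's total parameter travel is
  bounded by (rate × steps), so a few-hundred-step desk-scale run cannot
  leave initialization at that rate; scaled-down experiments here use 5e-3
  to 1e-2 with the same decay/stop semantics.

The LOOCV transfer-learning protocol (`loocv_transfer()`) fine-tunes a
pretrained model once per subject: n−2 train, 1 validation (round-robin: the
subject following the held-out one), 1 held out; each subject is predicted
by the model for which it was left out. With `max_epochs = 0` the base
weights pass through unchanged, which the tests use to validate the
bookkeeping in isolation.

## Spatial prior by three-stage registration

`register()` fits `T(x) = A(x + d(x))` from subject to template voxel
coordinates: a 6-dof rigid stage and a 12-dof affine refinement by
multi-resolution BFGS maximization of normalized cross-correlation (robust
to the phantom's multiplicative bias field), then a diffeomorphic-demons
style deformable stage for the residual displacement field `d` (Thirion
force, Gaussian-smoothed updates and field, coarse-to-fine). Everything is
deterministic: fixed initialization and fixed iteration budgets.

`warp_labels()` propagates the template labels through the fitted transform
with the smoothed-one-hot rule: each class indicator (including background)
is smoothed with a Gaussian of σ = 0.2 voxels, sampled at the mapped
coordinates, and the voxel takes the arg-max class. The same σ = 0.2 rule is
the package-wide default for *all* label interpolation (cubic resampling,
augmentation, native-space inversion): larger σ (e.g. 0.5 voxels) visibly
erodes structures about one voxel thick, such as the phantom's outer CSF
shell. The prior enters the network as one extra channel holding the label
codes divided by the number of classes; the paper states two input channels
but not the encoding, so the single-channel code encoding is this package's
documented choice.

The prior doubles as the "registration to atlas" baseline segmenter: on
phantoms it scores an overall Dice around 0.6–0.9 — crude but informative —
and the trained prior-augmented network must beat it per class, which the
acceptance tests check.

Displacement fields are stored in voxel units on the subject grid (the
registration grids used here are isotropic); NIfTI serialization converts
to millimetres via the stored spacing.

## Synthetic phantoms: what they emulate, and what not

Because the clinical cohort and the external challenge data cannot be
shipped, every stage is exercised on synthetic brain phantoms
(`phantom_spec()`, `make_template()`, `sample_subject()`, `make_cohort()`):

* **geometry** — nested ellipsoidal CSF / cortical-GM / WM shells with
  lateral ventricles, paired deep-gray nuclei, an inferior brainstem
  cylinder and a posterior cerebellum lobe. Volume fractions approximate
  adult anatomy (deep gray ≈ 3% of brain voxels, brainstem ≈ 2%,
  cerebellum ≈ 6%, WM the largest class), making cortical GM a thin shell
  (hard class) and deep GM a small structure whose intensity contrast
  against WM is controlled by `contrast_scale` (at 0 they are isointense —
  the failure mode that motivates the spatial prior);
* **intensity** — T1-like class means (CSF dark, WM bright), per-subject
  mean redraws, a low-order-polynomial multiplicative bias field
  (exponentiated, relative amplitude 0.1), and additive Gaussian noise
  (SD 4 on a 0–100 intensity scale);
* **anatomy variability** — per-subject smooth random warps, RMS 8 mm with
  16 mm Gaussian smoothness after affine-equivalent alignment, matching
  typical inter-subject deformable displacement magnitudes. This matters
  for the prior-effect experiment: with much smaller warps a network can
  memorize structure *positions* from a handful of subjects and a
  subject-specific prior adds nothing, which no real cohort resembles;
* **lesions** — spheres perturbed by smoothed noise, placed entirely inside
  the target tissue (WM, GM or mixed), T1-hypointense by default
  (intensity shift −30 applied before bias and noise); ground-truth labels
  keep the underlying tissue so intra-lesion accuracy is well defined.

All randomness flows through one seeded generator per call; identical seeds
give bit-identical phantoms. What the phantoms do *not* emulate: MR physics
(no sequence model), multi-contrast acquisition, partial-volume mixtures
beyond light boundary smoothing, cortical folding, or pathology beyond
focal intensity lesions. Passing the phantom experiments therefore shows the
pipeline's machinery is correct and that the prior helps exactly where
intensity fails; it does not certify clinical performance.

## Evaluation suite

Per class: Dice `2TP/(2TP+FP+FN)`; volume similarity
`1 − |V_X − V_Y|/(V_X + V_Y)` (location-blind); HD95, the 95th percentile of
minimum Euclidean distances from predicted to true voxels, in mm, honoring
anisotropic spacing, directed (predicted→true) as defined — a symmetric
variant is available but not default. The percentile uses linear
interpolation between order statistics (R type 7). Conventions: Dice and VS
are 1 when both masks are empty; HD95 is NaN when either mask is empty.
Distances use an exact Euclidean distance transform
(Felzenszwalb–Huttenlocher), validated against brute-force all-pairs
computation in the tests.

Intra-lesion accuracy is the fraction of WM-lesion voxels predicted as
white matter (3), and of GM-lesion voxels predicted as cortical (2) or deep
(4) gray matter; cohort summaries report mean, median and IQR, and empty
masks are excluded. Model comparisons use the two-sample Z statistic
`(x̄1 − x̄2)/√(s1²/n1 + s2²/n2)` with `|Z| > 2.5` flagged significant; both
zero-variance conventions (equal means → 0; unequal → signed infinity,
flagged) are explicit. External 10-class manual labels are harmonized by
condensing ventricles with CSF, relabeling WM hyperintensities as WM,
mapping basal ganglia to deep gray, and assigning infarction/"other" an
excluded code (255) that is masked out of every metric.

## Numerical and design choices

* Foreground = intensity > 0 (or the skull-strip mask); crop bounds carry a
  configurable margin (2 voxels in the experiments) and serialize 0-based
  half-open in JSON.
* z-score over the whole cropped volume; constant input is an error, not a
  silent epsilon.
* Trilinear interpolation for intensities; smoothed-one-hot arg-max
  (σ = 0.2 vox) for all labels; no operation introduces new label codes.
* Instance norm ε = 1e-5; soft-Dice ε = 1e-5 in numerator and denominator;
  cross-entropy log clamp at 1e-7 (the analytic gradient ignores the clamp,
  so finite-difference checks are run away from saturation).
* Augmentation draws one random affine per step (defaults ±10° rotation,
  ±10% scale, ±5 voxel translation), applied identically to image, prior
  channel (nearest-neighbour) and labels.
* Exact probability ties in the decision rule go to the lowest channel
  index.
* Demons displacement updates are smoothed with σ = 1.0 voxels and the
  running field with σ = 0.7 (fluid + elastic regularization); forces are
  zeroed where the denominator is < 1e-9.

## Experiment scales

The packaged experiments are sized for a single CPU: phantoms of 36³–64³
voxels at 3–4 mm spacing, a 32³ network grid with 8 (or 4) base filters for
training runs (128³ remains the inference default), cohorts of 5–8
subjects, and 60–100 epoch caps. The tiny-training benchmark (8 subjects,
soft Dice + prior) reaches an overall held-out Dice ≥ 0.8 and beats the
registration-only baseline in every class. The registration-recovery
experiment runs at 64³ and requires per-class Dice ≥ 0.8 after the
deformable stage. These sizes are the package's choices for reproducible
desk-scale validation, not estimates of the clinical data.

### The prior-effect experiment, and what the phantoms cannot show

A dedicated experiment trains with-prior and without-prior models on
isointense-deep-gray cohorts (`contrast_scale = 0`) across several seeds
and compares held-out deep-gray Dice (a sign test across seeds). On
clinical data the spatial prior substantially improves the deep-gray and
brainstem classes; on these phantoms the measured effect is approximately
zero, and the experiment is reported as such rather than tuned until it
passes. The reason is structural: the phantom's only inter-subject
variability is a single globally smooth warp of one template, so — given
the visible landmarks (ventricles, tissue shells) — a registration-based
prior and a network's internally learned positional prior carry the same
information. With the deep gray isointense to white matter, its interior
displacement is unidentifiable for *both* routes (the registration prior
itself only reaches a deep-gray Dice of roughly 0.3–0.7, insensitive to
the demons regularization), and once the contrast is learnable both routes
exploit intensity directly. Reproducing the clinical effect would require
phantom anatomy whose deep structures vary in ways not predictable from a
smooth warp of a single template; that is beyond this generator and is
called out under limitations.

## Known limitations

* The phantom generator is geometric, not physics-based; absolute Dice
  values on phantoms are not comparable to clinical values.
* Phantom inter-subject variability is one smooth warp of a fixed template,
  which makes subject anatomy predictable from visible landmarks; the
  clinical advantage of the spatial prior over a network's internal
  positional prior therefore does not materialize on phantoms (see the
  prior-effect section above).
* The registration engine is a compact NCC/demons implementation; it is
  deterministic and accurate on phantoms but not a substitute for a
  production registration suite on clinical data.
* Single-precision network internals bound gradient accuracy around 1e-6
  relative; irrelevant for training but visible in finite-difference tests
  at very small step sizes.
* `batch_size` is fixed at 1, as in the training protocol it implements.
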