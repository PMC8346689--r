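# brainseg3d

Fully automated multiclass brain-tissue segmentation of T1-weighted MRI in
R: a 3D encoder–decoder network (context/localization blocks, instance
normalization, deep supervision) whose second input channel is a
patient-specific **spatial prior** obtained by three-stage registration
(rigid → affine → deformable) of the subject to a template and propagation
of the template's tissue labels. The package targets researchers who want a
self-contained, dependency-light reference implementation of this pipeline —
including a synthetic brain-phantom generator so that every stage is
testable without clinical data.

Six tissue classes are segmented (plus background 0): cerebrospinal fluid
(1), cortical gray matter (2), white matter (3), deep gray matter (4),
brainstem (5), cerebellum (6).

## The model

The network follows the context/localization U-Net design: four
downsampling blocks (strided 3×3×3 convolution + residual context module),
four upsampling blocks (upscale + convolution, skip concatenation,
localization module), instance normalization and leaky ReLU after every
convolution, and deep supervision (1×1×1 side outputs of the last three
decoder levels, upsampled and summed before the final activation). Three
training objectives are provided:

* soft Dice, `L = 1 − mean_c (2Σ p_c t_c + ε)/(Σ p_c + Σ t_c + ε)`, with a
  sigmoid head over 6 tissue channels and the decision rule "argmax, but
  background unless some probability exceeds 0.5";
* categorical cross-entropy (CCE), softmax head over 7 channels;
* median-frequency-weighted CCE with `w_i = median(n_b)/median(n_i)` over
  per-subject voxel counts.

Training uses Adam (batch size 1), initial learning rate 5e-4, halving
after 10 epochs without validation improvement and stopping after 50.
Evaluation reports Dice, volume similarity `1 − |V_X−V_Y|/(V_X+V_Y)`,
HD95 (95th-percentile directed surface distance, mm), intra-lesion
accuracies, and two-sample Z comparisons with the `|Z| > 2.5` significance
rule. Forward and backward passes are hand-written C++ (im2col + GEMM); no
deep-learning framework is required.

## Worked example

Generate a phantom cohort, build a spatial prior, and score it as the
registration-only baseline segmentation:

```r
library(brainseg3d)

spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = c(3, 3, 3))
tpl  <- make_template(spec)
subj <- sample_subject(tpl, spec, seed = 7)

prior <- build_prior(subj$vol, tpl$vol, tpl$labels)   # rigid+affine+demons
report <- evaluate_cohort(list(prior), list(subj$labels),
                          lesion_masks = list(subj$lesions))
print(report)
```

```
<bs_metrics_report>
       class dice_mean dice_sd vs_mean vs_sd hd95_mean hd95_sd
   brainstem     0.903      NA   0.944    NA         3      NA
  cerebellum     0.868      NA   0.899    NA         0      NA
 cortical_gm     0.894      NA   0.989    NA         3      NA
         csf     0.834      NA   0.937    NA         3      NA
     deep_gm     0.890      NA   0.981    NA         3      NA
          wm     0.945      NA   0.991    NA         3      NA
overall Dice 0.889 +/- 0.000 (n=1)
```

Per tissue this prints the Dice overlap, volume similarity and
95th-percentile surface distance (mm; 3 mm is one voxel here) of the
warped template labels against the subject's ground truth. A
registration-only segmentation is informative but beatable; the trained
prior-augmented network exceeds it in every tissue class in the packaged
benchmark — `train()`, `segment()` and `run_design_matrix()` reproduce
that comparison end to end, and the methods vignette
(`vignettes/brainseg3d-methods.Rmd`) documents every modelling choice.

A command-line front end is installed with the package
(`system.file("cli", "brainseg", package = "brainseg3d")`) with subcommands
`phantom`, `prior`, `segment`, `evaluate`.

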