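# rgmcmp — registration-guided multi-channel multi-path CTV segmentation

In adaptive radiotherapy a patient is re-imaged and re-planned during
treatment, and the clinical target volume (CTV) must be re-contoured on
every new planning CT. Contour propagation by registration uses the
patient's own earlier course but inherits every registration error;
direct deep-learning segmentation can learn contouring rules but lacks
patient-specific prior information. `rgmcmp` implements the
combination: the first-course CT (CT1) is registered to the
second-course CT (CT2) by rigid-body (RB) or B-spline deformable (DIR)
registration, the first-course contour (CTV1) is propagated to give
the aligned guidance pair (aCT1, aCTV1), and a multi-channel
multi-path 3D encoder–decoder network refines the propagated contour —
the Rg-MCMP framework.

The core model: three input channels (aCT1, aCTV1, CT2) each feed an
independent encoder path (no cross-path feature mixing before the
decoder); the decoder receives skip connections from every path at each
depth, re-weighted by a squeeze-excitation channel-attention gate;
deep-supervision heads at the three coarsest decoder levels are
upsampled trilinearly and summed with the final head before the
softmax. Training minimizes the equal-weight combination

    L = 0.5 * Lce + 0.5 * Ldice,
    Lce    = (1/N) sum_i sum_k -y_ik log p_ik,
    Ldice  = 1 - (1/K) sum_k (2 sum_i p_ik y_ik + eps) /
                             (sum_i p_ik + sum_i y_ik + eps),  eps = 1,

with Adam (initial rate 2e-4, batch 1), he_normal initialization, a
0.2x learning-rate drop after 30 epochs without validation
improvement, early stopping after 50, and the best-validation
checkpoint returned. Accuracy is reported as DSC, HD95 (mm), and ASD
(mm), with two-sided paired t-tests across methods.

Because paired clinical courses are private data, the package includes
a synthetic paired-course CT phantom (elliptical body, bone rods, a
lesion whose CTV is the lesion plus a fixed margin, per-case lesion
regression/growth, a contralateral decoy organ, rigid offset + smooth
warp + noise) on which the whole ladder of methods — RB, DIR, plain
3D U-Net, SCSP, Rg-MCSP, Rg-MCMP — is exercisable end to end. The
methods vignette (`vignettes/rgmcmp-methods.Rmd`) documents every
model and design choice.

## Worked example

Generate one paired-course phantom case, align course 1 onto course 2
both rigidly and deformably, and score the propagated contours against
the course-2 ground truth:

```r
library(rgmcmp)

case <- generate_case(phantom_params(), seed = 1)
dsc(case$ctv1, case$ctv2)          # 0.749  (overlap before alignment)

cfg   <- registration_config(max_iterations = 150)
t_rb  <- register_rigid(case$ct2, case$ct1, cfg)
t_dir <- register_bspline(case$ct2, case$ct1, cfg, init_rigid = t_rb)

segmentation_metrics(propagate(case$ctv1, t_rb,  grid_of(case$ct2)),
                     case$ctv2)
#>         dsc  hd95_mm   asd_mm
#> 1 0.8889793 4.330127 2.018092
segmentation_metrics(propagate(case$ctv1, t_dir, grid_of(case$ct2)),
                     case$ctv2)
#>         dsc hd95_mm   asd_mm
#> 1 0.9239221     2.5 1.482289
```

Rigid alignment lifts the raw 0.75 overlap to DSC 0.89; the deformable
stage recovers most of the smooth inter-course warp and reaches 0.92
with roughly half the rigid stage's surface error. The remaining gap to
DSC 1 is the part of the CTV change that no intensity-driven transform
can supply (the lesion regressed while its margin rule stayed fixed) —
that is the part the guided network is there to learn.
`run_experiment()` trains the network ladder on a cohort of such cases
and tabulates per-case metrics, paired t-tests, and the
delta-correlation of Table-3 style; `ordering_experiment()` runs the
frozen desk-scale comparison over three seeds.

A thin command-line wrapper is installed with the package
(`inst/cli/rgmcmp`) with subcommands `simulate`, `register`,
`evaluate`, `run`, and `model-describe`.

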