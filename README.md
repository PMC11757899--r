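# sgtube

Skeleton-guided 3D convolutional segmentation of branching tubular
structures (airways, vessels), as a self-contained R package: a dual-stream
segmentation network whose auxiliary stream predicts the centerline
(skeleton) of the structure, a sigmoid-adaptive Tversky loss built for the
extreme class imbalance of skeleton maps, deterministic 3D thinning and
branch decomposition, and centerline-aware evaluation metrics — exercised
end-to-end on synthetic branching-tube phantoms with exact ground truth, so
no imaging data is required.

It is aimed at readers who want to study *how* skeleton supervision and
imbalance-aware losses interact with a 3D encoder–decoder: every component,
including the network's forward and backward passes, is implemented in the
package (R with Rcpp/RcppArmadillo kernels) and validated against
independent oracles — finite-difference gradients, brute-force metric
recounts, and analytic phantom geometry.

## The model

**Network.** A 3-level 3D U-Net-style main stream (two 3×3×3 convolutions +
ReLU per level, 2×2×2 max pooling, transpose-convolution upsampling with
skip concatenation) plus a skeleton-guided stream of two blocks attached to
the deepest encoder outputs. Each block applies a residual block and a
skeleton-attention gate

    A = sigmoid(ReLU(conv1(t) + conv1(f)))        (A in [0.5, 1))

where `t` are the stream's features and `f` the encoder's; the gated
features are concatenated back into the decoder, and both streams end in a
1×1×1 convolution + sigmoid (likelihood maps `p` for the structure, `p̂` for
its skeleton).

**Loss.** Training minimises `L_D(p, g) + L_ST(p̂, ĝ)` where `L_D` is the
Dice loss and the sigmoid-adaptive Tversky loss

    L_ST = 1 − Σ σ(γ(p̂ᵢ − 0.5)) ĝᵢ / (α Σ p̂ᵢ + β Σ ĝᵢ),   α + β = 1

steepens gradients for low-confidence voxels. The closed-form
foreground/background gradient ratios (`2/(1−L_D) − 1`,
`(1/α)/(1−L_T) − 1`, and `γσ(z)(1−σ(z))/α · 1/(1−L_ST) − 1`) are exported
as diagnostics and verified against numerical gradients in the tests.

**Metrics.** Tree length detected rate `TR = Σ sᵢp̂ᵢ / Σ sᵢ`, branch
detection rate `BD` (floor rule: a branch counts only when fully covered;
a relaxed coverage threshold is available), and voxel-wise
precision/recall/F-measure.

## Worked example

```r
library(sgtube)

# a 48^3 phantom: depth-3 branching tree, exact mask + analytic centerline
sample <- generate_phantom(phantom_spec(seed = 7))
sample$mask
#> <binary_volume> 48 x 48 x 48 voxels, spacing 1 x 1 x 1 mm
#>   foreground voxels: 1248 (1.128%)

# skeletonize the mask and decompose into branches
sk <- skeletonize(sample$mask)
decompose_branches(sk)
#> <branch_set> 7 branches (67 voxels), 3 bifurcation voxels

# the loss family on a toy example
dice_loss(c(0.8, 0.4), c(1, 0))
#> [1] 0.2727273
stl_loss(c(0.8, 0.4), c(1, 0), stl_params(0.1, 0.9, 10))
#> [1] 0.0661038

# train the dual-stream network on phantoms and evaluate held-out ones
res <- phantom_experiment(seed = 1)
round(res$mean, 3)
#>        tr        bd precision    recall f_measure
#>     1.000     1.000     0.975     0.985     0.980
```

`tr` is the fraction of held-out ground-truth centerline voxels covered by
the binarized prediction; `bd` the fraction of branches detected at 0.8
coverage; the remaining columns are voxel-wise scores. The numbers above
are from the exact command shown (seed 1).

## Command-line interface

A thin CLI over the package functions lives at `inst/cli/skeltube`
(installed under `system.file("cli", "skeltube", package = "sgtube")`):

```sh
skeltube phantom --out case01 --seed 1
skeltube skeletonize --mask case01/mask.nii.gz \
    --out-skeleton sk.nii.gz --out-branches branches.json
skeltube losscurve --out curves.csv
skeltube train | predict | evaluate ...   # see --help of each subcommand
```

Volumes are NIfTI (`.nii.gz`), branch sets JSON, metric reports JSON.
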