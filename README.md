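# cellseg3d

Two-stage instance segmentation of densely packed cells in 3D membrane
microscopy volumes, for researchers working with plant or animal tissue
imaged through a membrane channel (apical meristems, root primordia,
ovules, early embryos). The package addresses the *clumped cell problem*:
when a voxel classifier misses a patch of membrane, the foreground masks of
neighboring cells fuse and downstream clustering merges them into one
instance.

## Method

**Stage one** classifies every voxel as background, membrane or
cell-foreground with a compact U-Net-style 3D network (~0.3 M parameters,
shape-exact for any cuboid extent) trained under a boundary-weighted,
confidence-regularized Dice loss. Non-foreground classes use

$$L_{\mathrm{others}} = 1 - \frac{2\sum_k p_k\,g_k\,w_k}{\sum_k p_k^2 + \sum_k g_k^2},$$

with reverse-distance-transform weights $w_k$ that are largest next to the
membranes; the foreground class replaces $p_k$ by $p_k/(p_k+\alpha)$
(default $\alpha = 0.1$), which penalizes low-confidence foreground — the
signature of impending clumping near membranes — much more heavily than
plain Dice while keeping a small residual penalty even at $p_k = 1$. The
total loss is $L = L_{\mathrm{fg}} + L_{\mathrm{others}}$, with the
closed-form gradient implemented and checked against finite differences.

**Stage two (TASCAN, touching-area clustering)** needs nothing from the
network. The foreground is pre-clustered into supervoxels by a seeded
watershed on the Euclidean distance transform; supervoxels sharing more
than half their surface with a neighbor are absorbed; the rest are merged
into cells wherever their touching area (shared voxel faces) satisfies
$S_{uv} \ge \texttt{min\_area}$ — the pipeline's single user-facing
hyperparameter (default 30 faces, the scale of a typical membrane hole).
Membrane and leftover foreground voxels finally join their nearest cell.
The merge criterion is symmetric, so the result is independent of
processing order.

The package also provides TIFF/HDF5 volume I/O with seam-free tiled
inference, a synthetic membrane-phantom generator (Voronoi cells, thin
bright membranes, noise, controllable membrane holes) with voxel-perfect
ground truth, and the evaluation metrics: per-cell Jaccard/Dice with
overall and cell-count summaries, adapted Rand error, and variation of
information split into over- and under-segmentation components.

## Worked example

Generate a phantom, derive its ground-truth masks, run the clustering
stage and evaluate:

```r
library(cellseg3d)

ph <- generate_phantom(phantom_spec(extent = c(96, 96, 96), n_cells = 40,
                                    noise_sd = 0, seed = 11))
masks <- semantic_masks_from_labels(ph$labels, membrane_thickness = 2)
seg <- segment_instances(masks, min_area = 30)
seg
#> instance_segmentation: 40 cells, 778688 labeled voxels
report <- evaluate_segmentation(seg$labels, ph$labels)
report
#> evaluation_report: 40 gt cells vs 40 predicted
#>   Avg JI 0.9942  Avg DSC 0.9971
#>   JI>0.7 1.000  DSC>0.7 1.000  JI>0.5 1.000  DSC>0.5 1.000
#>   ARE 0.0051  VOI split 0.0318  merge 0.0329 (bits)
```

All 40 cells are recovered exactly (`Avg JI` is the mean per-cell Jaccard
index over ground-truth cells; the small VOI terms come from membrane
voxels being split between abutting cells during nearest-cell assignment).
Training the classifier and running the full two-stage pipeline:

```r
train <- lapply(1:2, function(i)
  generate_phantom(phantom_spec(extent = c(64, 64, 64), n_cells = 30, seed = i)))
fit <- train_semantic_model(
  lapply(train, \(p) list(intensity = p$intensity, labels = p$labels)),
  train_config(cuboid_min = 28, cuboid_max = 36, batch_size = 1, steps = 450))
fit <- train_semantic_model(               # brief full-volume fine-tune
  lapply(train, \(p) list(intensity = p$intensity, labels = p$labels)),
  train_config(cuboid_min = 64, cuboid_max = 64, batch_size = 1, steps = 50),
  init = fit$net)
hold <- generate_phantom(phantom_spec(extent = c(64, 64, 64), n_cells = 30, seed = 99))
probs <- predict_semantic_volume(hold$intensity, fit$net)
seg <- segment_instances(semantic_argmax(probs), min_area = 30)
evaluate_segmentation(seg$labels, hold$labels)
```

A command-line front end is installed with the package
(`inst/cli/cellseg3d`) with `simulate`, `train`, `segment` and `evaluate`
subcommands over a YAML configuration.

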