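---
title: "Methods: two-stage 3D cell instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage 3D cell instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Volumetric membrane microscopy of dense tissue (plant meristems, early
animal embryos) shows cells as dark interiors separated by thin bright
membranes, one to a few voxels thick. Instance segmentation — one integer
label per cell — is usually run in two stages: a voxel classifier produces
background / membrane / cell-foreground masks, and a clustering step cuts
the foreground into individual cells. The recurring failure mode is the
*clumped cell problem*: wherever the classifier misses a patch of membrane,
the foreground masks of the two abutting cells fuse, and the clustering
stage merges them into one instance. `cellseg3d` implements a pipeline
built around that failure mode, with a single user-facing hyperparameter.

## Stage one: semantic segmentation

### Loss

Each non-foreground class contributes a boundary-weighted Dice term

$$L_{\mathrm{others}} = 1 - \frac{2\sum_k p_k g_k w_k}
{\sum_k p_k^2 + \sum_k g_k^2},$$

where $p_k$ is the predicted class probability of voxel $k$, $g_k$ the
binary ground truth and $w_k$ a per-voxel weight. The weights sit in the
numerator only; since they multiply $g_k$, only in-mask voxels matter. The
cell-foreground class replaces $p_k$ with $p_k / (p_k + \alpha)$:

$$L_{\mathrm{fg}} = 1 - \frac{2\sum_k \frac{p_k}{p_k+\alpha} g_k w_k}
{\sum_k \left(\frac{p_k}{p_k+\alpha}\right)^2 + \sum_k g_k^2}.$$

With the default $\alpha = 0.1$ the replacement rises steeply below
$p \approx 0.2$, flattens in the middle, and stays slightly below 1 at
$p = 1$. Two consequences drive the design. First, low-confidence
foreground — which concentrates near membranes, exactly where clumping
originates — is penalized much more heavily than under plain Dice, so the
optimizer prefers calling an ambiguous voxel membrane rather than weakly
foreground. Second, because the replacement never reaches 1, a perfect
binary prediction keeps a residual foreground penalty of
$1 - 2r/(r^2+1) = 0.004525$ with $r = 1/1.1$; the term keeps acting as a
confidence regularizer throughout training. The total loss is the
foreground term plus the *mean* of the background and membrane terms;
averaging (rather than summing) keeps the foreground term's relative scale
independent of how many auxiliary classes there are.

The closed-form gradient (implemented in `total_loss_gradient()`) is the
package's central correctness anchor: the test suite and the acceptance
script compare it against central finite differences of `total_loss()` on
random cuboids, to 1e-4 relative error.

Degenerate cuboids — a random crop can miss a class entirely — contribute 0
rather than NaN for that class's term (the both-empty denominator rule).

### Boundary weights

`reverse_distance_weights()` computes, per class, the Euclidean distance of
each in-mask voxel to the nearest out-of-mask voxel and maps it affinely so
that boundary-adjacent voxels get weight 1 and the deepest interior gets
`w_min` (default 0.5, configurable). Voxels outside the mask get weight 1;
they never contribute. A mask of uniform depth (e.g. a one-voxel-thick
membrane sheet) gets unit weights everywhere — there is no gradient of
depth to express. The exact normalization of the reverse distance transform
is a design choice of this package; keeping the weights in $(0, 1]$ bounds
every loss term in $[0, 1]$ and the total in $[0, 2]$.

The distance transform itself is an exact separable 3D squared-Euclidean
transform (lower-envelope algorithm) implemented in compiled code; it is
verified in the tests against a brute-force all-pairs oracle on small
volumes.

### Network

The classifier is a compact U-Net-style 3D network (about 0.3 M parameters
at the defaults: 3 levels, 16 base channels, width doubling per level,
budget 1.5 M). Each downsampling is a stride-2 convolution plus a residual
1×1×1 projection of the 2× average-pooled input; each upsampling is a
learned 2×2×2 transposed convolution whose output is trimmed on the
trailing (high-index) edges to match the corresponding encoder map before
skip concatenation. Trimming rather than padding makes the network
shape-exact for *any* cuboid extent, cubic or not — the property the tiled
inference relies on. The output head is a 1×1×1 convolution to three
channels followed by a softmax (the loss needs probabilities in $[0,1]$).
Convolutions use replicate ("clamp") padding rather than zero padding: a
crop edge, a tile edge and the true volume edge then all present the same
input statistics to the network, which removes the zero-pad distribution
shift between training crops and whole-volume inference.

The engine is written in the package's compiled code as im2col + SGEMM
convolutions with hand-derived backward passes, trained by Adam at a
constant learning rate (a decay schedule was evaluated and brought no
benefit at the short training lengths this package targets). Training
samples cuboids of a uniformly random extent per axis (defaults 56³–64³,
batch 7) at uniformly random origins; variable-size cuboids improve
robustness at cuboid interfaces. All randomness flows through fixed
Mersenne-Twister seeds; training is reproducible on one device (bit
equality across BLAS builds is not promised).

At inference, `plan_tiles()` covers the volume with overlapping tiles whose
*core* regions partition it exactly; per-tile probabilities are stitched
from cores only ("center-crop stitching"), discarding overlap margins. How
full volumes should be assembled from cuboid predictions is genuinely open;
center-crop stitching was chosen because it is seam-free by construction
and exactly reproduces a single-tile prediction when the tile covers the
volume.

## Stage two: TASCAN

Instance segmentation operates on the three masks only — it takes no
parameters from the network.

1. **Watershed pre-clustering.** The foreground mask's Euclidean distance
   transform is flooded from its local maxima (window maxima with Chebyshev
   separation `h_sep = 3`; plateau maxima closer than `h_sep` are fused
   into one seed). Flooding is a deterministic priority queue: higher
   distance first, FIFO on ties. Basins whose peak rises less than 1 voxel
   above their highest saddle are merged into the neighboring basin — the
   usual watershed tolerance. Without it, thin corner wedges of a cell and
   membrane-hole tunnels form shallow basins whose contact area is below
   `min_area` but whose surface is mostly membrane-facing, so no later rule
   can merge them and each would surface as a spurious instance.
2. **Touching graph.** Supervoxels are nodes with surface area $S_u$ (all
   exposed voxel faces, volume boundary included) and edges with touching
   area $S_{uv}$ (shared faces, 6-connectivity). Faces are the only
   geometry consistent with an *area* of contact; `min_area = 30` therefore
   means 30 shared faces.
3. **Absorption.** A supervoxel sharing more than half ($ratio = 0.5$) of
   its surface with a single neighbor is merged into it, largest touching
   area first, recomputing after each merge until a fixpoint. This removes
   small watershed fragments enclosed by their parent cell.
4. **Clustering.** Cells are the connected components of the subgraph with
   edges $S_{uv} \ge$ `min_area`. The criterion is symmetric in $u$ and
   $v$, so the partition is independent of processing order — verified
   against brute-force transitive closure over random graphs under random
   node orderings.
5. **Assignment.** Membrane voxels and any foreground voxels left without
   an instance take the label of the nearest instance voxel (exact
   Euclidean distance, smallest instance id on ties). Instances are
   renumbered 1..K by decreasing volume.

`min_area` is the pipeline's only user-facing hyperparameter. Sweeping it
from 1 upward moves the instance count monotonically from the number of
connected foreground components up to the number of (absorbed) supervoxels;
nothing else changes and the network is never retrained. Its default, 30
faces, reflects the typical size of membrane holes: a hole must let two
cells' foregrounds share at least `min_area` faces before they are merged
into one cell.

## The synthetic phantom

`generate_phantom()` builds volumes that emulate densely packed tissue:
greedy farthest-point seeds in the interior, a Voronoi tessellation as the
cell map (convex, space-filling cells, as in plant/epithelial tissue),
bright membranes of configurable thickness between differing labels and at
the tissue border, additive Gaussian noise (default SD 0.05 relative to a
membrane–interior contrast of 1), and optional membrane holes: a chosen
fraction of cell–cell interfaces loses its intensity signal within a given
radius, reproducing the image-level cause of clumping.
`punch_membrane_holes()` applies the same perforation at the mask level
(membrane → foreground), so the clustering stage can be stressed with
controlled adhesions independently of any network.

What the phantom does *not* model: point-spread blur, attenuation with
depth, anisotropic sampling, irregular (non-convex) cell shapes, nuclei.
Passing tests on phantoms therefore demonstrate the algorithmic contracts —
loss behavior, shape-exactness, watershed/merging rules, metric
definitions — not microscope-grade segmentation accuracy on real tissue.

## Evaluation metrics

Per ground-truth cell (background excluded), the matched prediction is the
instance with maximal voxel overlap (ties to the smaller id; the matching
rule is this package's choice). Overall accuracy is the mean Jaccard index
and Dice coefficient over ground-truth cells; cell-count accuracy is the
fraction of cells with JI (or DSC) strictly above 0.7 (or 0.5).
Averaging over ground-truth cells (not predictions) was chosen because the
count accuracies are phrased as fractions of *cells*. The adapted Rand
error is 1 minus the pair-counting F-score computed from the
prediction × truth contingency table over voxels with nonzero ground
truth. The variation of information is reported as
`voi_split` $= H(\mathrm{pred}\mid\mathrm{gt})$ (over-segmentation) and
`voi_merge` $= H(\mathrm{gt}\mid\mathrm{pred})$ (under-segmentation), in
bits, over voxels foreground in either partition.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen as the smallest sizes at
which every mechanism is exercised: gradient checks on 6³ cuboids;
clustering oracles on graphs of up to 12 nodes; stage-2 recovery on a 96³
phantom with 40 cells (about 17 000 voxels per cell, comparable to
well-resolved tissue); and an end-to-end run that trains the default
network for 500 steps of batch 1 from two 64³ phantoms: 450 steps on
28³–36³ variable-size crops followed by 50 warm-started steps on
full-volume 64³ cuboids. The second phase is the variable-cuboid idea
taken to its endpoint — the final training distribution equals the
inference distribution, volume borders included. Pilot runs showed why it
matters at this scale: crop-only training leaves the true volume border
(the rarest pattern in the crop distribution) unstable, and a thin ring of
spuriously foreground voxels there splinters into a volatile number of
tiny extra instances; a short full-volume phase removes the ring
reproducibly. The budget still does not train the classifier to
convergence; the end-to-end check asserts recovery quality (average JI,
instance count within 10%), not final accuracy.

## Known limitations

* The network engine is single-device, CPU-oriented; there is no GPU path.
* Training determinism holds per device; different BLAS builds may differ
  in the last float digit.
* The phantom's convex cells underrepresent the irregular shapes of, e.g.,
  root primordia; `min_area` may need retuning on such data ("for an image
  with a much larger cell size, the value should be increased" is the
  operative intuition).
* HDF5 support covers one 3D dataset per key (uint32 or float64); no
  chunking/compression options are exposed.
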