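---
title: "Reconstructing 3D spine volumes from bi-planar radiographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D spine volumes from bi-planar radiographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plain radiographs are cheap, fast and low-dose, but they collapse the spine
onto two dimensions; CT recovers the 3D anatomy at the cost of dose and
access. `biplanar3d` implements an automatic 2D-to-3D pathway: given two
orthogonal simulated radiographs of the spine — an anteroposterior (AP) and
a lateral (Lat) view — a conditional generative adversarial network emits a
binary 3D spine volume. The package covers the whole experimental loop on
one CPU: a procedural CT phantom generator with paired ground truth, an
empirical bone-signal enhancement step, a parallel-beam projector that
renders the conditioning radiographs, the GAN itself with a from-scratch
training engine, volumetric and projection similarity metrics, and a
cross-validated experiment grid with rank-based statistics.

# The synthetic world

Clinical chest CT with expert spine labels cannot ship with a package, so
the data module builds phantoms instead. Each phantom is a chest-like HU
volume: an air background (−1024 HU), a soft-tissue body ellipse (40 HU)
containing two lung regions (−800 HU), and a spinal column of
vertebra-like bodies — an elliptic-cylinder trabecular core (400 HU)
wrapped in a one-voxel cortical shell (1200 HU) with a thin posterior
spinous process — separated by disc-height gaps at 80 HU. The paired
ground-truth mask is 1 exactly on bone-class voxels. Defaults: ten
vertebrae of 18 mm with 6 mm discs, 12 mm body radius, a 64×64×128 grid at
2 mm isotropic spacing ("desk scale"; a 128×128×256 / 1 mm grid is one
argument away). Inter-subject variation comes from per-phantom jitter:
±15% on the global radius, ±5% per vertebra, and a mild sinusoidal
posteroanterior curve of the column. Additive Gaussian HU noise (default
SD 15, clamped at ±6 SD and at the −1024 floor) models acquisition noise.

What the phantom *does* reproduce: the HU strata the enhancement step
discriminates on, disc gaps and posterior processes (the structures whose
blurring is the known failure mode of this reconstruction task), and a
non-degenerate distribution for the GAN to learn. What it does *not*:
realistic vertebral shape, ribs, scoliosis or pathology. A green
end-to-end test therefore establishes that the pipeline learns and that
enhancement helps *on this family of geometries* — not clinical accuracy.

# Bone-signal enhancement

The enhancement operator is a fixed per-voxel chain applied to raw HU:

1. threshold filter — values below −1024 are clamped to −1024; values
   *above 1000 are set to 0*;
2. body mask — 1 where HU > −400, else 0; applied multiplicatively;
3. rescale inversion — signal = (HU − RescaleIntercept)/RescaleSlope,
   i.e. back to scanner storage units (with the common slope 1 /
   intercept −1024, air maps to 0 and water to 1024);
4. windowing — signal ≤ 874 or ≥ 2024 becomes 0;
5. amplification — signal > 1300 is tripled.

The chain is implemented literally, including two consequences worth
knowing. First, dense bone above 1000 HU is zeroed by step 1 and then
mapped to the background level by step 3 — counter-intuitive, but that is
what the printed rule says; a `drop_high_hu_rule` flag provides a clamping
variant, with the literal rule as the default. Second, masked-out voxels
become 0 HU, which the rescale inversion maps to 1024 — *inside* the
window — so air and lung flatten to a uniform non-zero background rather
than to black. The net effect on the radiograph is exactly the intended
one: soft-tissue and lung contrast collapses while trabecular bone
(windowed and tripled) dominates. Nonzero enhanced signals always lie in
(874, 1300] ∪ (3900, 6072), a property the test-suite asserts.

The control condition ("original") is defined as the rescale inversion
alone on floor-clamped HU, with no masking, windowing or amplification.
The source text never defines its un-enhanced pathway beyond naming it;
rescale-only is the minimal reading and is documented as this package's
choice.

# Radiograph simulation

The reference workflow simulated radiographs with a GPU cone-beam toolbox
whose geometry parameters are not stated. This package uses a parallel-beam
forward projector instead: pixel (u, w) is the sum of signal along the
projection axis times the voxel spacing (AP integrates along y, Lat along
x). Parallel beams keep two exactly testable conservation laws — the
detector sum equals the volume sum times the axis spacing, and projection
is linear in the volume — which the acceptance suite checks at 1e-9.

Intensities follow a Beer–Lambert transfer, pixel = 1 − exp(−k·∫signal),
with a single k shared by both views. Because no intensity transfer is
stated in the source, k defaults to the value mapping the median
*through-bone* ray to 0.7 (a radiograph-like mid-grey): when the
segmentation is available — as it is whenever training cases are
prepared — bone rays are the detector pixels the projected mask touches;
without a mask the median nonzero ray is used. Either way k is computed
deterministically per volume. The projections are cropped to the mask-tight bounding box of the
spine dilated by 8 voxels and resampled bilinearly to the detector shape,
scale × (128, 256). Bilinear weights clamp the source coordinate *before*
flooring; clamping afterwards treats the two image edges asymmetrically
and breaks the left-right symmetry of symmetric phantoms (a bug the
symmetry test caught). Stored images are z-aligned (row 1 = inferior); the
radiographic superior-first convention is applied only when images are
exported to files.

# The conditional GAN

**Generator.** Two weight-independent 2D encoders (AP and Lat), each eight
convolution blocks with channels (64, 64, 64, 64, 32, 16, 8, 4), a 7×7
first kernel and 4×4 kernels after, each block Conv → batch norm → ReLU
with a residual add where input and output channels match (blocks 2–4),
and 2×2 max pooling on the first log2(W/4) blocks so every scale ends in a
4×8 bottleneck map with 4 channels. Per-view 2D decoders upsample the
bottleneck (nearest-neighbour + convolution, to avoid checkerboard
artifacts), concatenating skip connections from the last four encoder
blocks (resized nearest-neighbour when resolutions differ). The central 3D
decoder starts from the two bottlenecks tiled along their missing axis —
AP features live on (x, z) and are replicated along y, Lat features on
(y, z) replicated along x — permuted to a common (x, y, z, channel) order
and averaged. Each central stage is nearest-neighbour ×2 upsampling, a
4³ convolution, batch norm and ReLU; at stages where a view-decoder
feature of matching resolution exists, the central features and the two
tiled view features are averaged. A final 3³ convolution and sigmoid
yield a probability volume of shape scale × (128, 128, 256). The published
figure does not fully specify which tensors its "Add" marks combine;
the wiring above is this package's documented resolution, not a claim
about the original.

**Discriminator.** A 3D Patch-GAN: the candidate volume is concatenated
with the two conditioning radiographs tiled along their projection axes
(three input channels), passed through four stride-2 4³ convolutions with
channels (32, 64, 128, 256), LeakyReLU (slope 0.2) and batch norm from
layer 2, and closed by a single-channel 4³ convolution. The raw patch
scores feed least-squares losses; there is no final activation.

**Losses.** Least-squares adversarial objectives — discriminator
½E[(D(x)−1)²] + ½E[D(G(z))²], generator ½E[(D(G(z))−1)²] — plus a
voxelwise MSE reconstruction term, combined as λ₁·LSGAN + λ₂·MSE with
λ₁ = 2, λ₂ = 100. The reconstruction target is the binary mask as float;
the discriminator sees probability maps during training because
thresholding is not differentiable. Inference binarises at probability
≥ 0.4 (the stated threshold; the tie side at exactly 0.4 is this
package's choice).

**Training.** Per minibatch both players' gradients are evaluated at the
current parameters sharing one forward pass on the generated volume (the
fake is detached for the discriminator's own update), then both take one
Adam step — the simultaneous-update reading of the minimax game, chosen
over the strictly sequential one because it removes a third discriminator
forward pass per step on a CPU budget. Adam uses betas (0.5, 0.999),
batch size 4 at desk scale, and a default learning rate of 5e-3. The
usual conditional-GAN recipe (2e-4) assumes tens of thousands of updates;
desk-scale schedules here run tens to hundreds, and at 2e-4 the optimiser
cannot move the network far enough to matter (an Adam step moves each
weight by roughly the learning rate). Rates of 1e-3, 2e-3 and 5e-3 were
compared once on the single-phantom overfit task and a held-out two-fold
phantom experiment; 5e-3 converged fastest, generalised best and remained
stable, and is the package default (the textbook 2e-4 is one argument
away).

**Engine.** No deep-learning framework for R is available in the
dependency set, so the conv2d/conv3d forward and backward passes are
im2col + GEMM kernels (Rcpp/Armadillo), with batch norm, pooling, tiling
and Adam in R. GEMMs run in single precision (about twice the
double-precision throughput on one CPU; master weights, losses and every
non-GAN computation — notably SSIM — stay double). 3D convolutions
process the output z axis in bounded slabs so full-scale 128×128×256
volumes fit comfortably in memory. Every gradient path was verified
against central finite differences in a double-precision build during
development; the installed suite checks the behavioural consequence (a
small gradient step strictly decreases the objective) plus exhaustive
shape and loss-arithmetic contracts.

# Evaluation metrics

Volumetric overlap: Dice 2|A∩B|/(|A|+|B|), Jaccard |A∩B|/|A∪B|, and
overlap volume |A∩B|/min(|A|,|B|). Two empty volumes give DSC = JSC = 1
with a warning (vacuous agreement); OV is an error there because its
denominator vanishes — inside evaluation loops an empty prediction yields
OV = NA instead (`strict = FALSE`). The identity DSC = 2·JSC/(1+JSC) and
the ordering JSC ≤ DSC ≤ OV are asserted on hundreds of random pairs.

Projection similarity: SSIM between the AP and Lat sum projections of the
binary volumes (min-max normalised to [0, 1]; an all-constant projection
normalises to zeros). The SSIM combination uses the standard product form
with unit exponents and stabilisers C1 = (0.01 L)², C2 = (0.03 L)²,
C3 = C2/2 with L = 1 — the exponents are not stated in the source, and
this is the universal reference choice. The 11×11 sliding window is
Gaussian-weighted (σ 1.5), matching the canonical implementation; a
uniform-window flag exists. Windows are evaluated at valid positions
only. Whether the original work projected binary masks or
radiograph-style intensities is not stated; binary-mask projection is the
documented default here.

# Cross-validation and statistics

`kfoldSplits()` shuffles ids by seed into k near-equal folds; split f
tests on fold f, validates on fold (f+1) mod k and trains on the rest —
the 8:1:1 ratio at k = 10. At k = 2 that rule would leave no training
data, so the validation set is carved from the non-test half (one ninth
of it, rounded up); this is the package's own repair of a corner the
source design leaves undefined, and it is what the scaled-down two-fold
experiments use. The printed fold sizes of the smallest clinical subset
(256/34/34 for 333 cases) do not sum to the total and are not reproduced;
the ratio principle is implemented instead.

Condition contrasts use the two-sided Mann–Whitney U test (exact
enumeration for pooled n ≤ 12 without ties; otherwise the normal
approximation with tie correction and *no* continuity correction, so
identical samples give p = 1 exactly). Dataset-size contrasts within a
condition use Kruskal–Wallis with tie correction; the degenerate
all-equal input is defined as H = 0, p = 1. Both wrap the standard
`stats` implementations; exhaustive enumeration oracles in the test suite
keep the check independent. No multiple-testing correction is applied
(α = 0.05 per test), matching the source analysis. `runGrid()` executes
the (signal condition × dataset size × fold) grid with all seeds derived
from one master seed and returns a tidy long table;
`significanceTable()` lays out the per-metric condition and size
contrasts.

# Scaled-down replication: what is claimed

Full-scale training (a thousand clinical CTs, GPU, 50 epochs at
128×128×256) is out of reach on one CPU, so the end-to-end acceptance
experiment is a directional replication at scale 1/4: 40 phantoms, 2-fold
cross-validation, 15 epochs, enhanced signal condition — requiring
held-out mean Dice ≥ 0.5 and at least twice the untrained-generator
baseline — plus an enhanced-vs-original comparison averaged over three
seeds (part one runs the full two-fold CV; part two compares conditions
on fold 0 only, because running every fold × seed × condition would
treble an already quarter-hour computation; the shared enhanced run is
reused). The claim a green run supports is that the pipeline learns the
conditional mapping and that empirical bone enhancement does not hurt —
mirroring the direction, not the magnitude, of the published improvement.

# Numerical choices and degenerate inputs

* Batch-norm: population statistics within a batch; running estimates
  (momentum 0.9) used at inference. A constant channel normalises to zero
  via the ε = 1e-5 stabiliser rather than dividing by zero.
* Weight init: He-normal scaled by fan-in; biases zero; all randomness
  flows through seeded R RNG streams that are saved and restored, so
  library calls never perturb the caller's RNG.
* Child seeds derive from master seeds by a fixed 32-bit LCG-style hash,
  keeping every derived seed below 2³¹.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.
* NIfTI I/O is a minimal NIfTI-1 codec written for this package (no R
  NIfTI reader is available in the dependency set): 348-byte header,
  little- or big-endian detection, uint8/int16/int32/float32/float64,
  gzip transparently; `scl_slope`/`scl_inter` are applied on read. DICOM
  series reading is out of scope; the DICOM rescale metadata the
  enhancement step needs lives in `CTVolume` slots and JSON sidecars.
* Trilinear resampling is separable (three dense 1D interpolation
  matrices); the new grid preserves the physical extent within one voxel
  per axis.

# Known limitations

The phantom family is geometrically simple, so absolute metric values are
not comparable to clinical numbers. The cone-beam projection mode is
intentionally absent (parallel beam only); scatter, beam hardening and
spectral effects are not modelled. The GAN engine is single-threaded by
design apart from BLAS; full-scale training is possible but slow and is
not exercised by the tests beyond shape contracts. The statistical
harness assumes independent folds, which 2-fold cross-validation only
approximates.
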