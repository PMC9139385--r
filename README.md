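# biplanar3d

Automatic reconstruction of a three-dimensional binary spine volume from
two orthogonal (anteroposterior and lateral) simulated radiographs, for
researchers studying low-dose 2D-to-3D skeletal imaging pipelines.

A single spinal radiograph collapses the vertebral column onto a plane;
CT recovers the 3D anatomy at a much higher dose. This package implements
an end-to-end conditional-GAN pathway between the two on ordinary CPU
hardware:

* **Phantoms** — a procedural chest-CT generator (air / lung / soft
  tissue / disc / trabecular / cortical HU strata; vertebra-like bodies
  with cortical shells, posterior spinous processes and disc gaps) with
  paired ground-truth masks, standing in for clinical data.
* **Bone-signal enhancement** — an empirical per-voxel chain on raw HU:
  threshold filter (clamp below −1024, zero above 1000), body mask
  (HU > −400), rescale inversion `(HU − intercept)/slope`, bone window
  (zero outside (874, 2024)) and ×3 amplification above 1300.
* **Radiograph simulation** — a parallel-beam projector: line integrals
  ∫signal ds along y (AP) or x (Lat), a Beer–Lambert intensity transfer
  `1 − exp(−k·∫)`, spine-ROI cropping, detector resampling.
* **The 2D→3D GAN** — dual-view 2D encoders (channels 64,64,64,64,32,16,
  8,4; 7×7 then 4×4 kernels), per-view decoders with skip connections,
  a fused central 3D decoder (view features tiled along their projection
  axes and averaged), a sigmoid probability volume of shape
  scale·(128,128,256) binarised at 0.4; a 3D Patch-GAN discriminator
  (channels 32,64,128,256, 4³ kernels); least-squares adversarial losses
  `½E[(D(x)−1)²] + ½E[D(G(z))²]` and `½E[(D(G(z))−1)²]` combined with a
  voxel MSE term as `λ₁·LSGAN + λ₂·MSE`, λ₁ = 2, λ₂ = 100. Training runs
  on a from-scratch Rcpp/Armadillo im2col+GEMM engine with Adam —
  no deep-learning framework required.
* **Evaluation** — Dice `2|A∩B|/(|A|+|B|)`, Jaccard `|A∩B|/|A∪B|`,
  overlap volume `|A∩B|/min(|A|,|B|)`, and SSIM (11×11 Gaussian window)
  of the AP/Lat sum projections; k-fold cross-validation with a rolling
  validation fold; Mann–Whitney U and Kruskal–Wallis comparisons across
  signal conditions and dataset sizes.

See the methods vignette
(`vignettes/biplanar-spine-reconstruction.Rmd`) for the model details,
parameter choices and limitations.

## Worked example

```r
library(biplanar3d)

spec <- phantomSpec(nVertebrae = 10, seed = 1)
phantom <- generatePhantom(spec)
phantom$ct
#> CTVolume 64x64x128, spacing 2x2x2 mm, HU range [-1024, 1254]
phantom$seg
#> SegmentationVolume 64x64x128, 9638 foreground voxels (1.8%)

enhanced <- enhanceVolume(phantom$ct)
enhanced
#> EnhancedVolume (enhanced) 64x64x128, signal range [1000, 4447]

pair <- makeBiplanar(enhanced, geometry = 1/4,
                     crop = defaultCropROI(phantom$seg), sourceId = "demo")
pair
#> DRRPair 'demo': AP and Lat 32x64 radiographs in [0, 1]

dataset <- generateDataset(16, spec, seed = 1)
cases <- lapply(seq_along(dataset), function(i)
  prepareTrainingCase(dataset[[i]]$ct, dataset[[i]]$seg, "enhanced",
                      scale = 1/4, sourceId = sprintf("case%02d", i)))
fit <- trainGan(cases[1:15], generatorConfig(1/4), discriminatorConfig(),
                lossWeights(), trainConfig(epochs = 15, batchSize = 4, seed = 1))
round(tail(fit$history, 3), 4)
#>    epoch g_loss  g_adv g_recon d_loss val_loss
#> 13    13 4.9789 0.1603  0.0466 0.2040       NA
#> 14    14 4.8313 0.1636  0.0450 0.1832       NA
#> 15    15 4.6574 0.1884  0.0428 0.1573       NA

pred <- predictVolume(fit$generator, cases[[16]]$pair)
evaluateCase(pred, cases[[16]]$gt, caseId = "case16", strict = FALSE)
#> MetricReport 'case16': DSC 0.7276  JSC 0.5718  OV 0.8313  SSIM_AP 0.4884  SSIM_Lat 0.3235
```

Reading the numbers: the generator loss decomposes into its adversarial
(`g_adv`) and reconstruction (`g_recon`) parts — with λ₂ = 100 the MSE
term dominates and falls steadily. On the held-out phantom, a Dice of
0.73 means the predicted and true spine volumes overlap at 73% of their
mean size; OV 0.83 says 83% of the smaller volume is covered; the
projection SSIMs are lower because thin posterior processes blur first.
A fifteen-phantom, fifteen-epoch CPU run is a deliberately small
demonstration, not a converged model.

`runGrid()` orchestrates the full (signal condition × dataset size ×
fold) experiment and `significanceTable()` the rank-test comparisons.

## Command line

A thin CLI wraps the same functions (installed at
`inst/cli/biplanar3d`, or call `biplanar3d::mainCli()` directly):

```sh
biplanar3d phantom --n 40 --seed 7 --out data/ --scale 0.5
biplanar3d enhance --in data/case001_ct.nii.gz --out sig.nii.gz
biplanar3d drr     --in data/case001_ct.nii.gz --mask data/case001_mask.nii.gz \
                   --out-prefix case001 --scale 0.25
biplanar3d train   --data data/ --scale 0.25 --epochs 15 --seed 7 --out run/
biplanar3d predict --model run/gen.rds --ap case001 --lat case001 --out pred.nii.gz
biplanar3d evaluate --pred preds/ --gt gts/ --out metrics.csv
biplanar3d crossval --config grid.json --out results/
```

Volumes are NIfTI (`.nii`/`.nii.gz`); every artifact gets a JSON sidecar
with the seed and a config digest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, by running the installed package, the worked-example outputs
of the bone-enhancement rules — the threshold filter on −2000 HU and
1500 HU, the body mask on 0 HU, and the windowing rule on an imaging
signal of 800 — with the probe values planted in a phantom-derived CT
volume and pushed through the full enhancement pipeline, and writes them
as JSON.
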