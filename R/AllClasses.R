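#' @useDynLib biplanar3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif median pnorm kruskal.test wilcox.test dnorm predict
#' @importFrom utils write.csv read.csv head tail
NULL

# ---------------------------------------------------------------- volumes

#' CT volume in Hounsfield units
#'
#' A 3D voxel grid of Hounsfield-unit (HU) values with voxel spacing and the
#' DICOM rescale metadata (slope/intercept mapping stored values to HU).
#' The axis convention is fixed: x runs left to right, y posterior to
#' anterior, z inferior to superior.
#'
#' @slot voxels 3D numeric array of HU values.
#' @slot spacingMm numeric(3), per-axis voxel size in mm.
#' @slot rescaleSlope,rescaleIntercept DICOM rescale transform
#'   (HU = slope * stored + intercept); carried as metadata, the voxel data
#'   are already in HU.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacingMm = "numeric",
                 rescaleSlope = "numeric", rescaleIntercept = "numeric"),
  prototype(rescaleSlope = 1, rescaleIntercept = -1024))

setValidity("CTVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3) return("voxels must be a 3D array")
  if (!all(is.finite(v))) return("voxels must be finite")
  if (length(object@spacingMm) != 3 || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive values")
  if (length(object@rescaleSlope) != 1 || object@rescaleSlope == 0)
    return("rescaleSlope must be a non-zero scalar")
  TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D array of HU values.
#' @param spacingMm per-axis voxel size (mm).
#' @param rescaleSlope,rescaleIntercept DICOM rescale metadata.
#' @return A [CTVolume-class] object.
#' @export
ctVolume <- function(voxels, spacingMm = c(1, 1, 1),
                     rescaleSlope = 1, rescaleIntercept = -1024) {
  new("CTVolume", voxels = voxels, spacingMm = as.numeric(spacingMm),
      rescaleSlope = rescaleSlope, rescaleIntercept = rescaleIntercept)
}

#' Binary spine segmentation on a CT grid
#'
#' @slot mask 3D array with values in {0, 1}.
#' @slot spacingMm numeric(3) voxel size in mm.
#' @export
setClass("SegmentationVolume",
  representation(mask = "array", spacingMm = "numeric"))

setValidity("SegmentationVolume", function(object) {
  m <- object@mask
  if (length(dim(m)) != 3) return("mask must be a 3D array")
  if (!all(m %in% c(0, 1))) return("mask values must be strictly binary")
  if (length(object@spacingMm) != 3 || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive values")
  TRUE
})

#' Construct a SegmentationVolume
#' @param mask 3D binary array.
#' @param spacingMm per-axis voxel size (mm).
#' @return A [SegmentationVolume-class] object.
#' @export
segmentationVolume <- function(mask, spacingMm = c(1, 1, 1)) {
  new("SegmentationVolume", mask = mask, spacingMm = as.numeric(spacingMm))
}

#' Imaging-signal volume (original or bone-enhanced)
#'
#' Holds the non-negative imaging-signal values obtained from a CT volume
#' either by the plain rescale inversion (provenance "original") or by the
#' empirical bone-signal enhancement algorithm (provenance "enhanced").
#'
#' @slot signal 3D non-negative numeric array.
#' @slot spacingMm numeric(3) voxel size in mm.
#' @slot provenance "original" or "enhanced".
#' @export
setClass("EnhancedVolume",
  representation(signal = "array", spacingMm = "numeric", provenance = "character"))

setValidity("EnhancedVolume", function(object) {
  if (length(dim(object@signal)) != 3) return("signal must be a 3D array")
  if (!object@provenance %in% c("original", "enhanced"))
    return("provenance must be 'original' or 'enhanced'")
  if (object@provenance == "enhanced" && any(object@signal < 0))
    return("enhanced signal must be non-negative")
  if (length(object@spacingMm) != 3 || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive values")
  TRUE
})

# ------------------------------------------------------------- projection

#' Projection geometry for one radiographic view
#'
#' @slot mode "parallel" (default) or "cone".
#' @slot view "AP" or "Lat".
#' @slot attenuationScale per-mm attenuation coefficient k of the intensity
#'   model 1 - exp(-k * integral); NA means choose automatically so the
#'   median through-bone ray maps near 0.7.
#' @slot detectorShape integer(2), detector width x height in pixels.
#' @slot sourceDistanceMm source-to-axis distance (cone mode only).
#' @export
setClass("ProjectionGeometry",
  representation(mode = "character", view = "character",
                 attenuationScale = "numeric", detectorShape = "integer",
                 sourceDistanceMm = "numeric"),
  prototype(mode = "parallel", attenuationScale = NA_real_,
            sourceDistanceMm = 1000))

setValidity("ProjectionGeometry", function(object) {
  if (!object@mode %in% c("parallel", "cone")) return("mode must be parallel or cone")
  if (!object@view %in% c("AP", "Lat")) return("view must be AP or Lat")
  if (length(object@detectorShape) != 2 || any(object@detectorShape < 1))
    return("detectorShape must be 2 positive integers")
  k <- object@attenuationScale
  if (!is.na(k) && k <= 0) return("attenuationScale must be > 0")
  TRUE
})

#' Construct a ProjectionGeometry
#' @param view "AP" or "Lat".
#' @param detectorShape integer(2) detector size (width, height).
#' @param mode "parallel" or "cone".
#' @param attenuationScale per-mm attenuation k (NA = automatic).
#' @param sourceDistanceMm source distance for cone mode.
#' @return A [ProjectionGeometry-class] object.
#' @export
projectionGeometry <- function(view, detectorShape = c(128L, 256L),
                               mode = "parallel", attenuationScale = NA_real_,
                               sourceDistanceMm = 1000) {
  new("ProjectionGeometry", view = view, mode = mode,
      detectorShape = as.integer(detectorShape),
      attenuationScale = attenuationScale, sourceDistanceMm = sourceDistanceMm)
}

#' A bi-planar pair of simulated radiographs
#'
#' AP and Lat digitally reconstructed radiographs of one case, both in
#' [0, 1], sharing the detector shape. Rows of the image matrices index the
#' detector column (x for AP, y for Lat); columns index z (inferior first).
#'
#' @slot ap,lat numeric matrices in [0, 1].
#' @slot geometry list of two [ProjectionGeometry-class] records (ap, lat).
#' @slot sourceId case identifier.
#' @export
setClass("DRRPair",
  representation(ap = "matrix", lat = "matrix", geometry = "list",
                 sourceId = "character"))

setValidity("DRRPair", function(object) {
  if (!identical(dim(object@ap), dim(object@lat)))
    return("ap and lat must share detector shape")
  rng <- range(object@ap, object@lat)
  if (rng[1] < 0 || rng[2] > 1) return("radiograph values must lie in [0, 1]")
  TRUE
})

# ----------------------------------------------------------------- specs

#' Specification of a procedural spine phantom
#'
#' Describes a synthetic chest-CT stand-in: a soft-tissue body ellipse with
#' two lung regions and a stack of vertebra-like bodies (trabecular core,
#' one-voxel cortical shell, posterior spinous process) separated by disc
#' gaps, plus Gaussian HU noise.
#'
#' @slot nVertebrae number of vertebral bodies (>= 1).
#' @slot vertebraHeightMm,discHeightMm,bodyRadiusMm,processLengthMm
#'   anatomical lengths in mm (all > 0).
#' @slot huLevels named numeric of HU per tissue class: air, lung, soft,
#'   disc, trabecular, cortical; all within [-1024, 3000].
#' @slot noiseSd additive Gaussian HU noise SD (clamped at +-6 SD and at
#'   the -1024 floor).
#' @slot gridShape integer(3) voxel grid size.
#' @slot spacingMm numeric(3) voxel size in mm.
#' @slot seed integer RNG seed; the phantom is a deterministic function of
#'   the spec.
#' @export
setClass("PhantomSpec",
  representation(nVertebrae = "integer", vertebraHeightMm = "numeric",
                 discHeightMm = "numeric", bodyRadiusMm = "numeric",
                 processLengthMm = "numeric", huLevels = "numeric",
                 noiseSd = "numeric", gridShape = "integer",
                 spacingMm = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@nVertebrae < 1) return("nVertebrae must be >= 1")
  lens <- c(object@vertebraHeightMm, object@discHeightMm,
            object@bodyRadiusMm, object@processLengthMm)
  if (any(lens <= 0)) return("all lengths must be > 0")
  need <- c("air", "lung", "soft", "disc", "trabecular", "cortical")
  if (!all(need %in% names(object@huLevels)))
    return(paste("huLevels must name:", paste(need, collapse = ", ")))
  if (any(object@huLevels < -1024) || any(object@huLevels > 3000))
    return("huLevels must lie within [-1024, 3000]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@gridShape) != 3 || any(object@gridShape < 4))
    return("gridShape must be 3 positive integers")
  if (length(object@spacingMm) != 3 || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive lengths")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe the desk-scale stated world: a 64 x 64 x 128 grid at
#' 2 mm isotropic spacing holding ten vertebrae, with HU levels placing
#' trabecular bone inside and soft tissue outside the empirical bone
#' window. A full-scale 128 x 128 x 256 grid at 1 mm is configurable.
#'
#' @param nVertebrae vertebra count.
#' @param vertebraHeightMm,discHeightMm,bodyRadiusMm,processLengthMm sizes in mm.
#' @param huLevels named HU values (air, lung, soft, disc, trabecular, cortical).
#' @param noiseSd HU noise standard deviation.
#' @param gridShape integer(3) grid.
#' @param spacingMm numeric(3) voxel size in mm.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(nVertebrae = 3, seed = 1)
#' @export
phantomSpec <- function(nVertebrae = 10L, vertebraHeightMm = 18,
                        discHeightMm = 6, bodyRadiusMm = 12,
                        processLengthMm = 22,
                        huLevels = c(air = -1024, lung = -800, soft = 40,
                                     disc = 80, trabecular = 400,
                                     cortical = 1200),
                        noiseSd = 15, gridShape = c(64L, 64L, 128L),
                        spacingMm = c(2, 2, 2), seed = 1L) {
  new("PhantomSpec", nVertebrae = as.integer(nVertebrae),
      vertebraHeightMm = vertebraHeightMm, discHeightMm = discHeightMm,
      bodyRadiusMm = bodyRadiusMm, processLengthMm = processLengthMm,
      huLevels = huLevels, noiseSd = noiseSd,
      gridShape = as.integer(gridShape), spacingMm = as.numeric(spacingMm),
      seed = as.integer(seed))
}

# ------------------------------------------------------------ GAN configs

#' Generator architecture configuration
#'
#' Encodes the dual-view 2D encoder / fused 3D decoder generator: eight
#' Conv2D encoder blocks with channel schedule (64, 64, 64, 64, 32, 16, 8,
#' 4), a 7x7 first kernel and 4x4 kernels elsewhere, a 4 x 4 x 8 x 4
#' bottleneck, per-view 2D decoders and a central 3D decoder whose
#' upsampling chains shrink with the resolution scale. At scale 1 the
#' output is 128 x 128 x 256.
#'
#' @slot encoderChannels integer(8) channel schedule.
#' @slot firstKernel,otherKernel convolution kernel sizes.
#' @slot bottleneckShape integer(4) (x, y, z, channels) at the fusion point.
#' @slot viewDecoderUps,centralDecoderUps upsampling-stage counts at full
#'   scale (truncated proportionally at scale < 1).
#' @slot decoderChannels full-scale central-decoder channel schedule; the
#'   last \code{centralDecoderUps} entries are used at reduced scale.
#' @slot scale resolution multiplier, one of 1, 1/2, 1/4.
#' @slot outputShape integer(3) generated volume shape.
#' @export
setClass("GeneratorConfig",
  representation(encoderChannels = "integer", firstKernel = "integer",
                 otherKernel = "integer", bottleneckShape = "integer",
                 viewDecoderUps = "integer", centralDecoderUps = "integer",
                 decoderChannels = "integer", scale = "numeric",
                 outputShape = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (length(object@encoderChannels) != 8)
    return("encoderChannels must have length 8")
  if (!object@scale %in% c(1, 0.5, 0.25))
    return("scale must be one of 1, 1/2, 1/4")
  os <- object@outputShape
  if (length(os) != 3) return("outputShape must be 3 counts")
  if (os[1] != os[2] || os[3] != 2 * os[1])
    return("outputShape must be (S, S, 2S)")
  ups <- log2(os[1] / object@bottleneckShape[1])
  if (ups != round(ups))
    return("outputShape is not reachable from the bottleneck by doubling")
  if (object@centralDecoderUps != ups)
    return("centralDecoderUps inconsistent with outputShape/bottleneck")
  TRUE
})

#' Construct a GeneratorConfig
#'
#' @param scale resolution multiplier (1, 1/2 or 1/4). The output shape is
#'   scale * (128, 128, 256) and the upsampling chains shorten accordingly.
#' @param encoderChannels,firstKernel,otherKernel,bottleneckShape,
#'   decoderChannels architecture knobs; defaults follow the reference
#'   design.
#' @return A [GeneratorConfig-class] object.
#' @examples
#' generatorConfig(scale = 1/4)@outputShape   # 32 32 64
#' @export
generatorConfig <- function(scale = 1,
                            encoderChannels = c(64L, 64L, 64L, 64L, 32L, 16L, 8L, 4L),
                            firstKernel = 7L, otherKernel = 4L,
                            bottleneckShape = c(4L, 4L, 8L, 4L),
                            decoderChannels = c(8L, 8L, 4L, 2L, 2L)) {
  outputShape <- as.integer(round(c(128, 128, 256) * scale))
  cups <- as.integer(log2(outputShape[1] / bottleneckShape[1]))
  new("GeneratorConfig", encoderChannels = as.integer(encoderChannels),
      firstKernel = as.integer(firstKernel), otherKernel = as.integer(otherKernel),
      bottleneckShape = as.integer(bottleneckShape),
      viewDecoderUps = cups - 1L, centralDecoderUps = cups,
      decoderChannels = as.integer(decoderChannels),
      scale = scale, outputShape = outputShape)
}

#' Discriminator architecture configuration
#'
#' Four stride-2 Conv3D layers with channels (32, 64, 128, 256), cubic 4x4x4
#' kernels, LeakyReLU activations and batch normalisation, closed by a
#' single-channel Conv3D producing an unbounded patch-score grid (LSGAN
#' convention: no final activation).
#'
#' @slot channels integer channel schedule (strictly increasing).
#' @slot kernel cubic kernel size (>= 2).
#' @slot leakySlope LeakyReLU negative slope.
#' @slot finalChannels output channels of the closing convolution.
#' @export
setClass("DiscriminatorConfig",
  representation(channels = "integer", kernel = "integer",
                 leakySlope = "numeric", finalChannels = "integer"))

setValidity("DiscriminatorConfig", function(object) {
  if (any(diff(object@channels) <= 0)) return("channels must be strictly increasing")
  if (object@kernel < 2) return("kernel must be >= 2")
  TRUE
})

#' Construct a DiscriminatorConfig
#' @param channels stride-2 layer channels.
#' @param kernel cubic kernel size.
#' @param leakySlope LeakyReLU negative slope.
#' @return A [DiscriminatorConfig-class] object.
#' @export
discriminatorConfig <- function(channels = c(32L, 64L, 128L, 256L),
                                kernel = 4L, leakySlope = 0.2) {
  new("DiscriminatorConfig", channels = as.integer(channels),
      kernel = as.integer(kernel), leakySlope = leakySlope,
      finalChannels = 1L)
}

#' Loss weights of the combined generator objective
#'
#' The generator minimises lambda1 * LSGAN term + lambda2 * reconstruction
#' (voxel MSE) term; the reference weighting is lambda1 = 2, lambda2 = 100.
#'
#' @slot lambda1,lambda2 non-negative weights.
#' @export
setClass("LossWeights",
  representation(lambda1 = "numeric", lambda2 = "numeric"),
  prototype(lambda1 = 2, lambda2 = 100))

setValidity("LossWeights", function(object) {
  if (object@lambda1 < 0 || object@lambda2 < 0) return("weights must be >= 0")
  TRUE
})

#' Construct LossWeights
#' @param lambda1 adversarial weight (default 2).
#' @param lambda2 reconstruction weight (default 100).
#' @return A [LossWeights-class] object.
#' @export
lossWeights <- function(lambda1 = 2, lambda2 = 100) {
  new("LossWeights", lambda1 = lambda1, lambda2 = lambda2)
}

#' Training configuration
#'
#' @slot epochs training epochs (reference training stops around 50).
#' @slot batchSize minibatch size.
#' @slot learningRate Adam step size.
#' @slot optimizerBetas Adam (beta1, beta2).
#' @slot seed RNG seed controlling init and shuffling.
#' @slot binarizeThreshold probability threshold for the output binary
#'   volume (reference value 0.4).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizerBetas = "numeric",
                 seed = "integer", binarizeThreshold = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1) return("epochs must be >= 1")
  if (object@batchSize < 1) return("batchSize must be >= 1")
  th <- object@binarizeThreshold
  if (th <= 0 || th >= 1) return("binarizeThreshold must lie in (0, 1)")
  TRUE
})

#' Construct a TrainConfig
#' @param epochs epoch count (>= 1).
#' @param batchSize minibatch size (4 suits desk scale; 1 at full scale).
#' @param learningRate,optimizerBetas Adam hyper-parameters.
#' @param seed RNG seed.
#' @param binarizeThreshold output binarisation threshold in (0, 1).
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 4L, learningRate = 5e-3,
                        optimizerBetas = c(0.5, 0.999), seed = 1L,
                        binarizeThreshold = 0.4) {
  new("TrainConfig", epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, optimizerBetas = optimizerBetas,
      seed = as.integer(seed), binarizeThreshold = binarizeThreshold)
}

# --------------------------------------------------------------- reports

#' Per-case evaluation report
#'
#' Dice (DSC), Jaccard (JSC) and overlap-volume (OV) coefficients of the 3D
#' binary volumes plus SSIM of the AP and Lat sum projections.
#'
#' @slot caseId case identifier.
#' @slot dsc,jsc,ov overlap metrics in [0, 1] (NA where undefined).
#' @slot ssimAp,ssimLat projection SSIM in [-1, 1].
#' @export
setClass("MetricReport",
  representation(caseId = "character", dsc = "numeric", jsc = "numeric",
                 ov = "numeric", ssimAp = "numeric", ssimLat = "numeric"))

#' Train/validation/test index partition of one fold
#'
#' @slot foldIndex 0-based fold number.
#' @slot trainIds,valIds,testIds disjoint identifier vectors whose union is
#'   the full dataset.
#' @export
setClass("FoldSplit",
  representation(foldIndex = "integer", trainIds = "character",
                 valIds = "character", testIds = "character"))

setValidity("FoldSplit", function(object) {
  all3 <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all3)) return("train/val/test sets must be disjoint")
  TRUE
})

#' Experiment grid over signal conditions and dataset sizes
#'
#' @slot signalConditions subset of c("original", "enhanced").
#' @slot datasetSizes phantom counts per condition.
#' @slot k cross-validation folds.
#' @slot seed master seed for splits and training runs.
#' @export
setClass("ExperimentGrid",
  representation(signalConditions = "character", datasetSizes = "integer",
                 k = "integer", seed = "integer"))

setValidity("ExperimentGrid", function(object) {
  if (!all(object@signalConditions %in% c("original", "enhanced")))
    return("signalConditions must be a subset of {original, enhanced}")
  if (object@k < 2) return("k must be >= 2")
  TRUE
})

#' Construct an ExperimentGrid
#' @param signalConditions character subset of c("original", "enhanced").
#' @param datasetSizes integer vector of dataset sizes.
#' @param k folds (default 10).
#' @param seed master seed.
#' @return An [ExperimentGrid-class] object.
#' @export
experimentGrid <- function(signalConditions = c("original", "enhanced"),
                           datasetSizes = 40L, k = 10L, seed = 1L) {
  new("ExperimentGrid", signalConditions = signalConditions,
      datasetSizes = as.integer(datasetSizes), k = as.integer(k),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------- models

#' Conditional generator network
#'
#' Wraps the parameter tensors and batch-norm running statistics of the
#' dual-view encoder / fused 3D decoder generator. Use
#' [buildGenerator()] to create one and [predictVolume()] for inference.
#'
#' @slot config the [GeneratorConfig-class].
#' @slot params nested list of weight arrays.
#' @slot state nested list of batch-norm running statistics.
#' @export
setClass("SpineGenerator",
  representation(config = "GeneratorConfig", params = "list", state = "list"))

#' 3D patch discriminator network
#'
#' @slot config the [DiscriminatorConfig-class].
#' @slot params nested list of weight arrays.
#' @slot state batch-norm running statistics.
#' @export
setClass("SpineDiscriminator",
  representation(config = "DiscriminatorConfig", params = "list", state = "list"))
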