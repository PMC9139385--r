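# Accessor generics and show methods.

#' Access the voxel array of a volume
#' @param x a volume object.
#' @return the underlying numeric array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' Access the binary mask array
#' @param x a [SegmentationVolume-class].
#' @return 3D binary array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname maskArray
#' @export
setMethod("maskArray", "SegmentationVolume", function(x) x@mask)

#' Access the imaging-signal array
#' @param x an [EnhancedVolume-class].
#' @return 3D numeric array.
#' @export
setGeneric("signalArray", function(x) standardGeneric("signalArray"))

#' @rdname signalArray
#' @export
setMethod("signalArray", "EnhancedVolume", function(x) x@signal)

#' Voxel spacing in mm
#' @param x a volume object.
#' @return numeric(3).
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname spacingMm
#' @export
setMethod("spacingMm", "CTVolume", function(x) x@spacingMm)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "SegmentationVolume", function(x) x@spacingMm)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "EnhancedVolume", function(x) x@spacingMm)

#' Signal provenance ("original" or "enhanced")
#' @param x an [EnhancedVolume-class].
#' @return character scalar.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "EnhancedVolume", function(x) x@provenance)

#' Radiograph images of a bi-planar pair
#' @param x a [DRRPair-class].
#' @return numeric matrix in [0, 1].
#' @export
setGeneric("apImage", function(x) standardGeneric("apImage"))

#' @rdname apImage
#' @export
setMethod("apImage", "DRRPair", function(x) x@ap)

#' @rdname apImage
#' @export
setGeneric("latImage", function(x) standardGeneric("latImage"))

#' @rdname apImage
#' @export
setMethod("latImage", "DRRPair", function(x) x@lat)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %dx%dx%d, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(object@spacingMm, collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "SegmentationVolume", function(object) {
  d <- dim(object@mask)
  cat(sprintf("SegmentationVolume %dx%dx%d, %d foreground voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "EnhancedVolume", function(object) {
  d <- dim(object@signal)
  cat(sprintf("EnhancedVolume (%s) %dx%dx%d, signal range [%.0f, %.0f]\n",
              object@provenance, d[1], d[2], d[3],
              min(object@signal), max(object@signal)))
})

setMethod("show", "DRRPair", function(object) {
  d <- dim(object@ap)
  cat(sprintf("DRRPair '%s': AP and Lat %dx%d radiographs in [0, 1]\n",
              object@sourceId, d[1], d[2]))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(
    "MetricReport '%s': DSC %.4f  JSC %.4f  OV %s  SSIM_AP %.4f  SSIM_Lat %.4f\n",
    object@caseId, object@dsc, object@jsc,
    ifelse(is.na(object@ov), "NA", sprintf("%.4f", object@ov)),
    object@ssimAp, object@ssimLat))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit %d: %d train / %d val / %d test\n", object@foldIndex,
              length(object@trainIds), length(object@valIds),
              length(object@testIds)))
})

setMethod("show", "SpineGenerator", function(object) {
  n <- sum(vapply(rapply(object@params, length, how = "unlist"), sum, 0))
  cat(sprintf("SpineGenerator: scale %s, output %s, %d parameters\n",
              format(object@config@scale),
              paste(object@config@outputShape, collapse = "x"), n))
})

setMethod("show", "SpineDiscriminator", function(object) {
  n <- sum(vapply(rapply(object@params, length, how = "unlist"), sum, 0))
  cat(sprintf("SpineDiscriminator: channels (%s), %d parameters\n",
              paste(object@config@channels, collapse = ", "), n))
})

#' Coerce a MetricReport to a one-row data.frame
#' @param x a [MetricReport-class].
#' @param ... unused.
#' @return data.frame with columns case_id, dsc, jsc, ov, ssim_ap, ssim_lat.
#' @export
as.data.frame.MetricReport <- function(x, ...) {
  data.frame(case_id = x@caseId, dsc = x@dsc, jsc = x@jsc, ov = x@ov,
             ssim_ap = x@ssimAp, ssim_lat = x@ssimLat,
             stringsAsFactors = FALSE)
}
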