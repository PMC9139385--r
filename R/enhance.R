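# Empirical bone-signal enhancement: a fixed per-voxel pipeline
#   threshold filter -> body mask -> rescale inversion -> window -> amplify
# applied elementwise, converting raw HU into non-negative imaging-signal
# values. All rules are implemented literally, including the
# counter-intuitive high-HU rule that maps values above 1000 HU to 0
# (disable with drop_high_hu_rule if desired; the default is literal).

#' Threshold filter on raw HU values
#'
#' Clamps values below -1024 HU to -1024 and maps values above 1000 HU to 0.
#' Vectorised; the output always lies in [-1024, 1000].
#'
#' @param v numeric scalar or array of HU values (finite).
#' @param drop_high_hu_rule if TRUE, skip the ">1000 HU -> 0" rule and clamp
#'   at 1000 instead (non-default engineering escape hatch).
#' @return filtered HU values, same shape as \code{v}.
#' @examples
#' filterHU(c(-2000, 1500, 200))   # -1024 0 200
#' @export
filterHU <- function(v, drop_high_hu_rule = FALSE) {
  stop_if_not_finite(v, "filterHU input")
  out <- pmax(v, -1024)
  if (drop_high_hu_rule) out <- pmin(out, 1000) else out[out > 1000] <- 0
  out
}

#' Empirical body mask from HU values
#'
#' 1 where the HU value is strictly greater than -400 (body tissue), else 0.
#' Applied multiplicatively to the filtered values in [enhanceVolume()].
#'
#' @param v numeric scalar or array of HU values (finite).
#' @return numeric 0/1 array of the same shape.
#' @examples
#' bodyMask(c(0, -1000, -400))   # 1 0 0
#' @export
bodyMask <- function(v) {
  stop_if_not_finite(v, "bodyMask input")
  out <- as.numeric(v > -400)
  if (!is.null(dim(v))) dim(out) <- dim(v)
  out
}

#' Convert filtered HU to imaging-signal values
#'
#' Exact inverse of the DICOM rescale transform:
#' signal = (filtered HU - RescaleIntercept) / RescaleSlope.
#'
#' @param v filtered HU values.
#' @param slope rescale slope (non-zero).
#' @param intercept rescale intercept in HU.
#' @return imaging-signal values.
#' @examples
#' huToSignal(-24, 1, -1024)   # 1000
#' @export
huToSignal <- function(v, slope, intercept) {
  if (length(slope) != 1 || slope == 0)
    stop("rescale slope must be a non-zero scalar", call. = FALSE)
  (v - intercept) / slope
}

#' Empirical bone window and amplification
#'
#' Zeroes the signal outside the open window (874, 2024) and triples values
#' strictly above 1300 (which therefore land in (3900, 6072)); values in
#' (874, 1300] pass unchanged.
#'
#' @param s non-negative imaging-signal values.
#' @return windowed/amplified signal, same shape.
#' @examples
#' windowAmplify(c(800, 1000, 1500))   # 0 1000 4500
#' @export
windowAmplify <- function(s) {
  if (any(s < 0)) stop("imaging signal must be >= 0", call. = FALSE)
  out <- s
  out[s <= 874 | s >= 2024] <- 0
  amp <- out > 1300
  out[amp] <- 3 * out[amp]
  out
}

#' Bone-signal enhancement of a CT volume
#'
#' Applies the full empirical enhancement per voxel:
#' \code{windowAmplify(huToSignal(bodyMask(v) * filterHU(v)))} using the
#' volume's rescale metadata. Note that masked-out voxels (air, lung)
#' become 0 HU and hence signal \code{(0 - intercept) / slope} — with the
#' standard slope 1 / intercept -1024 this is 1024, inside the window; the
#' literal algorithm therefore flattens everything outside the body to a
#' common background level rather than to zero.
#'
#' @param ct a [CTVolume-class].
#' @param drop_high_hu_rule forwarded to [filterHU()].
#' @return an [EnhancedVolume-class] with provenance "enhanced".
#' @export
enhanceVolume <- function(ct, drop_high_hu_rule = FALSE) {
  validObject(ct)
  v <- ct@voxels
  filtered <- bodyMask(v) * filterHU(v, drop_high_hu_rule)
  sig <- windowAmplify(huToSignal(filtered, ct@rescaleSlope, ct@rescaleIntercept))
  new("EnhancedVolume", signal = sig, spacingMm = ct@spacingMm,
      provenance = "enhanced")
}

#' Un-enhanced imaging-signal volume (control condition)
#'
#' The "original" signal condition: the plain rescale inversion
#' \code{(HU - intercept) / slope} on HU clamped at the -1024 floor, with no
#' masking, windowing or amplification.
#'
#' @param ct a [CTVolume-class].
#' @return an [EnhancedVolume-class] with provenance "original".
#' @export
originalSignalVolume <- function(ct) {
  validObject(ct)
  if (ct@rescaleSlope == 0) stop("rescale slope must be non-zero", call. = FALSE)
  sig <- (pmax(ct@voxels, -1024) - ct@rescaleIntercept) / ct@rescaleSlope
  new("EnhancedVolume", signal = sig, spacingMm = ct@spacingMm,
      provenance = "original")
}
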