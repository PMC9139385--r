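# Parallel-beam digitally reconstructed radiographs. AP projects along y
# (posterior -> anterior), Lat along x (left -> right); detector rows index
# the remaining transverse axis and detector columns index z (inferior
# first; flipped to superior-first only on image export).

#' Parallel-beam line integral of a signal volume
#'
#' Pixel (u, w) is the sum of the signal along the projection axis times the
#' voxel spacing along that axis (a discrete line integral). AP integrates
#' along y giving an (x, z) image; Lat integrates along x giving (y, z).
#'
#' @param volume an [EnhancedVolume-class] (or 3D array via \code{spacing}).
#' @param view "AP" or "Lat".
#' @param spacing spacing override when \code{volume} is a bare array.
#' @return numeric matrix of line integrals (mm-weighted sums).
#' @export
lineIntegral <- function(volume, view, spacing = NULL) {
  if (is(volume, "EnhancedVolume")) {
    a <- volume@signal; sp <- volume@spacingMm
  } else {
    a <- volume; sp <- spacing %||% c(1, 1, 1)
  }
  if (length(dim(a)) != 3) stop("volume must be 3D", call. = FALSE)
  switch(view,
    AP  = apply(a, c(1, 3), sum) * sp[2],
    Lat = apply(a, c(2, 3), sum) * sp[1],
    stop("unknown view '", view, "' (use AP or Lat)", call. = FALSE))
}

#' Map line integrals to radiograph intensities
#'
#' Beer-Lambert-style transfer: pixel = 1 - exp(-k * integral), monotone
#' increasing, 0 at 0, asymptotically 1.
#'
#' @param integrals non-negative matrix of line integrals.
#' @param k attenuation scale per mm (> 0).
#' @return matrix of intensities in [0, 1).
#' @examples
#' toRadiograph(matrix(1000), 0.001)   # 1 - exp(-1)
#' @export
toRadiograph <- function(integrals, k) {
  if (length(k) != 1 || !is.finite(k) || k <= 0)
    stop("attenuation scale k must be a positive scalar", call. = FALSE)
  if (any(integrals < 0)) stop("integrals must be >= 0", call. = FALSE)
  1 - exp(-k * integrals)
}

# attenuation chosen so the median nonzero ray maps near `target`
auto_attenuation <- function(integrals, target = 0.7) {
  nz <- integrals[integrals > 0]
  if (!length(nz)) return(1e-3)
  -log(1 - target) / median(nz)
}

#' Mask-tight crop region of interest
#'
#' Bounding box of the foreground voxels dilated by a margin, clamped to
#' the grid — the default spine ROI used to crop chest DRRs.
#'
#' @param mask a [SegmentationVolume-class] or 3D binary array.
#' @param dilate margin in voxels (default 8).
#' @return list with integer ranges \code{x}, \code{y}, \code{z} (1-based,
#'   inclusive).
#' @export
defaultCropROI <- function(mask, dilate = 8) {
  m <- if (is(mask, "SegmentationVolume")) mask@mask else mask
  if (sum(m) == 0) stop("empty mask: no ROI", call. = FALSE)
  idx <- which(m != 0, arr.ind = TRUE)
  d <- dim(m)
  rng <- function(ax) c(max(1, min(idx[, ax]) - dilate),
                        min(d[ax], max(idx[, ax]) + dilate))
  list(x = rng(1), y = rng(2), z = rng(3))
}

# bilinear resample of a matrix to a new shape (voxel-center mapping,
# symmetric, clamped at edges)
resample_image <- function(img, newdim) {
  axis_w <- function(nOld, nNew) {
    s <- nOld / nNew
    src <- (seq_len(nNew) - 0.5) * s - 0.5
    src <- pmin(pmax(src, 0), nOld - 1)   # clamp before flooring (symmetry)
    i0 <- pmin(floor(src), nOld - 2); f <- src - i0
    i0 <- pmax(i0, 0); i1 <- i0 + 1
    if (nOld == 1) { i0 <- i1 <- 0; f <- rep(0, nNew) }
    W <- matrix(0, nNew, nOld)
    W[cbind(seq_len(nNew), i0 + 1)] <- W[cbind(seq_len(nNew), i0 + 1)] + (1 - f)
    W[cbind(seq_len(nNew), i1 + 1)] <- W[cbind(seq_len(nNew), i1 + 1)] + f
    W
  }
  Wu <- axis_w(nrow(img), newdim[1])
  Wv <- axis_w(ncol(img), newdim[2])
  Wu %*% img %*% t(Wv)
}

#' Simulate a bi-planar radiograph pair
#'
#' Projects the signal volume in the AP and Lat directions (parallel beam),
#' crops both projections to the spine ROI, applies the intensity transfer
#' and resamples to the detector shape. A single attenuation scale shared
#' by both views is chosen automatically (median nonzero ray -> 0.7) unless
#' the geometry specifies one.
#'
#' @param volume an [EnhancedVolume-class].
#' @param geometry list of two [ProjectionGeometry-class] (names ap, lat),
#'   or a numeric scale shortcut (detector = scale * (128, 256)).
#' @param crop ROI as returned by [defaultCropROI()] (list of x/y/z index
#'   ranges); NULL uses the full volume; an empty ROI is an error.
#' @param mask optional [SegmentationVolume-class] (or binary array) on the
#'   uncropped grid; when given, the automatic attenuation targets the
#'   median ray that passes through bone rather than the median nonzero
#'   ray, as the intensity model intends.
#' @param sourceId case identifier stored in the pair.
#' @return a [DRRPair-class].
#' @export
makeBiplanar <- function(volume, geometry = 1, crop = NULL, mask = NULL,
                         sourceId = "case") {
  if (is.numeric(geometry)) {
    det <- as.integer(round(c(128, 256) * geometry))
    geometry <- list(ap = projectionGeometry("AP", det),
                     lat = projectionGeometry("Lat", det))
  }
  det <- geometry$ap@detectorShape
  if (!identical(det, geometry$lat@detectorShape))
    stop("AP and Lat detector shapes must match", call. = FALSE)

  a <- volume@signal
  if (!is.null(crop)) {
    if (any(vapply(crop, function(r) r[2] < r[1], TRUE)))
      stop("empty crop ROI", call. = FALSE)
    a <- a[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], crop$z[1]:crop$z[2],
           drop = FALSE]
  }
  sub <- new("EnhancedVolume", signal = a, spacingMm = volume@spacingMm,
             provenance = volume@provenance)
  iAP <- lineIntegral(sub, "AP")
  iLat <- lineIntegral(sub, "Lat")

  k <- geometry$ap@attenuationScale
  if (is.na(k)) {
    if (!is.null(mask)) {
      m <- if (is(mask, "SegmentationVolume")) mask@mask else mask
      if (!is.null(crop))
        m <- m[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], crop$z[1]:crop$z[2],
               drop = FALSE]
      bAP <- apply(m, c(1, 3), sum) > 0
      bLat <- apply(m, c(2, 3), sum) > 0
      k <- auto_attenuation(c(iAP[bAP], iLat[bLat]))
    } else k <- auto_attenuation(c(iAP, iLat))
  }
  geometry$ap@attenuationScale <- k
  geometry$lat@attenuationScale <- k

  ap <- resample_image(toRadiograph(iAP, k), det)
  lat <- resample_image(toRadiograph(iLat, k), det)
  new("DRRPair", ap = pmin(pmax(ap, 0), 1), lat = pmin(pmax(lat, 0), 1),
      geometry = geometry, sourceId = sourceId)
}
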