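# NIfTI-1 I/O, volume resampling, JSON configuration and sidecars.
#
# No NIfTI reader is available in the dependency set, so a minimal NIfTI-1
# codec is implemented here: the 348-byte header, little-endian (byte order
# detected on read), datatypes uint8 / int16 / int32 / float32 / float64,
# gzip via gzfile(). Orientation handling is deliberately simple: data are
# stored and read in the package's fixed (x, y, z) order with a diagonal
# sform carrying the voxel spacing.

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITS <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L, float64 = 64L)

nii_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 2D/3D array as a NIfTI-1 file
#'
#' @param data numeric 2D or 3D array.
#' @param path output path (.nii or .nii.gz).
#' @param spacingMm voxel size per axis.
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64".
#' @return the path, invisibly.
#' @export
writeNifti <- function(data, path, spacingMm = rep(1, 3),
                       datatype = "float32") {
  dt <- NIFTI_DT[[datatype]]
  d <- dim(data) %||% length(data)
  if (length(d) > 7) stop("too many dimensions", call. = FALSE)
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  pix8 <- c(1, spacingMm[seq_along(d)], rep(1, 7 - length(d)))
  con <- nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents .. dim_info
  wi(dim8, 2)                      # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)         # intent_p1-3, intent_code
  wi(dt, 2); wi(NIFTI_BITS[[datatype]], 2); wi(0, 2)  # datatype,bitpix,slice_start
  wf(pix8)                         # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0, 2); wc("", 1); wi(2, 1)    # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                   # glmax, glmin
  wc("biplanar3d", 80); wc("", 24) # descrip, aux_file
  wi(0, 2); wi(1, 2)               # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))          # quatern_b/c/d, qoffset_x/y/z
  sp <- c(spacingMm, rep(1, 3))[1:3]
  wf(c(sp[1], 0, 0, 0)); wf(c(0, sp[2], 0, 0)); wf(c(0, 0, sp[3], 0))
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic
  writeBin(raw(4), con)            # no extensions
  vals <- as.vector(data)
  switch(datatype,
    uint8 = writeBin(as.integer(vals), con, size = 1, endian = "little"),
    int16 = writeBin(as.integer(vals), con, size = 2, endian = "little"),
    int32 = writeBin(as.integer(vals), con, size = 4, endian = "little"),
    float32 = writeBin(as.double(vals), con, size = 4, endian = "little"),
    float64 = writeBin(as.double(vals), con, size = 8, endian = "little"))
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path .nii or .nii.gz file.
#' @return list with \code{data} (array), \code{spacingMm},
#'   \code{sclSlope}, \code{sclInter}, \code{datatype}.
#' @export
readNifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header", call. = FALSE)
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = size > 1)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348) {
    if (rd(0, "integer", 1, 4, "big") == 348) endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic", call. = FALSE)
  dim8 <- rd(40, "integer", 8, 2, endian)
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  dtcode <- rd(70, "integer", 1, 2, endian)
  pixdim <- rd(76, "double", 8, 4, endian)
  voxoff <- rd(108, "double", 1, 4, endian)
  slope <- rd(112, "double", 1, 4, endian)
  inter <- rd(116, "double", 1, 4, endian)
  dtname <- names(NIFTI_DT)[match(dtcode, NIFTI_DT)]
  if (is.na(dtname)) stop("unsupported NIfTI datatype code ", dtcode,
                          call. = FALSE)
  skip <- voxoff - 348
  if (skip > 0) readBin(con, "raw", skip)
  nvox <- prod(d)
  vals <- switch(dtname,
    uint8 = as.numeric(readBin(con, "integer", nvox, 1, signed = FALSE,
                               endian = endian)),
    int16 = as.numeric(readBin(con, "integer", nvox, 2, endian = endian)),
    int32 = as.numeric(readBin(con, "integer", nvox, 4, endian = endian)),
    float32 = readBin(con, "double", nvox, 4, endian = endian),
    float64 = readBin(con, "double", nvox, 8, endian = endian))
  if (length(vals) < nvox) stop("truncated NIfTI data", call. = FALSE)
  if (!is.na(slope) && slope != 0 && !(slope == 1 && inter == 0))
    vals <- vals * slope + inter
  list(data = array(vals, d), spacingMm = pixdim[2:(1 + min(nd, 3))],
       sclSlope = slope, sclInter = inter, datatype = dtname)
}

#' Load a CT volume from NIfTI
#'
#' Voxel values are taken as HU. The DICOM acquisition rescale metadata
#' (used by the enhancement algorithm) is read from the volume's JSON
#' sidecar when present, else from the arguments.
#'
#' @param path NIfTI file.
#' @param rescaleSlope,rescaleIntercept defaults when no sidecar exists.
#' @return a [CTVolume-class].
#' @export
loadCT <- function(path, rescaleSlope = 1, rescaleIntercept = -1024) {
  nf <- readNifti(path)
  if (length(dim(nf$data)) != 3) stop("expected a 3D CT volume", call. = FALSE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::fromJSON(sc)
    rescaleSlope <- meta$rescaleSlope %||% rescaleSlope
    rescaleIntercept <- meta$rescaleIntercept %||% rescaleIntercept
  }
  ctVolume(nf$data, spacingMm = nf$spacingMm, rescaleSlope = rescaleSlope,
           rescaleIntercept = rescaleIntercept)
}

#' Load a binary segmentation from NIfTI
#' @param path NIfTI file (any datatype; nonzero means foreground).
#' @return a [SegmentationVolume-class].
#' @export
loadSegmentation <- function(path) {
  nf <- readNifti(path)
  segmentationVolume(array(as.numeric(nf$data != 0), dim(nf$data)),
                     spacingMm = nf$spacingMm)
}

#' Save a volume object as NIfTI (with a JSON sidecar)
#'
#' CT volumes are written as float32 HU, segmentations as uint8, signal
#' volumes as float32. The sidecar records class, seed/config digest
#' context and the rescale metadata.
#'
#' @param x a [CTVolume-class], [SegmentationVolume-class] or
#'   [EnhancedVolume-class].
#' @param path output .nii/.nii.gz path.
#' @param meta optional named list merged into the sidecar.
#' @return the path, invisibly.
#' @export
saveVolume <- function(x, path, meta = list()) {
  if (is(x, "CTVolume")) {
    writeNifti(x@voxels, path, x@spacingMm, "float32")
    meta <- c(list(class = "CTVolume", rescaleSlope = x@rescaleSlope,
                   rescaleIntercept = x@rescaleIntercept), meta)
  } else if (is(x, "SegmentationVolume")) {
    writeNifti(x@mask, path, x@spacingMm, "uint8")
    meta <- c(list(class = "SegmentationVolume"), meta)
  } else if (is(x, "EnhancedVolume")) {
    writeNifti(x@signal, path, x@spacingMm, "float32")
    meta <- c(list(class = "EnhancedVolume", provenance = x@provenance), meta)
  } else stop("unsupported object", call. = FALSE)
  writeSidecar(path, meta)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write a JSON sidecar for an artifact
#'
#' Records the configuration digest and seed sufficient to regenerate the
#' artifact, plus a timestamp.
#'
#' @param path the artifact path (sidecar goes next to it).
#' @param meta named list of metadata (seeds, configs, provenance).
#' @return sidecar path, invisibly.
#' @export
writeSidecar <- function(path, meta = list()) {
  meta$digest <- config_digest(meta)
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  sc <- sidecar_path(path)
  jsonlite::write_json(meta, sc, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(sc)
}

#' Resample a CT volume onto a new spacing
#'
#' Trilinear interpolation onto a corner-anchored grid whose extent matches
#' the source within one voxel per axis. Implemented as three separable
#' 1D linear interpolations.
#'
#' @param vol a [CTVolume-class].
#' @param newSpacingMm numeric(3) target spacing (> 0).
#' @return a resampled [CTVolume-class].
#' @export
resampleVolume <- function(vol, newSpacingMm) {
  if (any(newSpacingMm <= 0)) stop("new spacing must be > 0", call. = FALSE)
  d <- dim(vol@voxels); sp <- vol@spacingMm
  nd <- pmax(1L, as.integer(round(d * sp / newSpacingMm)))
  if (any(nd < 1)) stop("degenerate output grid", call. = FALSE)
  interp_w <- function(nOld, nNew, spOld, spNew) {
    src <- ((seq_len(nNew) - 0.5) * spNew) / spOld - 0.5
    src <- pmin(pmax(src, 0), nOld - 1)   # clamp before flooring (symmetry)
    i0 <- pmin(floor(src), nOld - 2); f <- src - i0
    i0 <- pmax(i0, 0); i1 <- i0 + 1
    if (nOld == 1) { i0 <- i1 <- 0; f <- rep(0, nNew) }
    W <- matrix(0, nNew, nOld)
    W[cbind(seq_len(nNew), i0 + 1)] <- W[cbind(seq_len(nNew), i0 + 1)] + 1 - f
    W[cbind(seq_len(nNew), i1 + 1)] <- W[cbind(seq_len(nNew), i1 + 1)] + f
    W
  }
  a <- vol@voxels
  Wx <- interp_w(d[1], nd[1], sp[1], newSpacingMm[1])
  a <- array(Wx %*% matrix(a, d[1], d[2] * d[3]), c(nd[1], d[2], d[3]))
  Wy <- interp_w(d[2], nd[2], sp[2], newSpacingMm[2])
  a <- aperm(array(Wy %*% matrix(aperm(a, c(2, 1, 3)), d[2], nd[1] * d[3]),
                   c(nd[2], nd[1], d[3])), c(2, 1, 3))
  Wz <- interp_w(d[3], nd[3], sp[3], newSpacingMm[3])
  a <- aperm(array(Wz %*% matrix(aperm(a, c(3, 1, 2)), d[3], nd[1] * nd[2]),
                   c(nd[3], nd[1], nd[2])), c(2, 3, 1))
  ctVolume(a, spacingMm = as.numeric(newSpacingMm),
           rescaleSlope = vol@rescaleSlope,
           rescaleIntercept = vol@rescaleIntercept)
}

#' Export a radiograph pair
#'
#' Writes each view as a lossless float32 NIfTI image (rows flipped so that
#' image row 0 is superior, the radiographic display convention) plus a
#' JSON geometry sidecar.
#'
#' @param pair a [DRRPair-class].
#' @param prefix output path prefix; files are <prefix>_ap.nii.gz,
#'   <prefix>_lat.nii.gz, <prefix>_geometry.json.
#' @return character vector of written paths, invisibly.
#' @export
saveDRRPair <- function(pair, prefix) {
  flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  pap <- paste0(prefix, "_ap.nii.gz")
  plat <- paste0(prefix, "_lat.nii.gz")
  writeNifti(flip(pair@ap), pap, datatype = "float32")
  writeNifti(flip(pair@lat), plat, datatype = "float32")
  g <- pair@geometry$ap
  meta <- list(sourceId = pair@sourceId, mode = g@mode,
               attenuationScale = g@attenuationScale,
               detectorShape = g@detectorShape, rowOrder = "superior-first")
  jsonlite::write_json(meta, paste0(prefix, "_geometry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pap, plat, paste0(prefix, "_geometry.json")))
}

#' Load a radiograph pair written by [saveDRRPair()]
#' @param prefix the path prefix used when saving.
#' @return a [DRRPair-class].
#' @export
loadDRRPair <- function(prefix) {
  flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  ap <- flip(readNifti(paste0(prefix, "_ap.nii.gz"))$data)
  lat <- flip(readNifti(paste0(prefix, "_lat.nii.gz"))$data)
  meta <- jsonlite::fromJSON(paste0(prefix, "_geometry.json"))
  det <- as.integer(meta$detectorShape)
  geom <- list(ap = projectionGeometry("AP", det, meta$mode,
                                       meta$attenuationScale),
               lat = projectionGeometry("Lat", det, meta$mode,
                                        meta$attenuationScale))
  new("DRRPair", ap = ap, lat = lat, geometry = geom,
      sourceId = meta$sourceId %||% "case")
}
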