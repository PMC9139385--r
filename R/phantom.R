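# Procedural spine phantom: a synthetic chest-CT stand-in with paired
# ground-truth segmentation. Geometry is analytic (elliptic cylinders and
# slabs evaluated on the voxel-center grid), so components are exact and no
# morphological post-processing is needed.

#' Generate a spine phantom CT with paired ground truth
#'
#' Builds a chest-like HU volume — air background, soft-tissue body ellipse,
#' two lung regions, and a spinal column of \code{nVertebrae} vertebra-like
#' bodies (trabecular core, one-voxel cortical shell, posterior spinous
#' process) separated by disc-height gaps of disc-level HU — together with a
#' binary mask that is 1 exactly on bone-class voxels. Per-phantom random
#' jitter (about +-15% on radii, a mild sinusoidal posteroanterior curve)
#' creates inter-subject variation; the result is a deterministic function
#' of the spec (including its seed).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{ct} ([CTVolume-class]) and \code{seg}
#'   ([SegmentationVolume-class]) on the same grid.
#' @examples
#' p <- generatePhantom(phantomSpec(nVertebrae = 3, noiseSd = 0, seed = 7))
#' sum(maskArray(p$seg)) > 0
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape; sp <- spec@spacingMm; hu <- spec@huLevels
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  Lx <- nx * sp[1]; Ly <- ny * sp[2]; Lz <- nz * sp[3]

  n <- spec@nVertebrae
  colHeight <- n * spec@vertebraHeightMm + (n - 1) * spec@discHeightMm
  if (colHeight + 2 * sp[3] > Lz)
    stop("grid too small: spine column of ", round(colHeight), " mm does not fit ",
         "the ", round(Lz), " mm z extent", call. = FALSE)

  with_seed(spec@seed, {
    jitterR <- runif(1, 0.85, 1.15)          # global radius jitter
    jitterV <- runif(n, 0.95, 1.05)          # per-vertebra radius jitter
    curveAmp <- runif(1, 0, 0.04) * Ly       # mild sinusoidal curve (mm)
    curvePhase <- runif(1, 0, 2 * pi)
    noise <- if (spec@noiseSd > 0) {
      e <- rnorm(nx * ny * nz, 0, spec@noiseSd)
      pmin(pmax(e, -6 * spec@noiseSd), 6 * spec@noiseSd)
    } else 0
  })

  # voxel-center coordinates (corner-anchored grid)
  xc <- (seq_len(nx) - 0.5) * sp[1]
  yc <- (seq_len(ny) - 0.5) * sp[2]
  zc <- (seq_len(nz) - 0.5) * sp[3]
  cx <- Lx / 2; cy <- Ly / 2

  # body ellipse and lungs (2D cross-sections, extruded along z)
  bodyA <- 0.42 * Lx; bodyB <- 0.38 * Ly
  body2d <- outer(((xc - cx) / bodyA)^2, ((yc - cy) / bodyB)^2, `+`) <= 1
  lungA <- 0.15 * Lx; lungB <- 0.20 * Ly
  lcy <- cy + 0.12 * Ly
  lung2d <- (outer(((xc - (cx - 0.20 * Lx)) / lungA)^2,
                   ((yc - lcy) / lungB)^2, `+`) <= 1) |
            (outer(((xc - (cx + 0.20 * Lx)) / lungA)^2,
                   ((yc - lcy) / lungB)^2, `+`) <= 1)
  lung2d <- lung2d & body2d

  ct <- array(hu[["air"]], gs)
  soft3d <- array(body2d, gs)                      # recycled along z
  ct[soft3d] <- hu[["soft"]]
  lungZ <- zc > 0.08 * Lz & zc < 0.92 * Lz
  lung3d <- array(lung2d, gs)
  lung3d[, , !lungZ] <- FALSE
  ct[lung3d] <- hu[["lung"]]

  # spinal column (posterior midline)
  sy0 <- cy - 0.20 * Ly
  rX <- spec@bodyRadiusMm * jitterR
  rY <- 0.85 * rX
  if (sy0 - rY - spec@processLengthMm < 0)
    stop("grid too small: posterior process does not fit the y extent",
         call. = FALSE)
  if (cx - rX < 0 || cx + rX > Lx)
    stop("grid too small: vertebral body does not fit the x extent",
         call. = FALSE)

  z0 <- (Lz - colHeight) / 2
  mask <- array(FALSE, gs)
  shellFrac <- 1 - sp[1] / rX                      # ~one-voxel cortical shell
  procHalfW <- max(2, 0.15 * rX)

  zstep <- spec@vertebraHeightMm + spec@discHeightMm
  syz <- sy0 + curveAmp * sin(2 * pi * zc / Lz + curvePhase)  # per-slice center

  for (v in seq_len(n)) {
    zlo <- z0 + (v - 1) * zstep
    zhi <- zlo + spec@vertebraHeightMm
    kz <- which(zc >= zlo & zc <= zhi)
    if (!length(kz)) next
    rx <- rX * jitterV[v]; ry <- rY * jitterV[v]
    for (k in kz) {
      r2 <- outer(((xc - cx) / rx)^2, ((yc - syz[k]) / ry)^2, `+`)
      inBody <- r2 <= 1
      endcap <- zc[k] < zlo + sp[3] || zc[k] > zhi - sp[3]
      cort <- inBody & (r2 > shellFrac^2 | endcap)
      trab <- inBody & !cort
      sl <- ct[, , k]
      sl[trab] <- hu[["trabecular"]]
      sl[cort] <- hu[["cortical"]]
      # posterior spinous process: thin midline slab, central 60% of body
      if (zc[k] > zlo + 0.2 * spec@vertebraHeightMm &&
          zc[k] < zhi - 0.2 * spec@vertebraHeightMm) {
        px <- abs(xc - cx) <= procHalfW
        py <- yc >= syz[k] - ry - spec@processLengthMm & yc <= syz[k] - ry * 0.3
        proc <- outer(px, py, `&`)
        sl[proc] <- hu[["cortical"]]
        mask[, , k] <- mask[, , k] | proc
      }
      ct[, , k] <- sl
      mask[, , k] <- mask[, , k] | inBody
    }
    # disc gap above vertebra v (soft-tissue-like HU, not in the mask)
    if (v < n) {
      kd <- which(zc > zhi & zc < zhi + spec@discHeightMm)
      for (k in kd) {
        r2 <- outer(((xc - cx) / rx)^2, ((yc - syz[k]) / ry)^2, `+`)
        sl <- ct[, , k]
        sl[r2 <= 1] <- hu[["disc"]]
        ct[, , k] <- sl
      }
    }
  }

  if (spec@noiseSd > 0) ct <- pmax(ct + noise, -1024)
  dim(ct) <- gs

  list(ct = ctVolume(ct, spacingMm = sp, rescaleSlope = 1,
                     rescaleIntercept = -1024),
       seg = segmentationVolume(array(as.numeric(mask), gs), spacingMm = sp))
}

#' Generate a reproducible phantom dataset
#'
#' Item i receives a seed derived deterministically from the master seed, so
#' item i is identical across runs regardless of \code{n} (as long as
#' n >= i + 1).
#'
#' @param n number of phantoms (>= 1).
#' @param spec template [PhantomSpec-class]; its seed slot is replaced per item.
#' @param seed master seed.
#' @return list of \code{n} phantom pairs as returned by [generatePhantom()].
#' @export
generateDataset <- function(n, spec = phantomSpec(), seed = 1L) {
  if (!is_count(n)) stop("n must be a positive count", call. = FALSE)
  lapply(seq_len(n), function(i) {
    spec@seed <- derive_seed(seed, i)
    generatePhantom(spec)
  })
}
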