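# Parallel-beam projector: conservation, linearity, intensity model,
# geometry conventions.

sig_vol <- function(a, sp = c(2, 2, 2)) {
  new("EnhancedVolume", signal = a, spacingMm = sp, provenance = "enhanced")
}

test_that("line integrals conserve mass and locate single voxels", {
  z <- sig_vol(array(0, c(6, 8, 10)))
  expect_true(all(lineIntegral(z, "AP") == 0))

  a <- array(0, c(6, 8, 10)); a[3, 5, 7] <- 5
  v <- sig_vol(a, sp = c(2, 2, 2))
  iAP <- lineIntegral(v, "AP")
  expect_equal(dim(iAP), c(6, 10))
  expect_equal(iAP[3, 7], 10)          # 5 * 2 mm
  expect_equal(sum(iAP != 0), 1)
  iLat <- lineIntegral(v, "Lat")
  expect_equal(dim(iLat), c(8, 10))
  expect_equal(iLat[5, 7], 10)
  # AP and Lat place the voxel on the same z detector row
  expect_equal(which(iAP != 0, arr.ind = TRUE)[2],
               which(iLat != 0, arr.ind = TRUE)[2])

  expect_error(lineIntegral(v, "oblique"), "unknown view")
})

test_that("projector conservation and linearity hold to 1e-9", {
  set.seed(21)
  for (r in 1:10) {
    d <- c(sample(4:12, 1), sample(4:12, 1), sample(4:16, 1))
    sp <- runif(3, 0.5, 3)
    a <- array(runif(prod(d)), d)
    v <- sig_vol(a, sp)
    expect_equal(sum(lineIntegral(v, "AP")), sum(a) * sp[2],
                 tolerance = 1e-9)
    expect_equal(sum(lineIntegral(v, "Lat")), sum(a) * sp[1],
                 tolerance = 1e-9)
    b <- array(runif(prod(d)), d)
    lhs <- lineIntegral(sig_vol(2 * a + 3 * b, sp), "AP")
    rhs <- 2 * lineIntegral(sig_vol(a, sp), "AP") +
      3 * lineIntegral(sig_vol(b, sp), "AP")
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
  }
})

test_that("intensity transfer is bounded, monotone and exact in closed form", {
  expect_equal(toRadiograph(matrix(0), 0.5), matrix(0))
  expect_equal(toRadiograph(matrix(1000), 0.001), matrix(1 - exp(-1)))
  expect_lt(toRadiograph(matrix(1e9), 0.01)[1], 1 + 1e-12)
  i <- matrix(seq(0, 100, length.out = 50))
  r <- toRadiograph(i, 0.03)
  expect_true(all(diff(r[, 1]) > 0))
  expect_true(all(r >= 0 & r < 1))
  expect_error(toRadiograph(matrix(1), 0), "positive")
  expect_error(toRadiograph(matrix(-1), 1), ">= 0")
})

test_that("biplanar pairs honour the detector contract and symmetry", {
  p <- generatePhantom(phantomSpec(nVertebrae = 3, noiseSd = 0, seed = 2))
  sig <- enhanceVolume(p$ct)
  roi <- defaultCropROI(p$seg)

  pair <- makeBiplanar(sig, geometry = 1, crop = roi, sourceId = "full")
  expect_s4_class(pair, "DRRPair")
  expect_equal(dim(apImage(pair)), c(128, 256))
  expect_equal(dim(latImage(pair)), c(128, 256))
  expect_true(all(apImage(pair) >= 0 & apImage(pair) <= 1))

  # the phantom is left-right symmetric: AP must mirror about its midline
  ap <- apImage(pair)
  expect_lt(max(abs(ap - ap[nrow(ap):1, ])), 1e-6)

  expect_error(makeBiplanar(sig, crop = list(x = c(5, 4), y = c(1, 2),
                                             z = c(1, 2))), "empty crop")
})

test_that("enhancement suppresses lung contrast in the AP radiograph", {
  p <- generatePhantom(phantomSpec(nVertebrae = 3, noiseSd = 0, seed = 13))
  roi <- list(x = c(1, 64), y = c(1, 64), z = c(1, 128))   # full chest view
  pe <- makeBiplanar(enhanceVolume(p$ct), 0.5, crop = roi)
  po <- makeBiplanar(originalSignalVolume(p$ct), 0.5, crop = roi)
  # lung columns sit at ~x = 0.3 and 0.7 of the width; body column at ~0.15
  lungc <- round(0.30 * 64); bodyc <- round(0.09 * 64)
  contrast <- function(img) abs(mean(img[lungc, ]) - mean(img[bodyc, ]))
  expect_false(identical(apImage(pe), apImage(po)))
  expect_lt(contrast(apImage(pe)), contrast(apImage(po)))
})
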