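# Bone-signal enhancement: the scalar rules, their composition, and the
# range/monotonicity invariants.

test_that("threshold filter clamps low HU and zeroes high HU", {
  expect_equal(filterHU(-2000), -1024)
  expect_equal(filterHU(1500), 0)
  expect_equal(filterHU(200), 200)
  expect_equal(filterHU(c(-1024, 1000)), c(-1024, 1000))  # boundaries pass
  expect_equal(filterHU(1000.5), 0)
  expect_error(filterHU(NaN), "non-finite")
  # escape hatch clamps instead of zeroing
  expect_equal(filterHU(1500, drop_high_hu_rule = TRUE), 1000)
})

test_that("body mask is strict at -400 HU", {
  expect_equal(bodyMask(0), 1)
  expect_equal(bodyMask(-1000), 0)
  expect_equal(bodyMask(-400), 0)
  expect_equal(bodyMask(-399.999), 1)
  m <- bodyMask(array(c(-500, 100), c(1, 2, 1)))
  expect_equal(dim(m), c(1, 2, 1))
  expect_equal(as.vector(m), c(0, 1))
})

test_that("rescale inversion is the exact affine inverse", {
  expect_equal(huToSignal(-24, 1, -1024), 1000)
  expect_equal(huToSignal(-1024, 1, -1024), 0)
  expect_equal(huToSignal(100, 2, 0), 50)
  expect_error(huToSignal(0, 0, 0), "non-zero")
})

test_that("windowing zeroes outside (874, 2024) and triples above 1300", {
  expect_equal(windowAmplify(800), 0)
  expect_equal(windowAmplify(1500), 4500)
  expect_equal(windowAmplify(1000), 1000)
  # boundaries: 874 and 2024 are excluded, 1300 passes unamplified
  expect_equal(windowAmplify(c(874, 2024, 1300, 1300.5)),
               c(0, 0, 1300, 3901.5))
  expect_error(windowAmplify(-1), ">= 0")
})

test_that("enhanceVolume matches the scalar composition oracle", {
  set.seed(5)
  hu <- array(runif(10^3, -2500, 2500), c(10, 10, 10))
  ct <- ctVolume(hu, rescaleSlope = 1, rescaleIntercept = -1024)
  enh <- enhanceVolume(ct)
  oracle <- apply(hu, 1:3, enhance_scalar)
  expect_equal(signalArray(enh), oracle)
  expect_identical(provenance(enh), "enhanced")

  # a 500 HU voxel lands at 3 * 1524
  ct1 <- ctVolume(array(c(500, -1024), c(2, 1, 1)))
  expect_equal(signalArray(enhanceVolume(ct1))[1, 1, 1], 4572)
})

test_that("enhanced signal occupies the predicted range bands", {
  set.seed(6)
  hu <- array(runif(4000, -2500, 2500), c(20, 20, 10))
  s <- signalArray(enhanceVolume(ctVolume(hu)))
  nz <- s[s != 0]
  expect_true(all(nz > 874))
  expect_true(all(nz <= 1300 | nz > 3900))
  expect_true(all(nz < 6072))
  # piecewise monotone within the window (un-amplified band vs amplified band)
  v <- seq(875, 2023, by = 0.5)
  out <- windowAmplify(v)
  expect_true(all(diff(out[v <= 1300]) >= 0))
  expect_true(all(diff(out[v > 1300]) >= 0))
})

test_that("the original (control) condition differs from enhancement", {
  p <- generatePhantom(phantomSpec(nVertebrae = 2, noiseSd = 0, seed = 9))
  orig <- originalSignalVolume(p$ct)
  enh <- enhanceVolume(p$ct)
  expect_identical(provenance(orig), "original")
  # rescale-only arithmetic
  expect_equal(signalArray(orig)[1, 1, 1], 0)           # air
  expect_equal(sort(unique(as.vector(signalArray(orig)))),
               c(0, 224, 1064, 1104, 1424, 2224))
  expect_false(identical(signalArray(orig), signalArray(enh)))
})
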