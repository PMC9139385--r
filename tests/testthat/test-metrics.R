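# Overlap metrics and projection SSIM.

rand_mask <- function(d, p = 0.3) array(rbinom(prod(d), 1, p), d)

test_that("overlap coefficients reproduce their defining ratios", {
  a <- array(0, c(5, 5, 4)); a[1:4, 1:5, 1:4] <- rep(c(1, 0), 40)
  expect_equal(dsc(a, a), 1)
  expect_equal(jsc(a, a), 1)
  expect_equal(ov(a, a), 1)

  # disjoint
  b <- 1 - a
  expect_equal(dsc(a, b), 0)
  expect_equal(jsc(a, b), 0)
  expect_equal(ov(a, b), 0)

  # |A| = |B| = 100, |A n B| = 50 -> DSC .5, JSC 1/3
  A <- array(0, c(10, 10, 2)); A[1:100] <- 1
  B <- array(0, c(10, 10, 2)); B[51:150] <- 1
  expect_equal(dsc(A, B), 0.5)
  expect_equal(jsc(A, B), 1 / 3)
  # |A| = 80, |B| = 200, intersection 50 -> OV = 0.625
  A2 <- array(0, c(10, 10, 3)); A2[21:100] <- 1
  B2 <- array(0, c(10, 10, 3)); B2[51:250] <- 1
  expect_equal(ov(A2, B2), 50 / 80)
  # subset -> OV = 1
  expect_equal(ov(A, array(1, c(10, 10, 2))), 1)
})

test_that("degenerate inputs follow the documented conventions", {
  e <- array(0, c(3, 3, 3))
  expect_warning(expect_equal(dsc(e, e), 1), "empty")
  expect_warning(expect_equal(jsc(e, e), 1), "empty")
  expect_error(ov(e, e), "empty")
  expect_error(dsc(e, array(0, c(2, 2, 2))), "same grid")
  expect_error(dsc(array(2, c(2, 2, 2)), array(1, c(2, 2, 2))), "binary")
})

test_that("metric identities and orderings hold on random volumes", {
  set.seed(31)
  for (r in 1:40) {
    a <- rand_mask(c(8, 8, 8), runif(1, 0.1, 0.6))
    b <- rand_mask(c(8, 8, 8), runif(1, 0.1, 0.6))
    if (sum(a) == 0 || sum(b) == 0) next
    d <- dsc(a, b); j <- jsc(a, b); o <- ov(a, b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_true(j <= d + 1e-12 && d <= o + 1e-12)
    # simultaneous axis permutation leaves all three unchanged
    pa <- aperm(a, c(3, 1, 2)); pb <- aperm(b, c(3, 1, 2))
    expect_equal(dsc(pa, pb), d)
    expect_equal(jsc(pa, pb), j)
    expect_equal(ov(pa, pb), o)
  }
})

test_that("ssim is 1 on identity, symmetric, and matches the oracle", {
  set.seed(32)
  x <- matrix(runif(48 * 40), 48, 40)
  y <- matrix(runif(48 * 40), 48, 40)
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-9)
  expect_true(abs(ssim(x, y)) <= 1)
  for (r in 1:3) {
    a <- matrix(runif(30 * 26), 30, 26)
    b <- a + matrix(rnorm(30 * 26, 0, 0.1), 30, 26)
    b[b < 0] <- 0; b[b > 1] <- 1
    expect_equal(ssim(a, b), ssim_reference(a, b), tolerance = 1e-6)
  }
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
  # uniform-window variant stays a valid similarity
  expect_equal(ssim(x, x, uniform = TRUE), 1, tolerance = 1e-9)
})

test_that("binary projections normalize as documented", {
  e <- array(0, c(12, 12, 12))
  expect_true(all(projectionForSSIM(e, "AP") == 0))
  s <- e; s[3, 4, 5] <- 1
  pAP <- projectionForSSIM(s, "AP")
  expect_equal(sum(pAP != 0), 1)
  expect_equal(pAP[3, 5], 1)
  m <- rand_mask(c(14, 14, 14))
  expect_equal(ssim(projectionForSSIM(m, "Lat"), projectionForSSIM(m, "Lat")), 1,
               tolerance = 1e-9)
})

test_that("evaluateCase assembles all five metrics coherently", {
  set.seed(33)
  g <- rand_mask(c(16, 16, 16), 0.3)
  r <- evaluateCase(segmentationVolume(g), segmentationVolume(g), "perfect")
  df <- as.data.frame(r)
  expect_equal(unname(unlist(df[, -1])), rep(1, 5), tolerance = 1e-9)

  comp <- 1 - g
  r2 <- evaluateCase(segmentationVolume(comp), segmentationVolume(g), "compl")
  expect_equal(r2@dsc, 0)
  expect_equal(r2@jsc, 0)
  expect_equal(r2@ov, 0)

  # empty prediction: strict errors, lenient returns NA for OV
  ep <- segmentationVolume(array(0, c(16, 16, 16)))
  expect_error(evaluateCase(ep, segmentationVolume(g)), "empty")
  r3 <- evaluateCase(ep, segmentationVolume(g), strict = FALSE)
  expect_true(is.na(r3@ov))
  expect_equal(r3@dsc, 0)
})
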