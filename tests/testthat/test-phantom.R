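# Procedural phantom generator: determinism, anatomy, invariants.

test_that("phantom generation is deterministic and anatomically consistent", {
  spec <- phantomSpec(nVertebrae = 3, noiseSd = 0, seed = 11)
  p1 <- generatePhantom(spec)
  p2 <- generatePhantom(spec)
  expect_identical(p1$ct@voxels, p2$ct@voxels)
  expect_identical(p1$seg@mask, p2$seg@mask)

  # mask marks bone exactly: every mask voxel carries a bone-class HU
  hu <- p1$ct@voxels[p1$seg@mask == 1]
  expect_true(all(hu %in% c(400, 1200)))

  # flood-fill oracle: 3 vertebrae -> 3 connected components
  expect_equal(flood_fill_components(p1$seg@mask), 3)

  # all tissue classes present
  expect_setequal(unique(as.vector(p1$ct@voxels)),
                  c(-1024, -800, 40, 80, 400, 1200))
})

test_that("air surrounds the body and CT values respect bounds", {
  p <- generatePhantom(phantomSpec(nVertebrae = 2, noiseSd = 0, seed = 4))
  d <- dim(p$ct@voxels)
  # grid corners are outside the body ellipse
  expect_equal(p$ct@voxels[1, 1, 1], -1024)
  expect_equal(p$ct@voxels[d[1], d[2], d[3]], -1024)

  pn <- generatePhantom(phantomSpec(nVertebrae = 2, noiseSd = 20, seed = 4))
  expect_gte(min(pn$ct@voxels), -1024)
  expect_lte(max(pn$ct@voxels), 1200 + 6 * 20)
  # mask voxels sit on tissue at least as dense as soft tissue
  expect_true(all(pn$ct@voxels[pn$seg@mask == 1] >= 40 - 6 * 20))
})

test_that("z profile of the mask recovers the vertebra count", {
  for (nv in c(2, 5, 8)) {
    p <- generatePhantom(phantomSpec(nVertebrae = nv, noiseSd = 0, seed = nv))
    prof <- apply(p$seg@mask, 3, sum)
    runs <- rle(prof > 0)
    expect_equal(sum(runs$values), nv)
  }
})

test_that("a grid too small for the spine errors out", {
  expect_error(generatePhantom(phantomSpec(nVertebrae = 30,
                                           gridShape = c(64, 64, 64))),
               "grid too small")
  expect_error(generatePhantom(phantomSpec(processLengthMm = 200)),
               "grid too small")
})

test_that("dataset seeding is per-item reproducible and non-degenerate", {
  spec <- phantomSpec(nVertebrae = 3, gridShape = c(48, 64, 96))
  d2 <- generateDataset(2, spec, seed = 7)
  d5 <- generateDataset(5, spec, seed = 7)
  expect_identical(d2[[1]]$ct@voxels, d5[[1]]$ct@voxels)
  expect_identical(d2[[2]]$seg@mask, d5[[2]]$seg@mask)

  expect_error(generateDataset(0, spec, 7), "positive count")

  masks <- lapply(d5, function(p) p$seg@mask)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(masks[[i]], masks[[j]]))
})
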