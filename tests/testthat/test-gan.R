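# Generator / discriminator architecture contracts, loss arithmetic,
# optimisation sanity, prediction semantics.

ns <- asNamespace("biplanar3d")

test_that("generator honours the shape contract at every scale", {
  for (sc in c(1 / 4, 1 / 2, 1)) {
    cfg <- generatorConfig(sc)
    expect_equal(cfg@outputShape, as.integer(c(128, 128, 256) * sc))
    g <- buildGenerator(cfg, seed = 1)
    W <- as.integer(128 * sc); H <- as.integer(256 * sc)
    set.seed(2)
    out <- ns$g_forward(g, matrix(runif(W * H), W, H),
                        matrix(runif(W * H), W, H), training = FALSE)$out
    expect_equal(dim(out), c(cfg@outputShape, 1L))
    expect_true(all(out > 0 & out < 1))     # final sigmoid
  }
  expect_error(generatorConfig(1 / 3), "scale")
  g4 <- buildGenerator(generatorConfig(1 / 4), seed = 1)
  expect_error(ns$g_forward(g4, matrix(0, 10, 10), matrix(0, 10, 10)),
               "32x64")
})

test_that("AP and Lat encoders are architecture twins with separate weights", {
  g <- buildGenerator(generatorConfig(1 / 4), seed = 3)
  expect_equal(lapply(g@params$enc$ap, function(b) dim(b$w)),
               lapply(g@params$enc$lat, function(b) dim(b$w)))
  expect_false(identical(g@params$enc$ap[[1]]$w, g@params$enc$lat[[1]]$w))
  # encoder channel schedule as configured, 7x7 first kernel then 4x4
  expect_equal(vapply(g@params$enc$ap, function(b) dim(b$w)[4], 0L),
               c(64L, 64L, 64L, 64L, 32L, 16L, 8L, 4L))
  expect_equal(dim(g@params$enc$ap[[1]]$w)[1:2], c(7L, 7L))
  expect_equal(dim(g@params$enc$ap[[2]]$w)[1:2], c(4L, 4L))
})

test_that("discriminator produces an unbounded conditional patch grid", {
  d <- buildDiscriminator(discriminatorConfig(), seed = 4)
  expect_equal(vapply(d@params$layers, function(b) dim(b$w)[5], 0L),
               c(32L, 64L, 128L, 256L))
  set.seed(5)
  cand <- array(runif(32 * 32 * 64 * 2), c(32, 32, 64, 2))
  ap <- array(runif(32 * 64 * 2), c(32, 64, 2))
  lat <- array(runif(32 * 64 * 2), c(32, 64, 2))
  # conditioning: candidate + two tiled radiographs = 3 input channels
  cond <- ns$cond_volume(cand, ap, lat)
  expect_equal(dim(cond), c(32L, 32L, 64L, 3L, 2L))
  expect_equal(cond[5, 9, 13, 2, 1], ap[5, 13, 1])   # AP tiled along y
  expect_equal(cond[5, 9, 13, 3, 2], lat[9, 13, 2])  # Lat tiled along x

  df <- ns$d_forward(d, cand, ap, lat, training = TRUE)
  expect_equal(dim(df$scores), c(2L, 2L, 4L, 2L))    # 32/2^4, 32/2^4, 64/2^4
  expect_false(all(df$scores >= 0 & df$scores <= 1)) # raw linear scores
  expect_error(ns$d_forward(d, array(0.5, c(8, 8, 8, 1)),
                            array(0, c(8, 8, 1)), array(0, c(8, 8, 1))),
               "receptive field")
  expect_error(discriminatorConfig(channels = c(64, 32)), "increasing")
})

test_that("LSGAN and reconstruction losses match brute-force arithmetic", {
  expect_equal(lsganDLoss(array(1, c(2, 2, 4)), array(0, c(2, 2, 4))), 0)
  expect_equal(lsganDLoss(array(0, c(2, 2)), array(1, c(2, 2))), 1)
  expect_equal(lsganDLoss(array(0.5, c(3, 3)), array(0.5, c(3, 3))), 0.25)
  expect_equal(lsganGLoss(array(1, c(4))), 0)
  expect_equal(lsganGLoss(array(0, c(4))), 0.5)
  expect_equal(lsganGLoss(array(0.5, c(4))), 0.125)
  expect_equal(reconstructionLoss(rep(1, 4), rep(0, 4)), 1)
  expect_equal(reconstructionLoss(c(1, 0, 1, 0), rep(0.5, 4)), 0.25)
  expect_equal(totalGLoss(0.5, 0.01, lossWeights(2, 100)), 2)
  expect_equal(totalGLoss(0, 0, lossWeights()), 0)
  expect_equal(totalGLoss(0.3, 5, lossWeights(2, 0)), 0.6)
  expect_error(lsganDLoss(array(0, c(2, 2)), array(0, c(3, 3))), "shape")
  expect_error(reconstructionLoss(array(0, c(2, 2)), array(0, c(4))), "shape")

  set.seed(6)
  for (r in 1:5) {
    dr <- array(rnorm(24), c(2, 3, 4)); dfk <- array(rnorm(24), c(2, 3, 4))
    # scalar loops as the independent route
    acc_d <- 0; acc_g <- 0
    for (i in seq_along(dr)) {
      acc_d <- acc_d + 0.5 * (dr[i] - 1)^2 / 24 + 0.5 * dfk[i]^2 / 24
      acc_g <- acc_g + 0.5 * (dfk[i] - 1)^2 / 24
    }
    expect_equal(lsganDLoss(dr, dfk), acc_d, tolerance = 1e-6)
    expect_equal(lsganGLoss(dfk), acc_g, tolerance = 1e-6)
  }
})

test_that("one small gradient step decreases the generator objective", {
  set.seed(7)
  gen <- buildGenerator(generatorConfig(1 / 4), seed = 8)
  disc <- buildDiscriminator(discriminatorConfig(), seed = 9)
  ap <- array(runif(32 * 64 * 2), c(32, 64, 2))
  lat <- array(runif(32 * 64 * 2), c(32, 64, 2))
  y <- array(rbinom(32 * 32 * 64 * 2, 1, 0.1), c(32, 32, 64, 2))
  w <- lossWeights()

  total_loss <- function(g) {
    gf <- ns$g_forward(g, ap, lat, training = TRUE)
    df <- ns$d_forward(disc, gf$out, ap, lat, training = TRUE)
    list(loss = totalGLoss(lsganGLoss(df$scores),
                           reconstructionLoss(y, gf$out), w),
         gf = gf, df = df)
  }
  l0 <- total_loss(gen)
  np <- length(l0$df$scores)
  db <- ns$d_backward(disc, l0$df$cache, w@lambda1 * (l0$df$scores - 1) / np,
                      need_input = TRUE, weight_grads = FALSE)
  dfake <- db$dcand + w@lambda2 * 2 * (l0$gf$out - y) / length(y)
  grads <- ns$g_backward(gen, l0$gf$cache, dfake)

  lr <- 1e-4
  gen@params <- ns$tree_map2(function(p, g) p - lr * g, gen@params, grads)
  l1 <- total_loss(gen)
  expect_lt(l1$loss, l0$loss)
})

test_that("prediction thresholds the probability map at 0.4", {
  cfg <- generatorConfig(1 / 4)
  gen <- buildGenerator(cfg, seed = 10)
  # zero all weights and set the final bias: output is exactly constant
  gen@params <- ns$tree_map1(function(x) x * 0, gen@params)
  mk_pair <- function() new("DRRPair", ap = matrix(0.5, 32, 64),
                            lat = matrix(0.5, 32, 64),
                            geometry = list(ap = projectionGeometry("AP", c(32L, 64L)),
                                            lat = projectionGeometry("Lat", c(32L, 64L))),
                            sourceId = "const")
  gen@params$fin$b <- log(0.41 / 0.59)       # sigmoid -> 0.41 everywhere
  segHi <- predictVolume(gen, mk_pair(), threshold = 0.4)
  expect_true(all(segHi@mask == 1))
  gen@params$fin$b <- log(0.39 / 0.61)       # sigmoid -> 0.39 everywhere
  segLo <- predictVolume(gen, mk_pair(), threshold = 0.4)
  expect_true(all(segLo@mask == 0))
  expect_true(all(segHi@mask %in% c(0, 1)))
  expect_error(predictVolume(gen, new("DRRPair", ap = matrix(0.5, 16, 32),
                                      lat = matrix(0.5, 16, 32),
                                      geometry = list(), sourceId = "bad")),
               "does not match")
})

test_that("training is seeded-reproducible, validates input, and conditions on the views", {
  cases <- get_cases(4, "enhanced")
  expect_error(trainGan(list(), tcfg = trainConfig(epochs = 1)), "non-empty")
  expect_error(trainConfig(epochs = 0), "epochs")
  bad <- cases[1:2]
  bad[[1]]$gt <- segmentationVolume(array(0, c(8, 8, 8)))
  expect_error(trainGan(bad, generatorConfig(1 / 4)), "output shape")

  tc <- trainConfig(epochs = 3, batchSize = 2, seed = 5)
  f1 <- trainGan(cases[1:2], generatorConfig(1 / 4), discriminatorConfig(),
                 lossWeights(), tc)
  f2 <- trainGan(cases[1:2], generatorConfig(1 / 4), discriminatorConfig(),
                 lossWeights(), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator@params$fin$w, f2$generator@params$fin$w)
  expect_named(f1$history,
               c("epoch", "g_loss", "g_adv", "g_recon", "d_loss", "val_loss"))

  # conditioning: different phantoms give different predicted volumes
  spec6 <- phantomSpec(nVertebrae = 6, seed = 61)
  spec10 <- phantomSpec(nVertebrae = 10, seed = 62)
  mk <- function(spec, id) {
    p <- generatePhantom(spec)
    prepareTrainingCase(p$ct, p$seg, "enhanced", scale = 1 / 4, sourceId = id)
  }
  c6 <- mk(spec6, "v6"); c10 <- mk(spec10, "v10")
  fit <- trainGan(list(c6, c10), generatorConfig(1 / 4), discriminatorConfig(),
                  lossWeights(), trainConfig(epochs = 4, batchSize = 2, seed = 3))
  o6 <- ns$g_forward(fit$generator, c6$pair@ap, c6$pair@lat,
                     training = FALSE)$out
  o10 <- ns$g_forward(fit$generator, c10$pair@ap, c10$pair@lat,
                      training = FALSE)$out
  expect_gt(mean(abs(o6 - o10) > 1e-8), 0.01)
})
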