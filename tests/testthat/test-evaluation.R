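# Cross-validation splits, rank statistics, experiment grid.

test_that("k-fold splits partition the ids with the 8:1:1 pattern", {
  ids <- sprintf("id%02d", 1:10)
  sp <- kfoldSplits(ids, 10, seed = 3)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s@testIds, 1)
    expect_length(s@valIds, 1)
    expect_length(s@trainIds, 8)
    expect_setequal(c(s@trainIds, s@valIds, s@testIds), ids)
  }
  # every id tested exactly once
  expect_setequal(unlist(lapply(sp, function(s) s@testIds)), ids)

  # 40 ids, k = 10: test folds of 4, exhaustive coverage
  ids40 <- sprintf("c%02d", 1:40)
  sp40 <- kfoldSplits(ids40, 10, seed = 5)
  tested <- unlist(lapply(sp40, function(s) s@testIds))
  expect_length(tested, 40)
  expect_setequal(tested, ids40)
  for (s in sp40) {
    expect_length(s@testIds, 4)
    expect_length(intersect(s@trainIds, s@testIds), 0)
    expect_length(intersect(s@valIds, s@testIds), 0)
    expect_length(intersect(s@trainIds, s@valIds), 0)
  }

  # partition property across (n, k) combinations, incl. uneven folds
  for (n in c(7, 11, 23)) for (k in c(2, 3, 5)) {
    idsx <- as.character(seq_len(n))
    for (s in kfoldSplits(idsx, k, seed = n + k))
      expect_setequal(c(s@trainIds, s@valIds, s@testIds), idsx)
  }
  expect_error(kfoldSplits(as.character(1:3), 5), "at least k")
})

test_that("two-fold splits keep a non-empty training set", {
  sp <- kfoldSplits(sprintf("c%02d", 1:40), 2, seed = 1)
  for (s in sp) {
    expect_length(s@testIds, 20)
    expect_gt(length(s@trainIds), 15)
    expect_gt(length(s@valIds), 0)
  }
})

test_that("Mann-Whitney U matches exact enumeration and its symmetries", {
  r <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)

  # identical multisets: p = 1 by construction
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mannWhitneyU(rep(2, 4), rep(2, 4))$p, 1)

  # symmetry in the arguments
  set.seed(41)
  a <- rnorm(5); b <- rnorm(4)
  expect_equal(mannWhitneyU(a, b)$p, mannWhitneyU(b, a)$p)

  # enumeration oracle over all small no-tie configurations
  for (r in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    v <- sample(100, na + nb)     # distinct -> no ties
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    expect_equal(mannWhitneyU(a, b)$p, mwu_enumerate_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis matches the rank formula and is shift invariant", {
  expect_equal(kruskalWallis(list(c(1, 2), c(1, 2), c(1, 2)))$H, 0)
  expect_equal(kruskalWallis(list(c(5, 5), c(5, 5), c(5, 5)))$p, 1)

  # hand-computed H for (1,2), (3,4), (5,6): ranks are the values themselves
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  n <- 6; rbar <- 3.5
  means <- c(1.5, 3.5, 5.5)
  H_hand <- 12 / (n * (n + 1)) * sum(2 * (means - rbar)^2)
  kw <- kruskalWallis(g)
  expect_equal(kw$H, H_hand, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(H_hand, 2, lower.tail = FALSE))

  shifted <- lapply(g, function(x) x + 100)
  expect_equal(kruskalWallis(shifted)$H, kw$H)
  expect_error(kruskalWallis(list(1:3)), "two groups")
  expect_error(kruskalWallis(list(1:3, numeric(0), 1:2)), "non-empty")
})

fab_results <- function(enh, ori, sizes = c(8, 16), metric = "dsc") {
  # fabricate fold metrics: one value per (condition, size, fold)
  rows <- list()
  for (s in seq_along(sizes)) for (f in seq_along(enh[[s]])) {
    rows[[length(rows) + 1]] <- data.frame(
      condition = c("enhanced", "original"), size = sizes[s], fold = f - 1,
      metric = metric, value = c(enh[[s]][f], ori[[s]][f]))
  }
  do.call(rbind, rows)
}

test_that("significance table flags condition contrasts as designed", {
  # identical conditions: no flags anywhere
  same <- fab_results(list(rep(0.5, 5), rep(0.6, 5)),
                      list(rep(0.5, 5), rep(0.6, 5)))
  st0 <- significanceTable(same)
  expect_false(any(st0$mw_sig))

  # enhanced uniformly above original, 10 folds pooled per condition
  set.seed(42)
  enh <- list(runif(5, 0.8, 0.9), runif(5, 0.8, 0.9))
  ori <- list(runif(5, 0.3, 0.4), runif(5, 0.3, 0.4))
  st1 <- significanceTable(fab_results(enh, ori))
  expect_true(all(st1$mw_sig))
  expect_lt(st1$mw_p[1], 0.05)

  # one row per metric x condition
  expect_equal(nrow(st1), 2)
  expect_named(st1, c("metric", "condition", "kw_p", "kw_sig", "mw_p", "mw_sig"))
  expect_error(significanceTable(same[same$condition == "enhanced" &
                                        same$size == 8, ]), "two")
})

test_that("runGrid produces finite fold-mean metrics deterministically", {
  ph <- get_phantoms(8)
  grid <- experimentGrid(signalConditions = "enhanced", datasetSizes = 8L,
                         k = 2L, seed = 17L)
  tc <- trainConfig(epochs = 2L, batchSize = 4L)
  res <- runGrid(grid, ph, generatorConfig(1 / 4), discriminatorConfig(),
                 lossWeights(), tc)
  expect_equal(sort(unique(res$fold)), c(0, 1))
  core <- res[res$metric %in% c("dsc", "jsc", "ov"), ]
  expect_true(all(is.finite(core$value)))
  expect_true(all(core$value >= 0 & core$value <= 1))
  expect_setequal(unique(res$metric),
                  c("dsc", "jsc", "ov", "ssim_ap", "ssim_lat", "dsc_untrained"))

  res2 <- runGrid(grid, ph, generatorConfig(1 / 4), discriminatorConfig(),
                  lossWeights(), tc)
  expect_identical(res, res2)

  expect_error(runGrid(experimentGrid(datasetSizes = 99L, k = 2L), ph),
               "exceed")
})
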