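# Cross-validation harness and rank-based statistics for the experiment
# grid (signal conditions x dataset sizes).

#' k-fold cross-validation splits with a rolling validation fold
#'
#' Ids are shuffled by the seed and partitioned into k near-equal folds
#' (size difference at most 1). Split f uses fold f as the test set, fold
#' (f + 1) mod k as the validation set and the remainder for training —
#' the 8:1:1 pattern at k = 10. At k = 2 the rolling rule would leave no
#' training data, so the validation set is instead carved from the non-test
#' half (one ninth of it, rounded up), preserving the 8:1 spirit.
#'
#' @param ids character (or coercible) identifiers, length >= k.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return list of k [FoldSplit-class] objects; across them every id
#'   appears in exactly one test set.
#' @export
kfoldSplits <- function(ids, k, seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k ids (", n, " < ", k, ")", call. = FALSE)
  shuffled <- with_seed(seed, sample(ids))
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  foldOf <- rep(seq_len(k), times = sizes)
  folds <- split(shuffled, foldOf)
  lapply(seq_len(k) - 1L, function(f) {
    test <- folds[[f + 1]]
    if (k == 2) {
      rest <- folds[[(f + 1) %% 2 + 1]]
      nval <- ceiling(length(rest) / 9)
      val <- rest[seq_len(nval)]
      train <- rest[-seq_len(nval)]
    } else {
      val <- folds[[(f + 1) %% k + 1]]
      train <- unlist(folds[-c(f + 1, (f + 1) %% k + 1)], use.names = FALSE)
    }
    new("FoldSplit", foldIndex = f, trainIds = train, valIds = val,
        testIds = test)
  })
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when the pooled sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction (no
#' continuity correction, so identical samples give p = 1 exactly).
#'
#' @param a,b non-empty numeric samples.
#' @return list with elements \code{U} (the U statistic of sample a) and
#'   \code{p} (two-sided p-value).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(10, 11, 12))$p   # 0.1
#' @export
mannWhitneyU <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p = 1))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 12
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p from the chi-square distribution with
#' (groups - 1) degrees of freedom. Degenerate all-equal input is defined
#' as H = 0, p = 1.
#'
#' @param samples list of at least two non-empty numeric samples.
#' @return list with elements \code{H} and \code{p}.
#' @examples
#' kruskalWallis(list(c(1, 2), c(1, 2), c(1, 2)))$H   # 0
#' @export
kruskalWallis <- function(samples) {
  if (length(samples) < 2) stop("need at least two groups", call. = FALSE)
  if (any(!vapply(samples, length, 0L)))
    stop("all groups must be non-empty", call. = FALSE)
  vals <- unlist(samples, use.names = FALSE)
  if (length(unique(vals)) == 1) return(list(H = 0, p = 1))
  grp <- rep(seq_along(samples), vapply(samples, length, 0L))
  kt <- kruskal.test(vals, factor(grp))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Significance table across conditions and sizes
#'
#' Per metric: a Mann-Whitney comparison of the enhanced vs original signal
#' conditions pooling all dataset sizes and folds, and a Kruskal-Wallis
#' comparison across dataset sizes within each condition.
#'
#' @param results long-format data.frame with columns condition, size,
#'   fold, metric, value (as produced by [runGrid()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per metric x condition: columns metric,
#'   condition, kw_p, kw_sig, mw_p, mw_sig (the Mann-Whitney columns are
#'   repeated across the conditions of a metric; NA when only one group
#'   exists).
#' @export
significanceTable <- function(results, alpha = 0.05) {
  conds <- unique(results$condition)
  sizes <- unique(results$size)
  if (length(conds) < 2 && length(sizes) < 2)
    stop("need at least two conditions or two sizes", call. = FALSE)
  metrics <- setdiff(unique(results$metric), "dsc_untrained")
  out <- do.call(rbind, lapply(metrics, function(m) {
    sub <- results[results$metric == m, ]
    mwp <- NA_real_
    if (length(conds) >= 2) {
      mwp <- mannWhitneyU(sub$value[sub$condition == conds[1]],
                          sub$value[sub$condition == conds[2]])$p
    }
    do.call(rbind, lapply(conds, function(cn) {
      kwp <- NA_real_
      if (length(sizes) >= 2) {
        gps <- lapply(sizes, function(s)
          sub$value[sub$condition == cn & sub$size == s])
        kwp <- kruskalWallis(gps)$p
      }
      data.frame(metric = m, condition = cn, kw_p = kwp,
                 kw_sig = !is.na(kwp) & kwp < alpha,
                 mw_p = mwp, mw_sig = !is.na(mwp) & mwp < alpha,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Run the full experiment grid
#'
#' For every (signal condition, dataset size, fold): radiograph pairs are
#' regenerated under that condition, the GAN is trained on the training
#' fold, and the held-out test cases are evaluated with all five metrics.
#' Every training/split seed derives deterministically from the grid seed,
#' so identical grids reproduce identical tables.
#'
#' @param grid an [ExperimentGrid-class].
#' @param phantoms list of phantom pairs from [generateDataset()]; at least
#'   max(datasetSizes) items.
#' @param gcfg,dcfg,w,tcfg model and training configurations.
#' @param includeBaseline also record the fold-mean DSC of an untrained
#'   generator on the same test cases (metric "dsc_untrained").
#' @param verbose print progress.
#' @return long-format data.frame (condition, size, fold, metric, value) of
#'   fold-mean metrics; per-case reports in attribute "per_case".
#' @export
runGrid <- function(grid, phantoms, gcfg = generatorConfig(1 / 4),
                    dcfg = discriminatorConfig(), w = lossWeights(),
                    tcfg = trainConfig(epochs = 15L),
                    includeBaseline = TRUE, verbose = FALSE) {
  validObject(grid)
  if (max(grid@datasetSizes) > length(phantoms))
    stop("datasetSizes exceed the available phantoms", call. = FALSE)
  rows <- list(); percase <- list()
  for (ci in seq_along(grid@signalConditions)) {
    cond <- grid@signalConditions[ci]
    for (si in seq_along(grid@datasetSizes)) {
      size <- grid@datasetSizes[si]
      ids <- sprintf("case%03d", seq_len(size))
      cases <- lapply(seq_len(size), function(i)
        prepareTrainingCase(phantoms[[i]]$ct, phantoms[[i]]$seg, cond,
                            scale = gcfg@scale, sourceId = ids[i]))
      names(cases) <- ids
      splits <- kfoldSplits(ids, grid@k, seed = derive_seed(grid@seed, ci, si))
      for (sp in splits) {
        f <- sp@foldIndex
        if (verbose)
          message(sprintf("grid: %s size %d fold %d", cond, size, f))
        seedF <- derive_seed(grid@seed, ci, si, f)
        tc <- tcfg; tc@seed <- seedF
        fit <- trainGan(cases[sp@trainIds], gcfg, dcfg, w, tc,
                        valDataset = cases[sp@valIds])
        base <- if (includeBaseline) buildGenerator(gcfg, seed = seedF) else NULL
        reps <- lapply(sp@testIds, function(id) {
          pred <- predictVolume(fit$generator, cases[[id]]$pair,
                                threshold = tcfg@binarizeThreshold,
                                spacingMm = cases[[id]]$gt@spacingMm)
          r <- evaluateCase(pred, cases[[id]]$gt, caseId = id, strict = FALSE)
          bd <- NA_real_
          if (!is.null(base)) {
            bpred <- predictVolume(base, cases[[id]]$pair,
                                   threshold = tcfg@binarizeThreshold)
            bd <- dsc(bpred@mask, cases[[id]]$gt@mask)
          }
          list(rep = r, base = bd)
        })
        dfc <- do.call(rbind, lapply(reps, function(x) as.data.frame(x$rep)))
        means <- c(dsc = mean(dfc$dsc), jsc = mean(dfc$jsc),
                   ov = mean(dfc$ov, na.rm = TRUE),
                   ssim_ap = mean(dfc$ssim_ap), ssim_lat = mean(dfc$ssim_lat))
        if (includeBaseline)
          means <- c(means,
                     dsc_untrained = mean(vapply(reps, function(x) x$base, 0)))
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, size = size, fold = f,
          metric = names(means), value = unname(means),
          stringsAsFactors = FALSE)
        percase[[sprintf("%s_%d_%d", cond, size, f)]] <- dfc
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_case") <- percase
  out
}
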