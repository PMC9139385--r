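# Independent oracles and shared fixtures for the test suite. These
# deliberately re-derive quantities with naive algorithms (flood fill,
# per-window loops, exhaustive enumeration) so the package implementation
# is checked against a second, separately coded route.

# 6-connected component count of a 3D binary array via BFS flood fill
flood_fill_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx <- which(mask != 0)
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (cur - 1) %/% (d[1] * d[2])
      r <- (cur - 1) %% (d[1] * d[2])
      j <- r %/% d[1]; i <- r %% d[1]
      for (nb in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                      c(0, 0, -1), c(0, 0, 1))) {
        ii <- i + nb[1]; jj <- j + nb[2]; kk <- k + nb[3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        lin <- 1 + ii + d[1] * (jj + d[2] * kk)
        if (mask[lin] != 0 && lab[lin] == 0L) {
          lab[lin] <- ncomp
          queue <- c(queue, lin)
        }
      }
    }
  }
  ncomp
}

# reference SSIM: explicit per-window loop with independently constructed
# Gaussian weights (canonical constants, L = 1)
ssim_reference <- function(x, y, window = 11, sigma = 1.5) {
  off <- seq_len(window) - (window + 1) / 2
  wg <- outer(stats::dnorm(off, sd = sigma), stats::dnorm(off, sd = sigma))
  wg <- wg / sum(wg)
  C1 <- 1e-4; C2 <- 9e-4
  n1 <- nrow(x) - window + 1; n2 <- ncol(x) - window + 1
  acc <- 0
  for (v in seq_len(n2)) {
    for (u in seq_len(n1)) {
      px <- x[u:(u + window - 1), v:(v + window - 1)]
      py <- y[u:(u + window - 1), v:(v + window - 1)]
      mx <- sum(wg * px); my <- sum(wg * py)
      vx <- sum(wg * px * px) - mx^2
      vy <- sum(wg * py * py) - my^2
      cxy <- sum(wg * px * py) - mx * my
      acc <- acc + ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  }
  acc / (n1 * n2)
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n, na) group assignments (no ties assumed)
mwu_enumerate_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">"))
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pool), na)
  us <- apply(combs, 2, function(ix) u_of(pool[ix], pool[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# naive scalar implementation of the full bone-enhancement chain
enhance_scalar <- function(v, slope = 1, intercept = -1024) {
  f <- if (v < -1024) -1024 else v
  if (f > 1000) f <- 0
  m <- if (v > -400) 1 else 0
  s <- (m * f - intercept) / slope
  if (s <= 874 || s >= 2024) s <- 0
  if (s > 1300) s <- 3 * s
  s
}

# shared desk-scale phantom dataset, generated once per session
phantom_cache <- new.env(parent = emptyenv())
get_phantoms <- function(n, seed = 2026) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- generateDataset(n, phantomSpec(), seed = seed)
  phantom_cache[[key]]
}

# training cases for a condition, cached
case_cache <- new.env(parent = emptyenv())
get_cases <- function(n, condition, seed = 2026) {
  key <- sprintf("%s_%d_%d", condition, n, seed)
  if (is.null(case_cache[[key]])) {
    ph <- get_phantoms(n, seed)
    cs <- lapply(seq_len(n), function(i)
      prepareTrainingCase(ph[[i]]$ct, ph[[i]]$seg, condition, scale = 1 / 4,
                          sourceId = sprintf("case%03d", i)))
    names(cs) <- sprintf("case%03d", seq_len(n))
    case_cache[[key]] <- cs
  }
  case_cache[[key]]
}
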