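# Minimal deep-learning engine backing the conditional GAN: thin R wrappers
# over the Rcpp im2col/GEMM convolution kernels plus batch normalisation,
# activations, nearest-neighbour resizing, tiling of 2D views into 3D
# feature volumes, and an Adam optimiser. Everything is deterministic given
# the R RNG state; all tensors are plain R arrays
#   2D: (W, H, C, N)    3D: (X, Y, Z, C, N)

# ---- padding helpers ("same" for stride 1, "half" for stride 2) ----------

pad_same <- function(k) c(floor((k - 1) / 2), ceiling((k - 1) / 2))

conv2d_f <- function(x, w, b, stride = 1L, pad = "same") {
  k <- dim(w)[1:2]
  p <- if (identical(pad, "same")) {
    if (stride == 1) c(pad_same(k[1]), pad_same(k[2]))
    else c(1L, 1L, 1L, 1L)                     # stride-2, k=4: halves size
  } else c(0L, 0L, 0L, 0L)
  list(y = .conv2d_fw(x, w, b, as.integer(stride),
                      as.integer(p[1]), as.integer(p[2]),
                      as.integer(p[3]), as.integer(p[4])),
       pads = p, stride = stride)
}

conv2d_b <- function(x, w, dy, meta, need_dx = TRUE, need_dw = TRUE) {
  .conv2d_bw(x, w, dy, as.integer(meta$stride),
             as.integer(meta$pads[1]), as.integer(meta$pads[3]),
             need_dx, need_dw)
}

conv3d_f <- function(x, w, b, stride = 1L, pad = "same") {
  k <- dim(w)[1:3]
  p <- if (identical(pad, "same")) {
    if (stride == 1) c(pad_same(k[1]), pad_same(k[2]), pad_same(k[3]))
    else rep(1L, 6)
  } else rep(0L, 6)
  list(y = .conv3d_fw(x, w, b, as.integer(stride),
                      as.integer(p[1]), as.integer(p[2]), as.integer(p[3]),
                      as.integer(p[4]), as.integer(p[5]), as.integer(p[6])),
       pads = p, stride = stride)
}

conv3d_b <- function(x, w, dy, meta, need_dx = TRUE, need_dw = TRUE) {
  .conv3d_bw(x, w, dy, as.integer(meta$stride),
             as.integer(meta$pads[1]), as.integer(meta$pads[3]),
             as.integer(meta$pads[5]), need_dx, need_dw)
}

# ---- batch normalisation -------------------------------------------------

# normalises over all dims except the channel dim (second to last);
# training mode uses batch statistics and updates running estimates.
bn_f <- function(x, gamma, beta, rm, rv, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); nd <- length(d); C <- d[nd - 1]
  perm <- c(setdiff(seq_len(nd), nd - 1), nd - 1)
  xm <- aperm(x, perm); dim(xm) <- c(length(x) / C, C)
  if (training) {
    m <- colMeans(xm)
    v <- colMeans(xm^2) - m^2
    rm <- momentum * rm + (1 - momentum) * m
    rv <- momentum * rv + (1 - momentum) * v
  } else {
    m <- rm; v <- rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xm, 2, m) %*% diag(invstd, C, C)
  ym <- xhat %*% diag(gamma, C, C) + matrix(beta, nrow(xm), C, byrow = TRUE)
  y <- array(ym, d[perm]); y <- aperm(y, order(perm))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           perm = perm, d = d),
       rm = rm, rv = rv)
}

bn_b <- function(dy, cache) {
  d <- cache$d; nd <- length(d); C <- d[nd - 1]
  dym <- aperm(dy, cache$perm); dim(dym) <- c(length(dy) / C, C)
  M <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym %*% diag(cache$gamma, C, C)
  # standard batch-norm input gradient
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * cache$xhat)
  dxm <- sweep(dxhat, 2, mean_dxhat) - cache$xhat %*% diag(mean_dxhat_xhat, C, C)
  dxm <- dxm %*% diag(cache$invstd, C, C)
  dx <- array(dxm, d[cache$perm]); dx <- aperm(dx, order(cache$perm))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ---------------------------------------------------------

relu_f <- function(x) { y <- x; y[y < 0] <- 0; y }
relu_b <- function(dy, x) { dy[x <= 0] <- 0; dy }
lrelu_f <- function(x, slope) .lrelu_fw(x, slope)
lrelu_b <- function(dy, x, slope) .lrelu_bw(dy, x, slope)
sigmoid_f <- function(x) 1 / (1 + exp(-x))

# ---- nearest-neighbour upsampling / resizing -----------------------------

up2_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

up2_b <- function(dy) {
  d <- dim(dy)
  dy[seq(1, d[1], 2), , , , drop = FALSE][, seq(1, d[2], 2), , , drop = FALSE] +
  dy[seq(2, d[1], 2), , , , drop = FALSE][, seq(1, d[2], 2), , , drop = FALSE] +
  dy[seq(1, d[1], 2), , , , drop = FALSE][, seq(2, d[2], 2), , , drop = FALSE] +
  dy[seq(2, d[1], 2), , , , drop = FALSE][, seq(2, d[2], 2), , , drop = FALSE]
}

up3_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , , drop = FALSE]
}

up3_b <- function(dy) {
  d <- dim(dy)
  o <- seq(1, d[1], 2); e <- seq(2, d[1], 2)
  acc <- NULL
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    part <- dy[seq(1 + di, d[1], 2), seq(1 + dj, d[2], 2),
               seq(1 + dk, d[3], 2), , , drop = FALSE]
    acc <- if (is.null(acc)) part else acc + part
  }
  acc
}

# nearest-neighbour resize of a 2D feature map stack (W,H,C,N)
resize2_nearest <- function(x, newWH) {
  d <- dim(x)
  ix <- pmin(d[1], pmax(1, ceiling((seq_len(newWH[1]) - 0.5) * d[1] / newWH[1])))
  iy <- pmin(d[2], pmax(1, ceiling((seq_len(newWH[2]) - 0.5) * d[2] / newWH[2])))
  list(y = x[ix, iy, , , drop = FALSE], ix = ix, iy = iy, d = d)
}

resize2_nearest_b <- function(dy, meta) {
  dx <- array(0, meta$d)
  # scatter-add (small maps only: bottleneck-sized skips)
  for (u in seq_along(meta$ix)) for (v in seq_along(meta$iy))
    dx[meta$ix[u], meta$iy[v], , ] <- dx[meta$ix[u], meta$iy[v], , ] +
      dy[u, v, , ]
  dx
}

# ---- tiling 2D view features into 3D volumes -----------------------------

# AP features live on (x, z): replicate along y -> (X, Y, Z, C, N)
tile_y_f <- function(f, ny) {
  d <- dim(f)  # (X, Z, C, N)
  aperm(array(f, c(d, ny)), c(1, 5, 2, 3, 4))
}
tile_y_b <- function(dy) colSums(aperm(dy, c(2, 1, 3, 4, 5)))

# Lat features live on (y, z): replicate along x -> (X, Y, Z, C, N)
tile_x_f <- function(f, nx) {
  d <- dim(f)  # (Y, Z, C, N)
  aperm(array(f, c(d, nx)), c(5, 1, 2, 3, 4))
}
tile_x_b <- function(dy) colSums(dy, dims = 1)

# ---- channel concat ------------------------------------------------------

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  out <- array(0, c(da[seq_len(nd - 2)], da[nd - 1] + db[nd - 1], da[nd]))
  if (nd == 4) { out[, , seq_len(da[3]), ] <- a; out[, , da[3] + seq_len(db[3]), ] <- b }
  else { out[, , , seq_len(da[4]), ] <- a; out[, , , da[4] + seq_len(db[4]), ] <- b }
  out
}

split_ch <- function(d, c1) {
  nd <- length(dim(d))
  if (nd == 4) list(a = d[, , seq_len(c1), , drop = FALSE],
                    b = d[, , -seq_len(c1), , drop = FALSE])
  else list(a = d[, , , seq_len(c1), , drop = FALSE],
            b = d[, , , -seq_len(c1), , drop = FALSE])
}

# ---- parameter initialisation and Adam -----------------------------------

he_conv <- function(kdims, cin, cout) {
  fan_in <- prod(kdims) * cin
  array(rnorm(prod(kdims) * cin * cout, 0, sqrt(2 / fan_in)),
        c(kdims, cin, cout))
}

conv_block_params <- function(kdims, cin, cout, bn = TRUE) {
  p <- list(w = he_conv(kdims, cin, cout), b = numeric(cout))
  if (bn) { p$gamma <- rep(1, cout); p$beta <- numeric(cout) }
  p
}

bn_state0 <- function(cout) list(rm = numeric(cout), rv = rep(1, cout))

# elementwise map over two parallel nested lists of arrays
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

tree_map1 <- function(f, a) {
  if (is.list(a)) return(lapply(a, tree_map1, f = f))
  f(a)
}

tree_sum <- function(f, a) {
  if (is.list(a)) return(sum(vapply(a, tree_sum, 0, f = f)))
  f(a)
}

# Adam runs on flattened parameter vectors (one vectorised update per step);
# the nested list structure is restored with relist().
adam_init <- function(params) {
  flat <- unlist(params, use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L,
       skeleton = params)
}

# relist that preserves the dim attributes of array leaves (utils::relist
# drops them)
tree_relist <- function(flat, skeleton, pos = 1L) {
  if (is.list(skeleton)) {
    out <- skeleton
    for (i in seq_along(skeleton)) {
      r <- tree_relist(flat, skeleton[[i]], pos)
      out[[i]] <- r$value; pos <- r$pos
    }
    return(list(value = out, pos = pos))
  }
  n <- length(skeleton)
  v <- flat[pos:(pos + n - 1)]
  if (!is.null(dim(skeleton))) dim(v) <- dim(skeleton)
  list(value = v, pos = pos + n)
}

adam_step <- function(params, grads, st, lr, betas = c(0.5, 0.999), eps = 1e-8) {
  p <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  st$t <- st$t + 1L
  st$m <- betas[1] * st$m + (1 - betas[1]) * g
  st$v <- betas[2] * st$v + (1 - betas[2]) * g^2
  upd <- lr * (st$m / (1 - betas[1]^st$t)) /
    (sqrt(st$v / (1 - betas[2]^st$t)) + eps)
  list(params = tree_relist(p - upd, st$skeleton)$value, state = st)
}
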