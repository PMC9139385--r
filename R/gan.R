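# The 2D->3D conditional GAN.
#
# Generator: two weight-independent 2D encoders (AP, Lat) of eight conv
# blocks (channels 64,64,64,64,32,16,8,4; 7x7 first kernel, 4x4 after;
# BN + ReLU; residual adds where channel counts match; 2x2 max pooling on
# the first log2(W/4) blocks) ending in a 4 x 8 bottleneck map with 4
# channels per view. Per-view 2D decoders upsample the bottleneck with skip
# connections from the last four encoder blocks. The central 3D decoder
# starts from the average of the two bottlenecks tiled along their missing
# axis (AP along y, Lat along x), upsamples with 4^3 convolutions, averages
# in the tiled per-view decoder features at matching resolutions, and closes
# with a 3^3 convolution and a sigmoid.
#
# Discriminator: 3D Patch-GAN. Candidate volume concatenated with the two
# conditioning radiographs tiled along their projection axes (3 input
# channels), four stride-2 4^3 conv layers (32,64,128,256) with LeakyReLU
# (BN from layer 2), closed by a 1-channel 4^3 convolution; the raw patch
# scores feed least-squares losses.

gan_dims <- function(config) {
  W <- config@outputShape[1]; H <- config@outputShape[3]
  cups <- as.integer(log2(W / config@bottleneckShape[1]))
  vups <- cups - 1L
  npool <- as.integer(log2(W / 4))
  chc <- tail(config@decoderChannels, cups)
  list(W = W, H = H, cups = cups, vups = vups, npool = npool,
       chc = chc, chv = chc[seq_len(vups)], ench = config@encoderChannels)
}

#' Build an untrained generator
#'
#' Allocates He-initialised weights for the dual-view encoder / fused 3D
#' decoder architecture described in [GeneratorConfig-class].
#'
#' @param config a [GeneratorConfig-class].
#' @param seed optional seed for the weight initialisation (otherwise the
#'   current RNG state is used).
#' @return a [SpineGenerator-class].
#' @examples
#' g <- buildGenerator(generatorConfig(scale = 1/4), seed = 1)
#' @export
buildGenerator <- function(config, seed = NULL) {
  validObject(config)
  dm <- gan_dims(config)
  build <- function() {
    enc1 <- function() {
      blocks <- list(); cin <- 1L
      for (i in 1:8) {
        k <- if (i == 1) config@firstKernel else config@otherKernel
        blocks[[i]] <- conv_block_params(c(k, k), cin, dm$ench[i])
        cin <- dm$ench[i]
      }
      blocks
    }
    dec1 <- function() {
      blocks <- list()
      cin <- dm$ench[8]
      for (j in seq_len(dm$vups)) {
        skipch <- dm$ench[9 - j]
        k <- config@otherKernel
        blocks[[j]] <- conv_block_params(c(k, k), cin + skipch, dm$chv[j])
        cin <- dm$chv[j]
      }
      blocks
    }
    cen <- list(); cin <- dm$ench[8]
    for (j in seq_len(dm$cups)) {
      k <- config@otherKernel
      cen[[j]] <- conv_block_params(c(k, k, k), cin, dm$chc[j])
      cin <- dm$chc[j]
    }
    fin <- conv_block_params(c(3, 3, 3), cin, 1L, bn = FALSE)
    list(enc = list(ap = enc1(), lat = enc1()),
         dec = list(ap = dec1(), lat = dec1()),
         cen = cen, fin = fin)
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  state <- list(
    enc = list(ap = lapply(dm$ench, bn_state0), lat = lapply(dm$ench, bn_state0)),
    dec = list(ap = lapply(dm$chv, bn_state0), lat = lapply(dm$chv, bn_state0)),
    cen = lapply(dm$chc, bn_state0))
  new("SpineGenerator", config = config, params = params, state = state)
}

#' Build an untrained discriminator
#'
#' @param config a [DiscriminatorConfig-class].
#' @param seed optional initialisation seed.
#' @return a [SpineDiscriminator-class].
#' @export
buildDiscriminator <- function(config = discriminatorConfig(), seed = NULL) {
  validObject(config)
  k <- config@kernel
  build <- function() {
    layers <- list(); cin <- 3L
    for (i in seq_along(config@channels)) {
      layers[[i]] <- conv_block_params(c(k, k, k), cin, config@channels[i],
                                       bn = i > 1)
      cin <- config@channels[i]
    }
    fin <- conv_block_params(c(k, k, k), cin, config@finalChannels, bn = FALSE)
    list(layers = layers, fin = fin)
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  nch <- config@channels
  state <- list(layers = c(list(NULL), lapply(nch[-1], bn_state0)))
  new("SpineDiscriminator", config = config, params = params, state = state)
}

# ---- generator forward ----------------------------------------------------

as_batch2d <- function(img) {
  if (is.matrix(img)) array(img, c(dim(img), 1L, 1L))
  else array(img, c(dim(img)[1:2], 1L, dim(img)[3]))
}

# one encoder block; returns output, cache and updated bn state
enc_block_f <- function(x, p, st, resid, pool, training) {
  cf <- conv2d_f(x, p$w, p$b)
  bn <- bn_f(cf$y, p$gamma, p$beta, st$rm, st$rv, training)
  a <- relu_f(bn$y)
  s <- if (resid) a + x else a
  if (pool) {
    mp <- .maxpool2d_fw(s)
    out <- mp$y; idx <- mp$idx
  } else { out <- s; idx <- NULL }
  list(out = out,
       cache = list(x = x, meta = cf, bncache = bn$cache, bnout = bn$y,
                    resid = resid, poolidx = idx, predim = dim(s)),
       st = list(rm = bn$rm, rv = bn$rv))
}

enc_block_b <- function(dout, p, cache, need_dx) {
  ds <- if (!is.null(cache$poolidx))
    .maxpool2d_bw(dout, cache$poolidx, as.integer(cache$predim)) else dout
  da <- relu_b(ds, cache$bnout)
  bnb <- bn_b(da, cache$bncache)
  cb <- conv2d_b(cache$x, p$w, bnb$dx, cache$meta, need_dx = need_dx || cache$resid)
  dx <- if (need_dx || cache$resid) cb$dx else NULL
  if (cache$resid) dx <- dx + ds
  list(dx = dx, grads = list(w = cb$dw, b = cb$db,
                             gamma = bnb$dgamma, beta = bnb$dbeta))
}

encoder_f <- function(x, pview, sview, dm, training) {
  caches <- list(); skips <- list(); sts <- list()
  for (i in 1:8) {
    resid <- i >= 2 && dm$ench[i] == dim(x)[3]
    r <- enc_block_f(x, pview[[i]], sview[[i]], resid, pool = i <= dm$npool,
                     training)
    x <- r$out; caches[[i]] <- r$cache; skips[[i]] <- r$out; sts[[i]] <- r$st
  }
  list(bottleneck = x, skips = skips, caches = caches, st = sts)
}

viewdec_f <- function(bott, skips, pview, sview, dm, training) {
  t <- bott; feats <- list(); caches <- list(); sts <- list()
  for (j in seq_len(dm$vups)) {
    tu <- up2_f(t)
    rz <- resize2_nearest(skips[[9 - j]], dim(tu)[1:2])
    tc <- cat_ch(tu, rz$y)
    cf <- conv2d_f(tc, pview[[j]]$w, pview[[j]]$b)
    bn <- bn_f(cf$y, pview[[j]]$gamma, pview[[j]]$beta,
               sview[[j]]$rm, sview[[j]]$rv, training)
    t <- relu_f(bn$y)
    feats[[j]] <- t
    caches[[j]] <- list(tc = tc, meta = cf, bncache = bn$cache, bnout = bn$y,
                        rz = rz, cin = dim(tu)[3])
    sts[[j]] <- list(rm = bn$rm, rv = bn$rv)
  }
  list(feats = feats, caches = caches, st = sts)
}

g_forward <- function(gen, ap, lat, training = TRUE) {
  dm <- gan_dims(gen@config)
  ap <- as_batch2d(ap); lat <- as_batch2d(lat)
  if (dim(ap)[1] != dm$W || dim(ap)[2] != dm$H)
    stop("input images must be ", dm$W, "x", dm$H, " for this generator",
         call. = FALSE)
  p <- gen@params; st <- gen@state

  eAP <- encoder_f(ap, p$enc$ap, st$enc$ap, dm, training)
  eLat <- encoder_f(lat, p$enc$lat, st$enc$lat, dm, training)
  dAP <- viewdec_f(eAP$bottleneck, eAP$skips, p$dec$ap, st$dec$ap, dm, training)
  dLat <- viewdec_f(eLat$bottleneck, eLat$skips, p$dec$lat, st$dec$lat, dm, training)

  N <- dim(ap)[4]
  ny0 <- dim(eAP$bottleneck)[1]      # bottleneck is (4, 8, C, N)
  F <- (tile_y_f(eAP$bottleneck, ny0) + tile_x_f(eLat$bottleneck, ny0)) / 2
  cenCaches <- list(); cenSt <- list()
  for (j in seq_len(dm$cups)) {
    Fu <- up3_f(F)
    cf <- conv3d_f(Fu, p$cen[[j]]$w, p$cen[[j]]$b)
    bn <- bn_f(cf$y, p$cen[[j]]$gamma, p$cen[[j]]$beta,
               st$cen[[j]]$rm, st$cen[[j]]$rv, training)
    a <- relu_f(bn$y)
    fused <- j <= dm$vups
    if (fused) {
      n_tile <- dim(a)[1]
      F <- (a + tile_y_f(dAP$feats[[j]], n_tile) +
                tile_x_f(dLat$feats[[j]], n_tile)) / 3
    } else F <- a
    cenCaches[[j]] <- list(x = Fu, meta = cf, bncache = bn$cache, bnout = bn$y,
                           fused = fused)
    cenSt[[j]] <- list(rm = bn$rm, rv = bn$rv)
  }
  ff <- conv3d_f(F, p$fin$w, p$fin$b)
  out5 <- sigmoid_f(ff$y)
  out <- array(out5, dim(out5)[c(1, 2, 3, 5)])

  state <- list(enc = list(ap = eAP$st, lat = eLat$st),
                dec = list(ap = dAP$st, lat = dLat$st), cen = cenSt)
  list(out = out, state = state,
       cache = list(eAP = eAP, eLat = eLat, dAP = dAP, dLat = dLat,
                    cen = cenCaches, Ffin = F, finmeta = ff, out5 = out5,
                    dm = dm))
}

# ---- generator backward ---------------------------------------------------

viewdec_b <- function(dfeats, caches, pview, dm) {
  # dfeats: list of gradients w.r.t. each decoder stage output (may contain
  # NULLs); returns gradient w.r.t. the bottleneck, per-skip gradients and
  # parameter grads
  vups <- dm$vups
  grads <- vector("list", vups)
  dskips <- list()
  dt <- NULL
  for (j in rev(seq_len(vups))) {
    g <- dfeats[[j]]
    if (!is.null(dt)) g <- if (is.null(g)) dt else g + dt
    if (is.null(g)) g <- array(0, dim(caches[[j]]$bnout))
    da <- relu_b(g, caches[[j]]$bnout)
    bnb <- bn_b(da, caches[[j]]$bncache)
    cb <- conv2d_b(caches[[j]]$tc, pview[[j]]$w, bnb$dx, caches[[j]]$meta)
    grads[[j]] <- list(w = cb$dw, b = cb$db, gamma = bnb$dgamma,
                       beta = bnb$dbeta)
    sp <- split_ch(cb$dx, caches[[j]]$cin)
    dskip <- resize2_nearest_b(sp$b, caches[[j]]$rz)
    key <- as.character(9 - j)
    dskips[[key]] <- if (is.null(dskips[[key]])) dskip else dskips[[key]] + dskip
    dt <- up2_b(sp$a)
  }
  list(dbott = dt, dskips = dskips, grads = grads)
}

encoder_b <- function(dbott, dskips, caches, pview, dm) {
  grads <- vector("list", 8)
  g <- dbott   # gradient w.r.t. block 8 output
  for (i in 8:1) {
    ds <- dskips[[as.character(i)]]
    if (!is.null(ds)) g <- g + ds
    r <- enc_block_b(g, pview[[i]], caches[[i]], need_dx = i > 1)
    grads[[i]] <- r$grads
    if (i > 1) g <- r$dx
  }
  grads
}

g_backward <- function(gen, cache, dout) {
  p <- gen@params; dm <- cache$dm
  d5 <- array(dout, dim(cache$out5))
  dlog <- d5 * cache$out5 * (1 - cache$out5)
  fb <- conv3d_b(cache$Ffin, p$fin$w, dlog, cache$finmeta)
  gfin <- list(w = fb$dw, b = fb$db)
  dF <- fb$dx

  cenGrads <- vector("list", dm$cups)
  dAPfeats <- vector("list", dm$vups)
  dLatfeats <- vector("list", dm$vups)
  for (j in rev(seq_len(dm$cups))) {
    cc <- cache$cen[[j]]
    if (cc$fused) {
      dAPfeats[[j]] <- tile_y_b(dF) / 3
      dLatfeats[[j]] <- tile_x_b(dF) / 3
      da <- dF / 3
    } else da <- dF
    da <- relu_b(da, cc$bnout)
    bnb <- bn_b(da, cc$bncache)
    cb <- conv3d_b(cc$x, p$cen[[j]]$w, bnb$dx, cc$meta)
    cenGrads[[j]] <- list(w = cb$dw, b = cb$db, gamma = bnb$dgamma,
                          beta = bnb$dbeta)
    dF <- up3_b(cb$dx)
  }
  dbottAP <- tile_y_b(dF) / 2
  dbottLat <- tile_x_b(dF) / 2

  vAP <- viewdec_b(dAPfeats, cache$dAP$caches, p$dec$ap, dm)
  vLat <- viewdec_b(dLatfeats, cache$dLat$caches, p$dec$lat, dm)

  encAP <- encoder_b(dbottAP + vAP$dbott, vAP$dskips, cache$eAP$caches,
                     p$enc$ap, dm)
  encLat <- encoder_b(dbottLat + vLat$dbott, vLat$dskips, cache$eLat$caches,
                      p$enc$lat, dm)

  list(enc = list(ap = encAP, lat = encLat),
       dec = list(ap = vAP$grads, lat = vLat$grads),
       cen = cenGrads, fin = gfin)
}

# ---- discriminator --------------------------------------------------------

cond_volume <- function(cand, ap, lat) {
  d <- dim(cand)                       # (X, Y, Z, N)
  apf <- array(ap, c(d[1], d[3], 1L, d[4]))
  latf <- array(lat, c(d[2], d[3], 1L, d[4]))
  cand5 <- array(cand, c(d[1:3], 1L, d[4]))
  cat_ch(cat_ch(cand5, tile_y_f(apf, d[2])), tile_x_f(latf, d[1]))
}

d_forward <- function(disc, cand, ap, lat, training = TRUE) {
  if (dim(cand)[1] < 16)
    stop("discriminator input smaller than its receptive field", call. = FALSE)
  ap <- if (is.matrix(ap)) array(ap, c(dim(ap), dim(cand)[4])) else ap
  lat <- if (is.matrix(lat)) array(lat, c(dim(lat), dim(cand)[4])) else lat
  x <- cond_volume(cand, ap, lat)
  p <- disc@params; st <- disc@state
  slope <- disc@config@leakySlope
  caches <- list(); sts <- list(NULL)
  for (i in seq_along(p$layers)) {
    cf <- conv3d_f(x, p$layers[[i]]$w, p$layers[[i]]$b, stride = 2L)
    if (i > 1) {
      bn <- bn_f(cf$y, p$layers[[i]]$gamma, p$layers[[i]]$beta,
                 st$layers[[i]]$rm, st$layers[[i]]$rv, training)
      pre <- bn$y
      sts[[i]] <- list(rm = bn$rm, rv = bn$rv)
      bncache <- bn$cache
    } else { pre <- cf$y; bncache <- NULL }
    a <- lrelu_f(pre, slope)
    caches[[i]] <- list(x = x, meta = cf, bncache = bncache, pre = pre)
    x <- a
  }
  ff <- conv3d_f(x, p$fin$w, p$fin$b)
  scores <- array(ff$y, dim(ff$y)[c(1, 2, 3, 5)])
  caches$fin <- list(x = x, meta = ff)
  list(scores = scores, cache = caches, state = list(layers = sts),
       score5 = ff$y)
}

d_backward <- function(disc, cache, dscores, need_input = FALSE,
                       weight_grads = TRUE) {
  # weight_grads = FALSE gives the cheap input-gradient-only pass used for
  # the generator update (skips im2col and the dW GEMMs)
  p <- disc@params; slope <- disc@config@leakySlope
  dsc5 <- array(dscores, dim(cache$fin$meta$y))
  fb <- conv3d_b(cache$fin$x, p$fin$w, dsc5, cache$fin$meta,
                 need_dw = weight_grads)
  gfin <- list(w = fb$dw, b = fb$db)
  dx <- fb$dx
  n <- length(p$layers)
  grads <- vector("list", n)
  for (i in n:1) {
    cc <- cache[[i]]
    da <- lrelu_b(dx, cc$pre, slope)
    if (!is.null(cc$bncache)) {
      bnb <- bn_b(da, cc$bncache)
      dz <- bnb$dx
      gbn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    } else { dz <- da; gbn <- NULL }
    cb <- conv3d_b(cc$x, p$layers[[i]]$w, dz, cc$meta,
                   need_dx = i > 1 || need_input, need_dw = weight_grads)
    grads[[i]] <- c(list(w = cb$dw, b = cb$db), gbn)
    dx <- cb$dx
  }
  dcand <- NULL
  if (need_input) {
    d <- dim(dx)
    dcand <- array(dx[, , , 1, ], d[c(1, 2, 3, 5)])
  }
  list(grads = list(layers = grads, fin = gfin), dcand = dcand)
}
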