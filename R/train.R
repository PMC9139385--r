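# LSGAN + reconstruction losses and the alternating training loop.

#' Least-squares discriminator loss
#'
#' \code{0.5 * mean((D(real) - 1)^2) + 0.5 * mean(D(fake)^2)} over all patch
#' scores.
#'
#' @param d_real,d_fake patch-score arrays of identical shape.
#' @return non-negative scalar.
#' @examples
#' lsganDLoss(array(1, c(2, 2)), array(0, c(2, 2)))   # 0
#' @export
lsganDLoss <- function(d_real, d_fake) {
  if (!identical(dim(d_real) %||% length(d_real),
                 dim(d_fake) %||% length(d_fake)))
    stop("score grids must share shape", call. = FALSE)
  0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2)
}

#' Least-squares generator loss
#'
#' \code{0.5 * mean((D(fake) - 1)^2)}.
#'
#' @param d_fake patch scores of the generated sample.
#' @return non-negative scalar.
#' @export
lsganGLoss <- function(d_fake) {
  if (!all(is.finite(d_fake))) stop("scores must be finite", call. = FALSE)
  0.5 * mean((d_fake - 1)^2)
}

#' Voxelwise reconstruction loss (MSE)
#'
#' @param y ground-truth volume.
#' @param g generated volume of the same shape.
#' @return mean squared voxel difference.
#' @export
reconstructionLoss <- function(y, g) {
  if (!identical(dim(y), dim(g))) stop("shape mismatch", call. = FALSE)
  mean((y - g)^2)
}

#' Combined generator objective
#'
#' \code{lambda1 * adversarial + lambda2 * reconstruction} with the
#' reference weighting lambda1 = 2, lambda2 = 100.
#'
#' @param lsgan_g adversarial generator loss.
#' @param l_re reconstruction loss.
#' @param w a [LossWeights-class].
#' @return scalar.
#' @examples
#' totalGLoss(0.5, 0.01, lossWeights())   # 2
#' @export
totalGLoss <- function(lsgan_g, l_re, w = lossWeights()) {
  w@lambda1 * lsgan_g + w@lambda2 * l_re
}

# stack a list of (W,H) matrices / 3D arrays into a batch array
stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), c(d, length(lst)))
}

#' Train the conditional GAN
#'
#' Alternating least-squares updates: per minibatch the discriminator takes
#' one Adam step on real and generated volumes (generated volumes detached),
#' then the generator takes one Adam step on the combined objective
#' \code{lambda1 * LSGAN + lambda2 * MSE}. The discriminator sees
#' probability maps (binarisation happens only at inference). Fully
#' reproducible given the seed in \code{tcfg}.
#'
#' @param dataset non-empty list of cases, each a list with elements
#'   \code{pair} ([DRRPair-class]) and \code{gt} ([SegmentationVolume-class]
#'   on the generator output grid).
#' @param gcfg,dcfg,w,tcfg generator / discriminator / loss-weight /
#'   training configurations.
#' @param valDataset optional validation cases (same structure); per-epoch
#'   validation reconstruction loss is recorded.
#' @param verbose print per-epoch losses.
#' @return list with \code{generator} (trained [SpineGenerator-class]),
#'   \code{history} (data.frame epoch, g_loss, g_adv, g_recon, d_loss,
#'   val_loss) and \code{discriminator}.
#' @export
trainGan <- function(dataset, gcfg = generatorConfig(1 / 4),
                     dcfg = discriminatorConfig(), w = lossWeights(),
                     tcfg = trainConfig(), valDataset = NULL,
                     verbose = FALSE) {
  if (length(dataset) == 0) stop("dataset must be non-empty", call. = FALSE)
  validObject(tcfg); validObject(w)

  os <- gcfg@outputShape
  for (cs in dataset) {
    if (!identical(dim(cs$gt@mask), as.integer(os)))
      stop("ground-truth grid does not match generator output shape",
           call. = FALSE)
  }

  with_seed(tcfg@seed, {
    gen <- buildGenerator(gcfg)
    disc <- buildDiscriminator(dcfg)
    adamG <- adam_init(gen@params)
    adamD <- adam_init(disc@params)
    betas <- tcfg@optimizerBetas; lr <- tcfg@learningRate
    hist <- data.frame()

    aps <- lapply(dataset, function(cs) cs$pair@ap)
    lats <- lapply(dataset, function(cs) cs$pair@lat)
    gts <- lapply(dataset, function(cs) cs$gt@mask)

    for (ep in seq_len(tcfg@epochs)) {
      ord <- sample(length(dataset))
      bs <- min(tcfg@batchSize, length(dataset))
      gl_ep <- ga_ep <- gr_ep <- dl_ep <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = bs)) {
        sel <- ord[b0:min(b0 + bs - 1, length(ord))]
        ap <- stack_batch(aps[sel]); lat <- stack_batch(lats[sel])
        yv <- stack_batch(gts[sel])

        gf <- g_forward(gen, ap, lat, training = TRUE)
        gen@state <- gf$state
        fake <- gf$out

        # Simultaneous-update variant: both players' gradients are taken at
        # the current parameters, sharing one forward pass on the generated
        # volume (the fake is detached for the discriminator's own step).
        dr <- d_forward(disc, yv, ap, lat, training = TRUE)
        disc@state <- dr$state
        df <- d_forward(disc, fake, ap, lat, training = TRUE)
        disc@state <- df$state
        dl <- lsganDLoss(dr$scores, df$scores)
        np <- length(dr$scores)
        gr <- d_backward(disc, dr$cache, (dr$scores - 1) / np)
        gfk <- d_backward(disc, df$cache, df$scores / np)
        dgrads <- tree_map2(`+`, gr$grads, gfk$grads)

        # generator gradients through the (pre-update) discriminator
        ga <- lsganGLoss(df$scores)
        grec <- reconstructionLoss(yv, fake)
        gl <- totalGLoss(ga, grec, w)
        db <- d_backward(disc, df$cache,
                         w@lambda1 * (df$scores - 1) / np,
                         need_input = TRUE, weight_grads = FALSE)
        dfake <- db$dcand + w@lambda2 * 2 * (fake - yv) / length(fake)
        ggrads <- g_backward(gen, gf$cache, dfake)

        stD <- adam_step(disc@params, dgrads, adamD, lr, betas)
        disc@params <- stD$params; adamD <- stD$state
        stG <- adam_step(gen@params, ggrads, adamG, lr, betas)
        gen@params <- stG$params; adamG <- stG$state

        if (!is.finite(gl) || !is.finite(dl))
          stop("NaN/Inf loss at epoch ", ep, " (g = ", gl, ", d = ", dl,
               "); reduce the learning rate or check the inputs",
               call. = FALSE)
        gl_ep <- gl_ep + gl; ga_ep <- ga_ep + ga; gr_ep <- gr_ep + grec
        dl_ep <- dl_ep + dl; nb <- nb + 1
      }
      vl <- NA_real_
      if (!is.null(valDataset) && length(valDataset)) {
        vap <- stack_batch(lapply(valDataset, function(cs) cs$pair@ap))
        vlat <- stack_batch(lapply(valDataset, function(cs) cs$pair@lat))
        vgt <- stack_batch(lapply(valDataset, function(cs) cs$gt@mask))
        vf <- g_forward(gen, vap, vlat, training = FALSE)
        vl <- reconstructionLoss(vgt, vf$out)
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, g_loss = gl_ep / nb, g_adv = ga_ep / nb,
        g_recon = gr_ep / nb, d_loss = dl_ep / nb, val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  G %.4f (adv %.4f, recon %.4f)  D %.4f  val %s",
                        ep, gl_ep / nb, ga_ep / nb, gr_ep / nb, dl_ep / nb,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    }
  })
  list(generator = gen, history = hist, discriminator = disc)
}

#' Predict a binary spine volume from a radiograph pair
#'
#' Runs the generator in inference mode (batch-norm running statistics) and
#' thresholds the probability map: voxel = 1 iff probability >= threshold
#' (reference threshold 0.4).
#'
#' @param generator a trained [SpineGenerator-class].
#' @param pair a [DRRPair-class] matching the generator input shape.
#' @param threshold binarisation threshold in (0, 1).
#' @param spacingMm voxel spacing recorded in the output volume.
#' @return a [SegmentationVolume-class].
#' @export
predictVolume <- function(generator, pair, threshold = 0.4,
                          spacingMm = c(1, 1, 1)) {
  dm <- gan_dims(generator@config)
  if (!identical(dim(pair@ap), as.integer(c(dm$W, dm$H))))
    stop("radiograph shape does not match the generator input", call. = FALSE)
  gf <- g_forward(generator, pair@ap, pair@lat, training = FALSE)
  segmentationVolume(array(as.numeric(gf$out >= threshold), dim(gf$out)[1:3]),
                     spacingMm = spacingMm)
}

#' @describeIn predictVolume S4 predict method.
#' @param object a [SpineGenerator-class].
#' @param ... forwarded to \code{predictVolume}.
#' @export
setMethod("predict", "SpineGenerator", function(object, ...) {
  predictVolume(object, ...)
})

#' Prepare one training case from a phantom
#'
#' Converts a CT/segmentation pair into GAN-ready tensors under a signal
#' condition: the CT is enhanced (or rescale-inverted for "original"),
#' projected into an AP/Lat radiograph pair cropped to the dilated
#' mask-tight spine ROI, and the ground-truth mask is cropped to the same
#' ROI and resampled (nearest neighbour) onto the generator output grid.
#'
#' @param ct a [CTVolume-class].
#' @param seg the paired [SegmentationVolume-class].
#' @param condition "enhanced" or "original".
#' @param scale generator resolution scale (1, 1/2, 1/4).
#' @param dilate ROI margin in voxels.
#' @param sourceId case identifier.
#' @return list with \code{pair} ([DRRPair-class]) and \code{gt}
#'   ([SegmentationVolume-class] on the scale * (128, 128, 256) grid).
#' @export
prepareTrainingCase <- function(ct, seg, condition = c("enhanced", "original"),
                                scale = 1 / 4, dilate = 8,
                                sourceId = "case") {
  condition <- match.arg(condition)
  sig <- if (condition == "enhanced") enhanceVolume(ct) else
    originalSignalVolume(ct)
  roi <- defaultCropROI(seg, dilate = dilate)
  pair <- makeBiplanar(sig, geometry = scale, crop = roi, mask = seg,
                       sourceId = sourceId)
  m <- seg@mask[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2],
                drop = FALSE]
  out <- as.integer(round(c(128, 128, 256) * scale))
  gt <- resample_nearest3(m, out)
  newsp <- seg@spacingMm * dim(m) / out
  list(pair = pair, gt = segmentationVolume(gt, spacingMm = newsp))
}

# nearest-neighbour resample of a 3D array onto a new grid
resample_nearest3 <- function(a, newdim) {
  d <- dim(a)
  ix <- pmin(d[1], pmax(1, ceiling((seq_len(newdim[1]) - 0.5) * d[1] / newdim[1])))
  iy <- pmin(d[2], pmax(1, ceiling((seq_len(newdim[2]) - 0.5) * d[2] / newdim[2])))
  iz <- pmin(d[3], pmax(1, ceiling((seq_len(newdim[3]) - 0.5) * d[3] / newdim[3])))
  a[ix, iy, iz, drop = FALSE]
}
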