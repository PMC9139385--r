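# Volumetric overlap metrics and projection SSIM.

as_binary_array <- function(x) {
  a <- if (is(x, "SegmentationVolume")) x@mask else x
  if (!all(a %in% c(0, 1))) stop("volume must be binary", call. = FALSE)
  a
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes must share the same grid", call. = FALSE)
}

#' Dice similarity coefficient
#'
#' \code{2|A n B| / (|A| + |B|)} for binary volumes. Two empty volumes give
#' 1 with a warning (vacuous perfect agreement).
#'
#' @param A,B binary arrays or [SegmentationVolume-class] objects of the
#'   same shape.
#' @return scalar in [0, 1].
#' @examples
#' a <- array(c(1, 1, 0, 0), c(2, 2, 1)); b <- array(c(1, 0, 1, 0), c(2, 2, 1))
#' dsc(a, b)   # 0.5
#' @export
dsc <- function(A, B) {
  a <- as_binary_array(A); b <- as_binary_array(B)
  check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both volumes empty: DSC defined as 1")
    return(1)
  }
  2 * sum(a * b) / (sa + sb)
}

#' Jaccard similarity coefficient
#'
#' \code{|A n B| / |A u B|}; empty-vs-empty gives 1 with a warning.
#'
#' @inheritParams dsc
#' @return scalar in [0, 1].
#' @export
jsc <- function(A, B) {
  a <- as_binary_array(A); b <- as_binary_array(B)
  check_same_shape(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) {
    warning("both volumes empty: JSC defined as 1")
    return(1)
  }
  inter / uni
}

#' Overlap volume
#'
#' \code{|A n B| / min(|A|, |B|)}; 1 whenever one volume contains the
#' other. Errors if either volume is empty (undefined denominator).
#'
#' @inheritParams dsc
#' @return scalar in [0, 1].
#' @export
ov <- function(A, B) {
  a <- as_binary_array(A); b <- as_binary_array(B)
  check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 || sb == 0)
    stop("overlap volume undefined for an empty volume", call. = FALSE)
  sum(a * b) / min(sa, sb)
}

# valid-mode correlation filter of a matrix with a (normalized) window;
# plain double-precision shift-and-add (121 shifted adds for an 11x11
# window), keeping SSIM at full double accuracy
filter_valid <- function(img, w) {
  k1 <- nrow(w); k2 <- ncol(w)
  n1 <- nrow(img) - k1 + 1; n2 <- ncol(img) - k2 + 1
  out <- matrix(0, n1, n2)
  for (j in seq_len(k2)) for (i in seq_len(k1))
    out <- out + w[i, j] * img[i:(i + n1 - 1), j:(j + n2 - 1)]
  out
}

ssim_window <- function(window = 11, sigma = 1.5, uniform = FALSE) {
  if (uniform) return(matrix(1 / window^2, window, window))
  r <- seq_len(window) - (window + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Structural similarity index of two images
#'
#' Windowed SSIM in its standard product form (luminance x contrast x
#' structure, unit exponents) with stabilisers C1 = (0.01 L)^2,
#' C2 = (0.03 L)^2, C3 = C2/2 and dynamic range L = 1 for normalized
#' images. The default window is 11 x 11 with Gaussian weighting
#' (sigma 1.5), matching the canonical reference implementation; set
#' \code{uniform = TRUE} for a flat window. Windows are evaluated at valid
#' (fully inside) positions and averaged.
#'
#' @param x,y numeric matrices in [0, 1], same shape, at least
#'   \code{window} pixels in each dimension.
#' @param window sliding window size (default 11).
#' @param sigma Gaussian window SD.
#' @param uniform use a flat window instead of Gaussian weights.
#' @return scalar in [-1, 1]; 1 iff the images are identical.
#' @export
ssim <- function(x, y, window = 11L, sigma = 1.5, uniform = FALSE) {
  if (!identical(dim(x), dim(y))) stop("images must share shape", call. = FALSE)
  if (any(dim(x) < window))
    stop("image smaller than the sliding window", call. = FALSE)
  w <- ssim_window(window, sigma, uniform)
  C1 <- 0.01^2; C2 <- 0.03^2
  mx <- filter_valid(x, w); my <- filter_valid(y, w)
  sxx <- filter_valid(x * x, w) - mx^2
  syy <- filter_valid(y * y, w) - my^2
  sxy <- filter_valid(x * y, w) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Sum projection of a binary volume for SSIM
#'
#' Parallel-beam line integral of the binary mask along the view axis,
#' min-max normalized to [0, 1]; an all-constant projection normalizes to
#' zeros.
#'
#' @param volume binary array or [SegmentationVolume-class].
#' @param view "AP" or "Lat".
#' @return matrix in [0, 1].
#' @export
projectionForSSIM <- function(volume, view) {
  a <- as_binary_array(volume)
  p <- switch(view,
    AP  = apply(a, c(1, 3), sum),
    Lat = apply(a, c(2, 3), sum),
    stop("unknown view '", view, "'", call. = FALSE))
  rng <- range(p)
  if (rng[2] == rng[1]) return(p * 0)
  (p - rng[1]) / (rng[2] - rng[1])
}

#' Evaluate all five similarity metrics for one case
#'
#' DSC, JSC and OV on the 3D binary volumes, and SSIM between the AP and
#' Lat sum projections of prediction and ground truth.
#'
#' @param pred,gt [SegmentationVolume-class] objects on the same grid.
#' @param caseId identifier stored in the report.
#' @param strict if FALSE, an undefined OV (empty prediction) becomes NA
#'   instead of an error — useful inside evaluation loops.
#' @return a [MetricReport-class].
#' @export
evaluateCase <- function(pred, gt, caseId = "case", strict = TRUE) {
  p <- as_binary_array(pred); g <- as_binary_array(gt)
  check_same_shape(p, g)
  ovv <- if (strict) ov(p, g) else
    tryCatch(ov(p, g), error = function(e) NA_real_)
  new("MetricReport", caseId = caseId,
      dsc = dsc(p, g), jsc = jsc(p, g), ov = ovv,
      ssimAp = ssim(projectionForSSIM(p, "AP"), projectionForSSIM(g, "AP")),
      ssimLat = ssim(projectionForSSIM(p, "Lat"), projectionForSSIM(g, "Lat")))
}
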