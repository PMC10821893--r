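# Primitive image operators. Filtering (despeckle, rolling ball, blur)
# follows the acquisition convention of the source procedures: applied
# per 2D z-slice; object counting is fully 3D.

.as_vol <- function(x, channel = NULL) {
  if (is(x, "ImageStack")) {
    if (is.null(channel)) stop("channel must be given for an ImageStack")
    return(getChannel(x, channel))
  }
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a matrix, 3D array or ImageStack")
}

.wrap_like <- function(x, channel, vol, was_matrix) {
  if (is(x, "ImageStack")) return(setChannel(x, channel, vol))
  if (was_matrix) return(vol[, , 1L])
  vol
}

.per_slice <- function(vol, f) {
  for (z in seq_len(dim(vol)[3L])) vol[, , z] <- f(vol[, , z])
  vol
}

#' 3x3 median despeckle
#'
#' Per-z-slice 3x3 median filter with nearest-neighbour edge padding;
#' the standard salt-and-pepper suppression step applied before
#' intensity readouts.
#'
#' @param x a matrix, a 3D array \code{[y, x, z]}, or an
#'   \linkS4class{ImageStack}.
#' @param channel channel role name, required for an ImageStack.
#' @return same type as \code{x} (ImageStack in, ImageStack out with the
#'   channel replaced).
#' @export
medianDespeckle <- function(x, channel = NULL) {
  vol <- .as_vol(x, channel)
  out <- .per_slice(vol, cpp_median3x3)
  .wrap_like(x, channel, out, is.matrix(x))
}

#' Rolling-ball background estimate
#'
#' Per-z-slice grayscale opening with a non-flat ball (spherical cap)
#' structuring element of the given pixel radius: erosion then dilation
#' with height \eqn{h(d) = \sqrt{r^2 - |d|^2}}. The estimate is a
#' pointwise lower envelope of the input and is idempotent.
#'
#' @inheritParams medianDespeckle
#' @param radius ball radius in pixels (>= 1).
#' @return background image, same type as \code{x}.
#' @export
rollingBallBackground <- function(x, radius, channel = NULL) {
  stopifnot(radius >= 1)
  vol <- .as_vol(x, channel)
  if (floor(radius) > min(dim(vol)[1:2]))
    stop("ball radius exceeds the slice extent")
  out <- .per_slice(vol, function(s) cpp_ball_dilate(
    cpp_ball_erode(s, radius), radius))
  .wrap_like(x, channel, out, is.matrix(x))
}

#' Rolling-ball background subtraction
#'
#' Subtracts the \code{\link{rollingBallBackground}} estimate from the
#' input, clipping at zero. Removes slowly varying background (ramps,
#' vignetting) while preserving puncta narrower than the ball.
#'
#' @inheritParams rollingBallBackground
#' @return background-subtracted image, same type as \code{x}.
#' @export
rollingBallSubtract <- function(x, radius, channel = NULL) {
  vol <- .as_vol(x, channel)
  bg <- .as_vol(rollingBallBackground(vol, radius), NULL)
  out <- pmax(vol - bg, 0)
  .wrap_like(x, channel, out, is.matrix(x))
}

#' Gaussian blur
#'
#' Per-z-slice separable 2D Gaussian convolution with reflective
#' boundaries; the kernel is normalised so total intensity is conserved
#' on interior-supported signals.
#'
#' @inheritParams medianDespeckle
#' @param sigma Gaussian sigma in pixels (> 0).
#' @return blurred image, same type as \code{x}.
#' @export
gaussianBlur <- function(x, sigma, channel = NULL) {
  stopifnot(sigma > 0)
  vol <- .as_vol(x, channel)
  out <- .per_slice(vol, function(s) cpp_gauss_blur(s, sigma))
  .wrap_like(x, channel, out, is.matrix(x))
}

#' Otsu threshold
#'
#' Exhaustive between-class-variance maximisation over a fixed-width
#' histogram of the intensities (256 bins spanning the observed range).
#' Returns the bin-edge intensity maximising the between-class variance;
#' voxels strictly above it are foreground.
#'
#' @param values numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return scalar threshold on the raw intensity scale.
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(
    pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins),
    nbins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nbins))
  n <- w[nbins]
  mtot <- mu[nbins]
  # candidate split after bin k: classes [1..k], [k+1..nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mtot * w0[valid] - n * mu[k][valid])^2 /
    (w0[valid] * w1[valid])
  kbest <- which.max(bcv)
  edges[kbest + 1L]
}

#' Global (batch-frozen) threshold
#'
#' Thresholds one channel into a \linkS4class{BinaryMask}, with
#' membership defined as intensity strictly greater than the threshold.
#' The numeric threshold is either supplied (\code{value}) or computed
#' once by Otsu's method on a designated reference image and then meant
#' to be reused verbatim for every image of a batch; the value and its
#' origin are recorded in the mask provenance.
#'
#' @inheritParams medianDespeckle
#' @param value fixed numeric threshold. Exactly one of \code{value} and
#'   \code{reference} must be given.
#' @param reference image (matrix/array/ImageStack) on which to compute
#'   the Otsu threshold; for an ImageStack the same \code{channel} is
#'   used.
#' @return a \linkS4class{BinaryMask}.
#' @export
globalThreshold <- function(x, channel = NULL, value = NULL,
                            reference = NULL) {
  vol <- .as_vol(x, channel)
  vs <- if (is(x, "ImageStack")) voxelSize(x) else c(0.5, 0.2, 0.2)
  if (is.null(value)) {
    if (is.null(reference))
      stop("automatic thresholding needs a designated reference image")
    value <- otsuThreshold(.as_vol(reference, channel))
    method <- "otsu_on_reference"
  } else {
    method <- "fixed"
  }
  BinaryMask(vol > value, voxelSize = vs,
             provenance = list(channel = channel %||% "",
                               threshold = value, method = method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mask_pair <- function(a, b) {
  ma <- if (is(a, "BinaryMask")) maskData(a) else a
  mb <- if (is(b, "BinaryMask")) maskData(b) else b
  if (!identical(dim(ma), dim(mb))) stop("mask shapes differ")
  list(a = ma, b = mb,
       vs = if (is(a, "BinaryMask")) voxelSize(a) else c(0.5, 0.2, 0.2))
}

#' Mask arithmetic
#'
#' Voxelwise boolean combinations of two masks of identical shape:
#' \code{maskSubtract(a, b)} is \code{a AND NOT b} (its output is
#' disjoint from \code{b} by construction), \code{maskUnion} is OR,
#' \code{maskIntersect} is AND.
#'
#' @param a,b \linkS4class{BinaryMask} objects or logical arrays of
#'   identical shape.
#' @return a \linkS4class{BinaryMask}.
#' @export
maskSubtract <- function(a, b) {
  p <- .mask_pair(a, b)
  BinaryMask(p$a & !p$b, p$vs, provenance = list(op = "subtract"))
}

#' @rdname maskSubtract
#' @export
maskUnion <- function(a, b) {
  p <- .mask_pair(a, b)
  BinaryMask(p$a | p$b, p$vs, provenance = list(op = "union"))
}

#' @rdname maskSubtract
#' @export
maskIntersect <- function(a, b) {
  p <- .mask_pair(a, b)
  BinaryMask(p$a & p$b, p$vs, provenance = list(op = "intersect"))
}

#' 3D connected-component object counting
#'
#' Labels maximal connected components of a binary mask across z under
#' the declared connectivity (default 26), discards components whose
#' voxel count falls outside \code{[minVoxels, maxVoxels]}, and reports
#' per-object voxel counts, calibrated volumes and centroids (and mean
#' intensities when an intensity image is supplied). Surviving labels
#' are renumbered consecutively from 1 in first-encounter order.
#'
#' @param mask a \linkS4class{BinaryMask} or logical 3D array.
#' @param connectivity 6 or 26.
#' @param minVoxels,maxVoxels inclusive size filter in voxels. The
#'   default \code{minVoxels = 2} suppresses single-voxel speckle;
#'   \code{maxVoxels = Inf} disables the upper filter.
#' @param intensity optional numeric array of the mask's shape for
#'   per-object mean intensities.
#' @param voxelSize micrometres per voxel \code{(dz, dy, dx)}; taken
#'   from the mask when it is a BinaryMask.
#' @return list with \code{labels} (integer 3D array) and
#'   \code{objects}, a data.frame with columns \code{label},
#'   \code{voxels}, \code{volume_um3}, centroid \code{z}, \code{y},
#'   \code{x} (1-based voxel indices) and optionally
#'   \code{mean_intensity}.
#' @export
labelObjects3D <- function(mask, connectivity = 26L, minVoxels = 2L,
                           maxVoxels = Inf, intensity = NULL,
                           voxelSize = NULL) {
  if (minVoxels > maxVoxels) stop("minVoxels > maxVoxels")
  m <- if (is(mask, "BinaryMask")) maskData(mask) else mask
  if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
  vs <- voxelSize %||%
    (if (is(mask, "BinaryMask")) voxelSize(mask) else c(0.5, 0.2, 0.2))
  d <- dim(m)
  lab <- cpp_label3d(as.logical(m), d[1L], d[2L], d[3L],
                     as.integer(connectivity))
  nlab <- max(lab)
  dim(lab) <- d
  if (nlab == 0L)
    return(list(labels = lab, objects = data.frame(
      label = integer(), voxels = integer(), volume_um3 = numeric(),
      z = numeric(), y = numeric(), x = numeric())))
  counts <- tabulate(lab, nlab)
  keep <- which(counts >= minVoxels & counts <= maxVoxels)
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  lab[] <- ifelse(lab > 0L, remap[pmax(lab, 1L)], 0L)
  if (!length(keep))
    return(list(labels = lab, objects = data.frame(
      label = integer(), voxels = integer(), volume_um3 = numeric(),
      z = numeric(), y = numeric(), x = numeric())))
  idx <- which(lab > 0L)
  l <- lab[idx]
  ay <- (idx - 1L) %% d[1L] + 1L
  ax <- ((idx - 1L) %/% d[1L]) %% d[2L] + 1L
  az <- (idx - 1L) %/% (d[1L] * d[2L]) + 1L
  nk <- length(keep)
  obj <- data.frame(
    label = seq_len(nk),
    voxels = as.integer(tabulate(l, nk)),
    z = as.numeric(tapply(az, l, mean)),
    y = as.numeric(tapply(ay, l, mean)),
    x = as.numeric(tapply(ax, l, mean)))
  obj$volume_um3 <- obj$voxels * prod(vs)
  if (!is.null(intensity))
    obj$mean_intensity <- as.numeric(tapply(intensity[idx], l, mean))
  obj <- obj[, c("label", "voxels", "volume_um3", "z", "y", "x",
                 if (!is.null(intensity)) "mean_intensity")]
  list(labels = lab, objects = obj)
}

#' Maxima by prominence flooding
#'
#' Finds one point per accepted local maximum of a 2D image within a
#' region. A connected equal-value plateau with no strictly higher
#' neighbour is a candidate; it is rejected if it connects to a strictly
#' higher pixel through pixels of value greater than (its value minus
#' \code{tolerance}), equal-value maxima within tolerance of one another
#' merge to a single reported point, and maxima whose value does not
#' exceed \code{tolerance} (a zero-baseline noise floor; in particular
#' any maximum of value <= 0) are not reported. Plateaus report their
#' centroid.
#'
#' @param image2d numeric matrix.
#' @param tolerance non-negative prominence tolerance on the intensity
#'   scale.
#' @param region logical matrix delimiting the search region (default:
#'   whole image). Pixels outside the region are ignored entirely.
#' @return data.frame with columns \code{y}, \code{x} (1-based, possibly
#'   fractional for plateaus) and \code{value}.
#' @export
findMaxima <- function(image2d, tolerance, region = NULL) {
  stopifnot(is.matrix(image2d), tolerance >= 0)
  if (is.null(region))
    region <- matrix(TRUE, nrow(image2d), ncol(image2d))
  if (is(region, "BinaryMask")) region <- maskData(region)[, , 1L]
  if (!any(region)) stop("empty region")
  m <- cpp_find_maxima(image2d, region, tolerance)
  data.frame(y = m[, 1L], x = m[, 2L], value = m[, 3L])
}

#' Maximum-intensity projection
#'
#' @inheritParams medianDespeckle
#' @return 2D matrix, the voxelwise maximum over z.
#' @export
maxProject <- function(x, channel = NULL) {
  vol <- .as_vol(x, channel)
  apply(vol, c(1L, 2L), max)
}

#' Mean intensity under a mask
#'
#' @param x numeric matrix/array or \linkS4class{ImageStack}.
#' @param mask logical matrix/array or \linkS4class{BinaryMask} of the
#'   same shape; must contain at least one member voxel.
#' @param channel channel role name, for an ImageStack.
#' @return scalar mean intensity.
#' @export
meanIntensity <- function(x, mask = NULL, channel = NULL) {
  vol <- if (is.matrix(x)) x else .as_vol(x, channel)
  if (is.null(mask)) return(mean(vol))
  m <- if (is(mask, "BinaryMask")) maskData(mask) else mask
  if (is.matrix(vol) && length(dim(m)) == 3L) m <- m[, , 1L]
  if (!identical(dim(m), dim(vol))) stop("mask shape differs from image")
  if (!any(m)) stop("empty mask")
  mean(vol[m])
}

#' Area fraction of a 2D mask
#'
#' @param mask2d logical matrix (or single-slice BinaryMask).
#' @return member pixels / total pixels.
#' @export
areaFraction <- function(mask2d) {
  m <- if (is(mask2d, "BinaryMask")) maskData(mask2d)[, , 1L] else mask2d
  mean(m)
}

#' Manders overlap coefficient
#'
#' \deqn{r = \sum_i A_i B_i / \sqrt{\sum_i A_i^2 \sum_i B_i^2}}
#' computed over the union of the two evaluation masks (all voxels when
#' no masks are given). Symmetric in its arguments, invariant to
#' rescaling either channel, and equal to 1 iff the channels are
#' proportional on the evaluation region.
#'
#' @param a,b numeric arrays/matrices of identical shape (channel
#'   intensities).
#' @param maskA,maskB optional logical arrays or
#'   \linkS4class{BinaryMask}s; evaluation region is their union.
#' @return scalar in [0, 1].
#' @export
overlapCoefficient <- function(a, b, maskA = NULL, maskB = NULL) {
  if (!identical(dim(a), dim(b))) stop("channel shapes differ")
  sel <- if (is.null(maskA) && is.null(maskB)) {
    rep(TRUE, length(a))
  } else {
    ma <- if (is.null(maskA)) FALSE else
      (if (is(maskA, "BinaryMask")) maskData(maskA) else maskA)
    mb <- if (is.null(maskB)) FALSE else
      (if (is(maskB, "BinaryMask")) maskData(maskB) else maskB)
    as.logical(ma | mb)
  }
  av <- as.numeric(a)[sel]
  bv <- as.numeric(b)[sel]
  sa <- sum(av * av)
  sb <- sum(bv * bv)
  if (sa == 0 || sb == 0)
    stop("a channel is all zero in the evaluation region")
  sum(av * bv) / sqrt(sa * sb)
}
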