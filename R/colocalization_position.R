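#' Two-channel voxelwise Pearson correlation
#'
#' Pearson correlation between the raw intensities of two co-registered
#' channels, evaluated over a voxel support defined by the channels'
#' foreground masks. The default \code{"union"} support (voxels foreground
#' in at least one channel) deliberately retains exclusion zones — voxels
#' where one signal is present and the other absent — which an intersection
#' rule would hide; thresholding defines the support only, raw intensities
#' always enter the correlation.
#'
#' @param a,b [FilteredStack-class] objects of identical shape.
#' @param support \code{"union"} (default), \code{"intersection"} or
#'   \code{"all"} voxels.
#' @return list with \code{pearson_r}, \code{p_value}, \code{n_voxels},
#'   \code{support_rule}.
#' @examples
#' tc <- generateTwoChannel("shell", seed = 3)
#' channelCorrelation(filterStack(tc$channelA), filterStack(tc$channelB))
#' @export
channelCorrelation <- function(a, b,
                               support = c("union", "intersection", "all")) {
  support <- match.arg(support)
  if (!identical(dim(intensities(a)), dim(intensities(b))))
    stop("geometry error: channel stacks differ in shape")
  sel <- switch(support,
    union = validMask(a) | validMask(b),
    intersection = validMask(a) & validMask(b),
    all = array(TRUE, dim(intensities(a))))
  if (sum(sel) < 3L)
    stop("need at least 3 voxels in the correlation support")
  x <- intensities(a)[sel]; y <- intensities(b)[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance within the support")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_voxels = sum(sel), support_rule = support)
}

#' Center of a signal
#'
#' Intensity-weighted centroid of the foreground voxels (default) or the
#' unweighted centroid of the foreground mask. Returned in 1-based voxel
#' coordinates (z, y, x); multiply by [voxelSize()] for micrometres.
#'
#' @param f a [FilteredStack-class].
#' @param weighted use intensity weights (default TRUE).
#' @return numeric (z, y, x) centroid in voxel coordinates.
#' @export
signalCenter <- function(f, weighted = TRUE) {
  m <- validMask(f)
  if (!any(m)) stop("empty signal: no foreground voxel")
  idx <- which(m, arr.ind = TRUE)
  w <- if (weighted) intensities(f)[m] else rep(1, nrow(idx))
  c(z = sum(idx[, 1] * w), y = sum(idx[, 2] * w),
    x = sum(idx[, 3] * w)) / sum(w)
}

#' Relative positional variance of one signal about another's center
#'
#' Euclidean distances are taken from every foreground voxel of channel A
#' (each voxel counted once, regardless of intensity) to a reference point
#' — typically [signalCenter()] of channel B. The statistic is the variance
#' of those distances divided by their mean, \eqn{\sigma^2 / \mu}: near 0
#' for a thin shell (all voxels equidistant from the center), and R/20 for
#' voxels filling a uniform ball of radius R. It has units of length and
#' scales linearly under isotropic spatial rescaling.
#'
#' @param a a [FilteredStack-class] (channel A).
#' @param center reference point, 1-based voxel coordinates (z, y, x).
#' @param units \code{"um"} (default; distances use [voxelSize()]) or
#'   \code{"voxel"}; the two agree when voxels are isotropic with unit side.
#' @param varType \code{"population"} (default) or \code{"sample"} variance.
#' @param weighted weight voxels by intensity (off by default; the
#'   intensity-weighted variant is provided for exploration only).
#' @return list with \code{center}, \code{mu}, \code{sigma2}, \code{rpv},
#'   \code{n_voxels}, \code{units}.
#' @examples
#' tc <- generateTwoChannel("intermixed", radius = 10, seed = 5)
#' fa <- filterStack(tc$channelA); fb <- filterStack(tc$channelB)
#' relativePositionalVariance(fa, signalCenter(fb), units = "voxel")$rpv
#' @export
relativePositionalVariance <- function(a, center, units = c("um", "voxel"),
                                       varType = c("population", "sample"),
                                       weighted = FALSE) {
  units <- match.arg(units)
  varType <- match.arg(varType)
  m <- validMask(a)
  if (sum(m) < 2L) stop("need at least 2 foreground voxels in channel A")
  idx <- which(m, arr.ind = TRUE)
  scale <- if (units == "um") voxelSize(a) else c(1, 1, 1)
  dz <- (idx[, 1] - center[1]) * scale[1]
  dy <- (idx[, 2] - center[2]) * scale[2]
  dx <- (idx[, 3] - center[3]) * scale[3]
  d <- sqrt(dz^2 + dy^2 + dx^2)
  w <- if (weighted) intensities(a)[m] else rep(1, length(d))
  w <- w / sum(w)
  mu <- sum(w * d)
  if (mu <= 0) stop("undefined statistic: mean distance is zero")
  sigma2 <- sum(w * (d - mu)^2)
  if (varType == "sample" && !weighted)
    sigma2 <- sigma2 * length(d) / (length(d) - 1)
  list(center = center, mu = mu, sigma2 = sigma2, rpv = sigma2 / mu,
       n_voxels = length(d), units = units)
}
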