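#' Otsu background threshold
#'
#' Single-level Otsu threshold: the cut maximizing the between-class
#' variance (equivalently, minimizing the pooled within-class variance) of
#' the quantized intensity histogram. Data with at most \code{nBins}
#' distinct values (e.g. any 8-bit image) get one histogram bin per value,
#' so the result is exact: the returned threshold is the midpoint between
#' the largest background value and the smallest foreground value of the
#' optimal split. Otherwise \code{nBins} equal-width bins over
#' \code{[min, max]} are used, with bin centres standing in for the values
#' and the threshold placed at the separating bin edge.
#'
#' The returned value t defines the foreground as intensities strictly
#' greater than t (ties at t are background). Ties in the criterion are
#' broken towards the smallest threshold.
#'
#' @param values numeric vector (or array) of intensities.
#' @param nBins histogram resolution (default 256).
#' @return A single numeric threshold.
#' @examples
#' otsuThreshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L)
    stop("need at least 2 intensity values")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("degenerate input: all intensity values identical")
  u <- sort(unique(v))
  exact <- length(u) <= nBins
  if (exact) {
    levels <- u
    h <- tabulate(match(v, u), nbins = length(u))
  } else {
    width <- (hi - lo) / nBins
    idx <- pmin(pmax(ceiling((v - lo) / width), 1L), nBins)
    h <- tabulate(idx, nbins = nBins)
    levels <- lo + (seq_len(nBins) - 0.5) * width  # bin centres
  }
  n <- length(v)
  w1 <- cumsum(h)
  s1 <- cumsum(h * levels)
  total <- s1[length(s1)]
  k <- seq_len(length(h) - 1L)          # candidate splits: class1 = bins 1..k
  w1k <- w1[k]; w2k <- n - w1k
  ok <- w1k > 0 & w2k > 0
  mu1 <- s1[k] / w1k
  mu2 <- (total - s1[k]) / w2k
  sigma_b <- w1k * w2k * (mu1 - mu2)^2
  sigma_b[!ok] <- -Inf
  best <- which.max(sigma_b)            # first maximum -> smallest threshold
  if (exact) (levels[best] + levels[best + 1L]) / 2
  else lo + best * (hi - lo) / nBins
}

#' Apply a background threshold to a stack
#'
#' Computes the Otsu threshold over all voxels of the stack (or uses a
#' supplied one) and marks every voxel strictly above it as foreground.
#' Sub-threshold voxels are flagged invalid rather than altered, which is
#' equivalent to the convention of setting them to NaN: they are excluded
#' from all downstream statistics while original intensities remain
#' available.
#'
#' @param stack a [VoxelStack-class].
#' @param threshold optional numeric threshold to use instead of Otsu.
#' @return A [FilteredStack-class].
#' @examples
#' a <- array(5, c(3, 8, 8)); a[2, 3:5, 3:5] <- 100
#' f <- filterStack(VoxelStack(a))
#' foregroundVolume(f)
#' @export
filterStack <- function(stack, threshold = NULL) {
  a <- intensities(stack)
  t <- if (is.null(threshold)) otsuThreshold(a) else as.numeric(threshold)
  mask <- a > t
  if (!any(mask))
    stop("empty foreground: no voxel above threshold ", format(t))
  new("FilteredStack", source = stack, threshold = t,
      validMask = array(mask, dim(a)))
}

#' Threshold a 2D projection
#'
#' Same contract as [filterStack()] but for a [ProjectionImage-class]; used
#' by the homogeneity path, which thresholds the projection rather than the
#' stack.
#'
#' @param projection a [ProjectionImage-class].
#' @param threshold optional numeric threshold to use instead of Otsu.
#' @return list with elements \code{threshold} and logical \code{mask}.
#' @export
filterProjection <- function(projection, threshold = NULL) {
  img <- intensities(projection)
  t <- if (is.null(threshold)) otsuThreshold(img) else as.numeric(threshold)
  mask <- img > t
  if (!any(mask))
    stop("empty foreground: no pixel above threshold ", format(t))
  list(threshold = t, mask = mask)
}
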