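#' Rescale foreground intensities to [0, 1]
#'
#' Min-max rescaling of the valid (above-background) pixels: the minimum
#' maps to 0 and the maximum to 1. Invalid pixels stay NA.
#'
#' @param img numeric matrix (e.g. a projection's intensities).
#' @param mask logical matrix of valid pixels.
#' @return numeric matrix with valid pixels in [0, 1] and NA elsewhere.
#' @export
rescaleForeground <- function(img, mask) {
  if (!any(mask)) stop("empty foreground: nothing to rescale")
  v <- img[mask]
  lo <- min(v); hi <- max(v)
  out <- matrix(NA_real_, nrow(img), ncol(img))
  out[mask] <- if (hi == lo) 0 else (v - lo) / (hi - lo)
  out
}

#' Quantize a [0, 1] image to discrete gray levels
#'
#' Linear scaling of [0, 1] to the integers 1..\code{nLevels} by
#' round-to-nearest (halves away from zero), the convention of the standard
#' co-occurrence routines: \code{level = floor(x * (nLevels - 1) + 0.5) + 1}.
#' So 0 maps to level 1, 1 to level \code{nLevels}, and 0.5 to level 5 at
#' the default 8 levels. Equivalently, equal-width bins of width
#' \code{1/(nLevels-1)} centred on \code{k/(nLevels-1)} (the two extreme
#' bins are half-width), with deterministic edge handling.
#'
#' @param scaled numeric matrix with valid values in [0, 1], NA elsewhere.
#' @param nLevels number of gray levels (default 8).
#' @return integer matrix of levels 1..nLevels, NA on invalid pixels.
#' @examples
#' quantizeLevels(matrix(c(0, 0.5, 1), 1))
#' @export
quantizeLevels <- function(scaled, nLevels = 8L) {
  ok <- !is.na(scaled)
  if (any(scaled[ok] < 0 | scaled[ok] > 1))
    stop("scaled values must lie in [0, 1]")
  q <- matrix(NA_integer_, nrow(scaled), ncol(scaled))
  q[ok] <- as.integer(floor(scaled[ok] * (nLevels - 1) + 0.5)) + 1L
  q
}

#' Gray-level co-occurrence matrix (horizontal offset)
#'
#' Counts, for every pair of horizontally adjacent valid pixels
#' ((y, x), (y, x + 1)), the quantized level pair (i, j). Accumulation is
#' over the single offset (0, +1) and is not symmetrized; any pair touching
#' an invalid (NA) pixel is skipped.
#'
#' @param quantized integer matrix of levels 1..nLevels with NA on invalid
#'   pixels, as produced by [quantizeLevels()].
#' @param nLevels number of gray levels (default 8).
#' @return A [CooccurrenceMatrix-class].
#' @export
cooccurrence <- function(quantized, nLevels = 8L) {
  if (ncol(quantized) < 2L)
    stop("unscoreable image: no horizontal neighbour exists")
  left <- quantized[, -ncol(quantized), drop = FALSE]
  right <- quantized[, -1L, drop = FALSE]
  ok <- !is.na(left) & !is.na(right)
  if (!any(ok))
    stop("unscoreable image: zero valid horizontal pairs")
  i <- left[ok]; j <- right[ok]
  cnt <- matrix(tabulate((j - 1L) * nLevels + i, nbins = nLevels * nLevels),
                nLevels, nLevels)
  new("CooccurrenceMatrix", counts = cnt, nPairs = as.integer(sum(ok)))
}

#' Homogeneity score of a co-occurrence matrix
#'
#' The texture homogeneity statistic
#' \deqn{H = \sum_{i,j} \frac{p(i,j)}{1 + |i - j|}, \quad p = counts / n_{pairs},}
#' which measures how much of the co-occurrence mass sits on or near the
#' diagonal: 1 means every adjacent pixel pair shares the same gray level;
#' values near 0 mean adjacent pixels almost always differ maximally.
#'
#' @param mat a [CooccurrenceMatrix-class].
#' @return numeric score in (0, 1].
#' @export
glcmHomogeneity <- function(mat) {
  cnt <- counts(mat)
  if (nPairs(mat) < 1L) stop("need at least one valid pair")
  n <- nrow(cnt)
  w <- 1 / (1 + abs(outer(seq_len(n), seq_len(n), "-")))
  sum(cnt * w) / nPairs(mat)
}

#' Homogeneity score of a stack
#'
#' The full texture path: project the stack along z (sum projection by
#' default), Otsu-threshold the projection, min-max rescale the foreground,
#' quantize to 8 gray levels, accumulate the horizontal co-occurrence
#' matrix over valid pixel pairs, and score it with [glcmHomogeneity()].
#' A constant foreground (degenerate rescale) is assigned the limiting
#' score of exactly 1.
#'
#' @param stack a [VoxelStack-class] (a [ProjectionImage-class] is also
#'   accepted and used as-is).
#' @param mode projection mode, \code{"sum"} (default) or \code{"max"}.
#' @param nLevels number of gray levels (default 8).
#' @return list with \code{score}, \code{nPairs}, \code{threshold},
#'   \code{matrix} (the [CooccurrenceMatrix-class]).
#' @examples
#' g <- generateLLPS(dropletVolume = 1500, seed = 1)
#' homogeneityScore(g$stack)$score
#' @export
homogeneityScore <- function(stack, mode = c("sum", "max"), nLevels = 8L) {
  mode <- match.arg(mode)
  proj <- if (is(stack, "ProjectionImage")) stack else project(stack, mode)
  flt <- filterProjection(proj)
  img <- intensities(proj)
  fg <- img[flt$mask]
  if (min(fg) == max(fg)) {
    # constant foreground: all co-occurrence mass on the diagonal
    npair <- sum(flt$mask[, -ncol(img), drop = FALSE] &
                 flt$mask[, -1L, drop = FALSE])
    return(list(score = 1, nPairs = as.integer(npair),
                threshold = flt$threshold, matrix = NULL))
  }
  scaled <- rescaleForeground(img, flt$mask)
  q <- quantizeLevels(scaled, nLevels)
  mat <- cooccurrence(q, nLevels)
  list(score = glcmHomogeneity(mat), nPairs = nPairs(mat),
       threshold = flt$threshold, matrix = mat)
}
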