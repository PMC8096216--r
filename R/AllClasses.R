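#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' VoxelStack: a 3D fluorescence intensity stack
#'
#' The elementary container of the package: a non-negative 3D intensity
#' array indexed \code{(z, y, x)} together with its voxel geometry and
#' channel label. Timelapse series (e.g. FRAP acquisitions) reuse the same
#' container with the first axis reinterpreted as time and
#' \code{timelapse = TRUE}; \code{frameTime} then gives seconds per frame.
#'
#' @slot intensities numeric 3D array, dimensions \code{(z, y, x)}; all
#'   values finite and >= 0. Integer camera data are promoted to double on
#'   ingest; all downstream arithmetic is floating point.
#' @slot voxelSize numeric length-3 \code{(dz, dy, dx)} in micrometres, all
#'   > 0. For timelapse stacks \code{dz} is ignored.
#' @slot channel free-text channel label.
#' @slot frameTime seconds per frame for timelapse stacks, or \code{NULL}.
#' @slot timelapse logical; \code{TRUE} when the first axis is time.
#'
#' @seealso [VoxelStack()], [readStack()], [project()], [filterStack()]
#' @export
setClass("VoxelStack",
  representation(
    intensities = "array",
    voxelSize   = "numeric",
    channel     = "character",
    frameTime   = "numericOrNULL",
    timelapse   = "logical"
  ),
  prototype(
    voxelSize = c(0.3, 0.0636, 0.0636),
    channel = "unknown",
    frameTime = NULL,
    timelapse = FALSE
  )
)

setValidity("VoxelStack", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L)
    msg <- c(msg, "intensities must be a 3D array indexed (z, y, x)")
  if (!all(is.finite(object@intensities)))
    msg <- c(msg, "all intensities must be finite")
  else if (any(object@intensities < 0))
    msg <- c(msg, "all intensities must be >= 0")
  if (length(object@voxelSize) != 3L || !all(is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive values (dz, dy, dx)")
  if (length(object@channel) != 1L)
    msg <- c(msg, "channel must be a single label")
  if (!is.null(object@frameTime) &&
      (length(object@frameTime) != 1L || !is.finite(object@frameTime) ||
       object@frameTime <= 0))
    msg <- c(msg, "frameTime must be a single positive number or NULL")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelStack
#'
#' @param intensities 3D numeric array \code{(z, y, x)}, or a 2D matrix
#'   which is treated as a single-plane stack.
#' @param voxelSize numeric \code{(dz, dy, dx)} in micrometres.
#' @param channel channel label.
#' @param frameTime optional seconds per frame (timelapse stacks).
#' @param timelapse logical, first axis is time rather than z.
#' @return A [VoxelStack-class] object.
#' @examples
#' vs <- VoxelStack(array(runif(4 * 5 * 5), c(4, 5, 5)))
#' dim(intensities(vs))
#' @export
VoxelStack <- function(intensities, voxelSize = c(0.3, 0.0636, 0.0636),
                       channel = "unknown", frameTime = NULL,
                       timelapse = !is.null(frameTime)) {
  if (is.matrix(intensities))
    intensities <- array(intensities, c(1L, nrow(intensities), ncol(intensities)))
  storage.mode(intensities) <- "double"
  new("VoxelStack", intensities = intensities,
      voxelSize = as.numeric(voxelSize), channel = as.character(channel),
      frameTime = if (is.null(frameTime)) NULL else as.numeric(frameTime),
      timelapse = isTRUE(timelapse))
}

#' ProjectionImage: a z-collapsed view of a stack
#'
#' @slot intensities 2D numeric matrix (y, x).
#' @slot mode \code{"sum"} or \code{"max"}.
#' @slot sourceDepth number of z-planes collapsed.
#' @seealso [project()]
#' @export
setClass("ProjectionImage",
  representation(intensities = "matrix", mode = "character",
                 sourceDepth = "integer"))

setValidity("ProjectionImage", function(object) {
  msg <- character()
  if (!object@mode %in% c("sum", "max"))
    msg <- c(msg, "mode must be 'sum' or 'max'")
  if (object@sourceDepth < 1L)
    msg <- c(msg, "sourceDepth must be >= 1")
  if (!all(is.finite(object@intensities)))
    msg <- c(msg, "projection intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' FilteredStack: a stack with a background threshold applied
#'
#' Couples a [VoxelStack-class] with the Otsu background threshold computed
#' for it and the resulting foreground mask. A voxel is foreground
#' (\code{valid}) iff its intensity is strictly greater than the threshold;
#' ties at the threshold are background, mirroring the convention of setting
#' sub-threshold voxels to NaN before downstream statistics. Original
#' intensities are retained untouched.
#'
#' @slot source the thresholded [VoxelStack-class].
#' @slot threshold numeric background intensity threshold.
#' @slot validMask logical array, same dimensions as the source intensities.
#' @seealso [filterStack()], [signalVolume()], [heterogeneitySD()]
#' @export
setClass("FilteredStack",
  representation(source = "VoxelStack", threshold = "numeric",
                 validMask = "array"))

setValidity("FilteredStack", function(object) {
  msg <- character()
  if (!identical(dim(object@validMask), dim(object@source@intensities)))
    msg <- c(msg, "validMask must match source dimensions")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite value")
  if (any(object@source@intensities[object@validMask] <= object@threshold))
    msg <- c(msg, "every valid voxel must exceed the threshold strictly")
  if (length(msg)) msg else TRUE
})

#' CooccurrenceMatrix: gray-level adjacency counts
#'
#' Counts of horizontally adjacent quantized gray-level pairs
#' \code{(i, j)}, accumulated over offset \code{(0, +1)} only and not
#' symmetrized; pairs touching an invalid (background) pixel are skipped.
#'
#' @slot counts \code{nLevels x nLevels} non-negative count matrix.
#' @slot nPairs total number of valid pairs (equals \code{sum(counts)}).
#' @seealso [cooccurrence()], [glcmHomogeneity()]
#' @export
setClass("CooccurrenceMatrix",
  representation(counts = "matrix", nPairs = "integer"))

setValidity("CooccurrenceMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) != ncol(object@counts))
    msg <- c(msg, "counts must be square")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != object@nPairs)
    msg <- c(msg, "nPairs must equal sum(counts)")
  if (length(msg)) msg else TRUE
})

#' FrapExperiment: one photobleaching acquisition
#'
#' A pre-bleach reference image, an image of the bleaching laser spot, and
#' the post-bleach recovery timelapse, all sharing (y, x) shape.
#'
#' @slot prebleach single-plane [VoxelStack-class] taken before bleaching.
#' @slot laser single-plane [VoxelStack-class] showing the bleach spot.
#' @slot timelapse [VoxelStack-class] with time on the first axis and
#'   \code{frameTime} set.
#' @seealso [frapAnalyze()], [generateFRAP()]
#' @export
setClass("FrapExperiment",
  representation(prebleach = "VoxelStack", laser = "VoxelStack",
                 timelapse = "VoxelStack"))

setValidity("FrapExperiment", function(object) {
  msg <- character()
  yx <- function(v) dim(v@intensities)[2:3]
  if (!identical(yx(object@prebleach), yx(object@laser)) ||
      !identical(yx(object@prebleach), yx(object@timelapse)))
    msg <- c(msg, "prebleach, laser and timelapse must share (y, x) shape")
  if (dim(object@timelapse@intensities)[1] < 2L)
    msg <- c(msg, "timelapse needs at least 2 frames")
  if (!isTRUE(object@timelapse@timelapse))
    msg <- c(msg, "timelapse stack must have timelapse = TRUE")
  if (length(msg)) msg else TRUE
})

#' FrapExperiment constructor
#'
#' @param prebleach,laser single-plane [VoxelStack-class] objects.
#' @param timelapse timelapse [VoxelStack-class] (first axis = time,
#'   \code{frameTime} set).
#' @return A [FrapExperiment-class].
#' @export
FrapExperiment <- function(prebleach, laser, timelapse) {
  new("FrapExperiment", prebleach = prebleach, laser = laser,
      timelapse = timelapse)
}

#' RecoveryCurve: normalized, photobleach-corrected FRAP recovery
#'
#' @slot recoveryRegion logical (y, x) mask of the monitored bleached region.
#' @slot prebleachMean mean pre-bleach intensity over the recovery region.
#' @slot rawMeans per-frame mean intensity in the region (uncorrected).
#' @slot bleachRate least-squares slope (intensity per frame) of the
#'   reference trace used for photobleach correction.
#' @slot rateAdjusted logical; TRUE when the correction magnitude had to be
#'   increased to obtain a positive percent recovery.
#' @slot adjustIterations number of 10 percent step-ups applied.
#' @slot correctionMode \code{"ratio"}, \code{"additive"} or \code{"none"}.
#' @slot normalized per-frame corrected mean / prebleach mean.
#' @slot percentRecovery normalized(final) - normalized(first post-bleach).
#' @slot unrecoveredFraction 1 - normalized(final); the literal pre-bleach
#'   minus final-frame difference, reported alongside.
#' @slot frameTime seconds per frame.
#' @seealso [normalizeWithCorrection()], [percentRecovery()]
#' @export
setClass("RecoveryCurve",
  representation(
    recoveryRegion = "matrix", prebleachMean = "numeric",
    rawMeans = "numeric", bleachRate = "numeric",
    rateAdjusted = "logical", adjustIterations = "integer",
    correctionMode = "character", normalized = "numeric",
    percentRecovery = "numeric", unrecoveredFraction = "numeric",
    frameTime = "numeric"))

setValidity("RecoveryCurve", function(object) {
  msg <- character()
  if (!any(object@recoveryRegion))
    msg <- c(msg, "recovery region must be non-empty")
  if (!all(is.finite(object@normalized)))
    msg <- c(msg, "normalized values must be finite")
  if (length(object@rawMeans) != length(object@normalized))
    msg <- c(msg, "rawMeans and normalized must have equal length")
  if (length(msg)) msg else TRUE
})
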