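#' Extract the intensity array
#' @param x a VoxelStack, ProjectionImage or FilteredStack.
#' @return numeric array (3D) or matrix (2D projection).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Voxel dimensions in micrometres
#' @param x a VoxelStack or FilteredStack.
#' @return numeric (dz, dy, dx).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Channel label
#' @param x a VoxelStack or FilteredStack.
#' @return character label.
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' Background threshold of a filtered object
#' @param x a FilteredStack.
#' @return numeric threshold; foreground voxels are strictly above it.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' Foreground mask
#' @param x a FilteredStack.
#' @return logical array, TRUE where intensity > threshold.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Number of foreground voxels
#' @param x a FilteredStack.
#' @return integer count of TRUE entries in the mask.
#' @export
setGeneric("foregroundVolume", function(x) standardGeneric("foregroundVolume"))

#' Co-occurrence counts
#' @param x a CooccurrenceMatrix.
#' @return integer count matrix.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Number of valid adjacent pairs
#' @param x a CooccurrenceMatrix.
#' @return integer pair count.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Normalized recovery values of a FRAP curve
#' @param x a RecoveryCurve.
#' @return numeric per-frame corrected mean / pre-bleach mean.
#' @export
setGeneric("normalizedCurve", function(x) standardGeneric("normalizedCurve"))

#' Percent recovery of a FRAP curve
#'
#' Conventional definition: normalized intensity of the final frame minus
#' the normalized intensity of the first post-bleach frame. The complement
#' (1 - final normalized value) is available as [unrecoveredFraction()].
#' @param x a RecoveryCurve.
#' @return numeric in [0, 1] after rate adjustment.
#' @export
setGeneric("percentRecovery", function(x) standardGeneric("percentRecovery"))

#' Unrecovered fraction of a FRAP curve
#' @param x a RecoveryCurve.
#' @return numeric 1 - normalized(final frame).
#' @export
setGeneric("unrecoveredFraction",
           function(x) standardGeneric("unrecoveredFraction"))

#' @describeIn intensities 3D array of a VoxelStack
#' @export
setMethod("intensities", "VoxelStack", function(x) x@intensities)
#' @describeIn intensities matrix of a ProjectionImage
#' @export
setMethod("intensities", "ProjectionImage", function(x) x@intensities)
#' @describeIn intensities 3D array of a FilteredStack's source
#' @export
setMethod("intensities", "FilteredStack", function(x) x@source@intensities)

#' @describeIn voxelSize of a VoxelStack
#' @export
setMethod("voxelSize", "VoxelStack", function(x) x@voxelSize)
#' @describeIn voxelSize of a FilteredStack's source
#' @export
setMethod("voxelSize", "FilteredStack", function(x) x@source@voxelSize)

#' @describeIn channelLabel of a VoxelStack
#' @export
setMethod("channelLabel", "VoxelStack", function(x) x@channel)
#' @describeIn channelLabel of a FilteredStack's source
#' @export
setMethod("channelLabel", "FilteredStack", function(x) x@source@channel)

#' @describeIn threshold of a FilteredStack
#' @export
setMethod("threshold", "FilteredStack", function(x) x@threshold)
#' @describeIn validMask of a FilteredStack
#' @export
setMethod("validMask", "FilteredStack", function(x) x@validMask)
#' @describeIn foregroundVolume of a FilteredStack
#' @export
setMethod("foregroundVolume", "FilteredStack",
          function(x) sum(x@validMask))

#' @describeIn counts of a CooccurrenceMatrix
#' @export
setMethod("counts", "CooccurrenceMatrix", function(x) x@counts)
#' @describeIn nPairs of a CooccurrenceMatrix
#' @export
setMethod("nPairs", "CooccurrenceMatrix", function(x) x@nPairs)

#' @describeIn normalizedCurve of a RecoveryCurve
#' @export
setMethod("normalizedCurve", "RecoveryCurve", function(x) x@normalized)
#' @describeIn percentRecovery of a RecoveryCurve
#' @export
setMethod("percentRecovery", "RecoveryCurve", function(x) x@percentRecovery)
#' @describeIn unrecoveredFraction of a RecoveryCurve
#' @export
setMethod("unrecoveredFraction", "RecoveryCurve",
          function(x) x@unrecoveredFraction)

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@intensities)
  axis1 <- if (object@timelapse) "t" else "z"
  cat(sprintf("VoxelStack [%s=%d, y=%d, x=%d] channel='%s'\n",
              axis1, d[1], d[2], d[3], object@channel))
  cat(sprintf("  voxel size (dz,dy,dx) = (%.4g, %.4g, %.4g) um\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  if (!is.null(object@frameTime))
    cat(sprintf("  frame time = %.4g s\n", object@frameTime))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "ProjectionImage", function(object) {
  cat(sprintf("ProjectionImage [%d x %d], mode='%s', %d plane(s) collapsed\n",
              nrow(object@intensities), ncol(object@intensities),
              object@mode, object@sourceDepth))
})

setMethod("show", "FilteredStack", function(object) {
  d <- dim(object@validMask)
  cat(sprintf(
    "FilteredStack [z=%d, y=%d, x=%d] threshold=%.6g, foreground=%d voxel(s)\n",
    d[1], d[2], d[3], object@threshold, sum(object@validMask)))
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix %dx%d, %d valid pair(s)\n",
              nrow(object@counts), ncol(object@counts), object@nPairs))
})

setMethod("show", "RecoveryCurve", function(object) {
  cat(sprintf(
    "RecoveryCurve: %d frame(s), percent recovery %.4f (unrecovered %.4f)\n",
    length(object@normalized), object@percentRecovery,
    object@unrecoveredFraction))
  cat(sprintf("  bleach rate %.6g intensity/frame, correction '%s'%s\n",
              object@bleachRate, object@correctionMode,
              if (object@rateAdjusted)
                sprintf(", adjusted %d time(s)", object@adjustIterations)
              else ""))
})

setMethod("show", "FrapExperiment", function(object) {
  d <- dim(object@timelapse@intensities)
  cat(sprintf("FrapExperiment: %d frames of %d x %d, frame time %.3g s\n",
              d[1], d[2], d[3],
              if (is.null(object@timelapse@frameTime)) NA_real_
              else object@timelapse@frameTime))
})
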