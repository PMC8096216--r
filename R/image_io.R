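#' Read a multi-page grayscale TIFF as a VoxelStack
#'
#' Pages map to the first (z or time) axis in acquisition order. Integer
#' sample formats (8/16-bit) are returned bit-exact as doubles; pixel
#' values are never rescaled.
#'
#' If a YAML sidecar file \code{<path>.yml} (or \code{.yaml}) exists, its
#' \code{voxel_size} (dz, dy, dx in micrometres), \code{channel} and
#' \code{frame_time} entries supply defaults for the corresponding
#' arguments; explicit arguments win.
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param channel channel label attached to the stack.
#' @param voxelSize numeric (dz, dy, dx) in micrometres.
#' @param frameTime optional seconds per frame; setting it marks the stack
#'   as a timelapse (first axis = time).
#' @return A [VoxelStack-class].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeStack(VoxelStack(array(1:24, c(2, 3, 4))), f)
#' readStack(f)
#' @export
readStack <- function(path, channel = "unknown", voxelSize = NULL,
                      frameTime = NULL) {
  if (!file.exists(path))
    stop("cannot read TIFF: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L)
        stop("multi-sample (colour) TIFF not supported: ", path)
      p <- p[, , 1L]
    }
    p
  })
  dims <- vapply(pages, dim, integer(2))
  if (length(pages) > 1L && any(dims != dims[, 1L]))
    stop("ragged TIFF: pages of '", path, "' differ in size")
  a <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]]

  side <- .readSidecar(path)
  if (is.null(voxelSize))
    voxelSize <- if (!is.null(side$voxel_size)) as.numeric(side$voxel_size)
                 else c(0.3, 0.0636, 0.0636)
  if (identical(channel, "unknown") && !is.null(side$channel))
    channel <- as.character(side$channel)
  if (is.null(frameTime) && !is.null(side$frame_time))
    frameTime <- as.numeric(side$frame_time)
  VoxelStack(a, voxelSize = voxelSize, channel = channel,
             frameTime = frameTime)
}

.readSidecar <- function(path) {
  for (ext in c(".yml", ".yaml")) {
    sc <- paste0(path, ext)
    if (file.exists(sc))
      return(yaml::read_yaml(sc))
  }
  NULL
}

#' Write a VoxelStack to a multi-page grayscale TIFF
#'
#' Non-negative integer data up to 65535 are written losslessly (8- or
#' 16-bit per sample as needed); floating or larger-valued data are
#' quantized to 16 bits over \code{[0, max]}, the usual dynamic range of
#' camera acquisitions.
#'
#' @param stack a [VoxelStack-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  a <- intensities(stack)
  nz <- dim(a)[1]
  mx <- max(a)
  integerish <- all(a == round(a))
  if (integerish && mx <= 255) {
    bits <- 8L; scale <- 255
  } else if (integerish && mx <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    bits <- 16L
    a <- if (mx > 0) round(a / mx * 65535) else a
    scale <- 65535
  }
  pages <- lapply(seq_len(nz), function(z) a[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Export a foreground mask as an inspection TIFF
#'
#' Writes the valid mask of a [FilteredStack-class] as an 8-bit TIFF with
#' foreground voxels at 255 and background at 0.
#'
#' @param f a [FilteredStack-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(f, path) {
  m <- validMask(f)
  writeStack(VoxelStack(array(255 * m, dim(m)), voxelSize = voxelSize(f)),
             path)
}

#' Collapse a stack along z
#'
#' Sum-intensity projections feed the texture homogeneity analysis; the
#' max projection is retained as an alternative mode and for the
#' max-projection area metric.
#'
#' @param stack a [VoxelStack-class].
#' @param mode \code{"sum"} or \code{"max"}.
#' @return A [ProjectionImage-class].
#' @examples
#' p <- project(VoxelStack(array(1, c(2, 2, 2))), "sum")
#' intensities(p)
#' @export
project <- function(stack, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  a <- intensities(stack)
  img <- apply(a, c(2, 3), if (mode == "sum") sum else max)
  new("ProjectionImage", intensities = img, mode = mode,
      sourceDepth = dim(a)[1])
}

#' Center-crop a stack in the (y, x) plane
#'
#' Utility for reducing a larger field of view to the square crop
#' convention used throughout the pipeline (55 x 55 pixels by default,
#' i.e. 3.5 x 3.5 um at 0.0636 um/pixel). Cropping around a specific
#' signal remains an upstream, interactive step.
#'
#' @param stack a [VoxelStack-class].
#' @param size integer (height, width) of the crop; a single value is
#'   recycled. Default \code{c(55, 55)}.
#' @return A cropped [VoxelStack-class] (all z-planes retained).
#' @export
centerCrop <- function(stack, size = c(55L, 55L)) {
  size <- rep(as.integer(size), length.out = 2L)
  a <- intensities(stack)
  d <- dim(a)
  if (any(size > d[2:3]))
    stop("crop size exceeds image extent")
  y0 <- (d[2] - size[1]) %/% 2L
  x0 <- (d[3] - size[2]) %/% 2L
  VoxelStack(a[, y0 + seq_len(size[1]), x0 + seq_len(size[2]), drop = FALSE],
             voxelSize = voxelSize(stack), channel = channelLabel(stack),
             frameTime = stack@frameTime, timelapse = stack@timelapse)
}
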