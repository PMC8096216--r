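## Ground-truthed synthetic image generation.
##
## The generators embody the two condensate regimes the analysis is meant
## to distinguish: a compressible polymer condensate conserves material, so
## compaction (more crosslinks) shrinks its volume and raises its
## concentration; a liquid droplet keeps a fixed concentration, so adding
## material grows its volume. Geometry is defined in physical micrometres
## so anisotropic voxel grids are handled naturally.

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable in-plane Gaussian blur (zero padding). z blur is deliberately
# omitted: the emulated stacks are deconvolved and coarsely sampled in z.
.blurXY <- function(a, sigma) {
  if (sigma <= 0) return(a)
  kern1 <- function(n) {
    r <- ceiling(3 * sigma)
    g <- exp(-((-r):r)^2 / (2 * sigma^2))
    g <- g / sum(g)
    K <- matrix(0, n, n)
    for (off in (-r):r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + g[off + r + 1]
    }
    K
  }
  d <- dim(a)
  Ky <- kern1(d[2]); Kx <- kern1(d[3])
  out <- a
  for (z in seq_len(d[1])) out[z, , ] <- Ky %*% a[z, , ] %*% t(Kx)
  out
}

.addNoise <- function(img, noise, sd) {
  switch(noise,
    none = img,
    gaussian = pmax(img + stats::rnorm(length(img), 0, sd), 0),
    poisson = array(stats::rpois(length(img), pmax(img, 0)), dim(img)),
    stop("unknown noise model: ", noise))
}

.physGrid <- function(shape, voxelSize, center) {
  # squared physical distance of every voxel to `center` (voxel coords)
  z <- (seq_len(shape[1]) - center[1]) * voxelSize[1]
  y <- (seq_len(shape[2]) - center[2]) * voxelSize[2]
  x <- (seq_len(shape[3]) - center[3]) * voxelSize[3]
  outer(outer(z^2, y^2, "+"), x^2, "+")
}

#' Generate a liquid-droplet (LLPS-regime) stack
#'
#' A sphere of uniform intensity (\code{concentration}) and prescribed
#' voxel volume is placed at a random interior position, blurred in-plane,
#' and overlaid with background and noise. Because concentration is fixed,
#' populations that vary \code{dropletVolume} show no volume-intensity
#' correlation — the liquid signature. The sphere is defined in physical
#' micrometres, so on the default anisotropic grid it appears as an oblate
#' voxel ellipsoid, as real droplets do in z-stacks.
#'
#' @param concentration uniform droplet intensity (default 80).
#' @param dropletVolume target droplet volume in voxels (default 2000).
#' @param shape stack dimensions (z, y, x); default \code{c(19, 55, 55)} —
#'   the 55 x 55 in-plane crop convention with enough 0.3 um z-planes to
#'   hold droplets up to ~4000 voxels with a 2-voxel margin.
#' @param voxelSize (dz, dy, dx) in micrometres.
#' @param psfSigma in-plane Gaussian blur sigma in voxels (default 0.5).
#' @param background additive background level (default 10).
#' @param noise \code{"gaussian"}, \code{"poisson"} or \code{"none"}.
#' @param noiseSd Gaussian noise SD as a fraction of the foreground
#'   intensity (default 0.05).
#' @param margin minimum clearance, in voxels, between droplet and stack
#'   border (default 2).
#' @param seed integer seed; identical (parameters, seed) give bit-identical
#'   output.
#' @return list with \code{stack} ([VoxelStack-class]) and \code{truth}
#'   (named list of all parameters plus realized foreground volume and
#'   integrated intensity).
#' @export
generateLLPS <- function(concentration = 80, dropletVolume = 2000,
                         shape = c(19L, 55L, 55L),
                         voxelSize = c(0.3, 0.0636, 0.0636),
                         psfSigma = 0.5, background = 10,
                         noise = c("gaussian", "poisson", "none"),
                         noiseSd = 0.05, margin = 2, seed = NULL) {
  noise <- match.arg(noise)
  .withSeed(seed, {
    rPhys <- (3 * dropletVolume * prod(voxelSize) / (4 * pi))^(1 / 3)
    semi <- rPhys / voxelSize            # voxel semi-axes (z, y, x)
    lo <- semi + margin + 1
    hi <- shape - semi - margin
    if (any(hi < lo))
      stop("geometry error: droplet of ", dropletVolume,
           " voxels does not fit the stack with a ", margin, "-voxel margin")
    center <- lo + stats::runif(3) * (hi - lo)
    member <- .physGrid(shape, voxelSize, center) <= rPhys^2
    # droplet voxels take the concentration value itself; background fills
    # the rest (blurring the difference keeps the plateau exact)
    signal <- (concentration - background) * member
    signal <- .blurXY(array(signal, shape), psfSigma)
    img <- .addNoise(background + signal, noise, noiseSd * concentration)
    list(
      stack = VoxelStack(img, voxelSize = voxelSize, channel = "synthetic-llps"),
      truth = list(regime = "LLPS", concentration = concentration,
                   droplet_volume = dropletVolume,
                   realized_volume = sum(member),
                   realized_integrated_intensity = concentration * sum(member),
                   r_phys_um = rPhys, center = unname(center),
                   psf_sigma = psfSigma, background = background,
                   noise = noise, noise_sd = noiseSd, seed = seed))
  })
}

#' Generate a polymer-condensate (PPPS-regime) stack
#'
#' \code{nPuncta} Gaussian blobs are placed uniformly inside a nucleolar
#' bounding sphere whose radius, together with the blob spread, shrinks as
#' \code{crosslinkDensity} rises — emulating crosslink-driven compaction.
#' After in-plane blurring the field is rescaled so its integrated
#' intensity equals \code{totalIntensity} exactly: material is conserved,
#' so measured volume falls and mean intensity rises with density — the
#' compressible-polymer signature.
#'
#' @param totalIntensity conserved integrated signal intensity
#'   (default 2e5).
#' @param nPuncta number of blobs (default 6).
#' @param crosslinkDensity compaction parameter in [0, 1].
#' @param clusterRadius nucleolar bounding radius in micrometres at density
#'   0 (default 0.9); shrinks by the factor \code{1 - 0.75 * density}.
#' @param blobSigma blob Gaussian sigma in micrometres at density 0
#'   (default 0.28); shrinks by the factor \code{1 - 0.6 * density}.
#' @inheritParams generateLLPS
#' @return list with \code{stack} and \code{truth} (includes the realized
#'   foreground volume, defined as voxels above 1 percent of the peak
#'   noiseless signal).
#' @export
generatePPPS <- function(totalIntensity = 2e5, nPuncta = 6L,
                         crosslinkDensity = 0.5,
                         clusterRadius = 0.9, blobSigma = 0.28,
                         shape = c(19L, 55L, 55L),
                         voxelSize = c(0.3, 0.0636, 0.0636),
                         psfSigma = 0.5, background = 10,
                         noise = c("gaussian", "poisson", "none"),
                         noiseSd = 0.05, seed = NULL) {
  noise <- match.arg(noise)
  if (nPuncta < 1L) stop("need at least one punctum")
  if (crosslinkDensity < 0 || crosslinkDensity > 1)
    stop("crosslinkDensity must lie in [0, 1]")
  .withSeed(seed, {
    rc <- clusterRadius * (1 - 0.75 * crosslinkDensity)
    sb <- blobSigma * (1 - 0.6 * crosslinkDensity)
    centerStack <- (shape + 1) / 2
    # uniform placement inside the bounding sphere (physical um)
    u <- matrix(stats::rnorm(3 * nPuncta), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- rc * stats::runif(nPuncta)^(1 / 3)
    centersPhys <- u * rad
    field <- array(0, shape)
    for (p in seq_len(nPuncta)) {
      cVox <- centerStack + centersPhys[p, ] / voxelSize
      d2 <- .physGrid(shape, voxelSize, cVox)
      field <- field + exp(-d2 / (2 * sb^2))
    }
    field <- .blurXY(field, psfSigma)
    field <- field * (totalIntensity / sum(field))
    fgMask <- field > 0.01 * max(field)
    refIntensity <- mean(field[fgMask])
    img <- .addNoise(background + field, noise, noiseSd * refIntensity)
    list(
      stack = VoxelStack(img, voxelSize = voxelSize, channel = "synthetic-ppps"),
      truth = list(regime = "PPPS", total_intensity = totalIntensity,
                   n_puncta = nPuncta, crosslink_density = crosslinkDensity,
                   cluster_radius_um = rc, blob_sigma_um = sb,
                   realized_volume = sum(fgMask),
                   realized_integrated_intensity = sum(field),
                   psf_sigma = psfSigma, background = background,
                   noise = noise, noise_sd = noiseSd, seed = seed))
  })
}

#' Generate a two-channel intermixed or shell configuration
#'
#' Channel B is a uniform ball of the given radius; channel A either fills
#' the same ball uniformly (\code{"intermixed"}) or forms a spherical shell
#' hugging B's surface (\code{"shell"}). Both share a center at the stack
#' center and are blurred and degraded independently. Geometry is defined
#' in voxel units on an isotropic grid so the analytic dispersion fixed
#' points (uniform ball: rpv = R/20; thin shell: rpv near 0) apply
#' directly.
#'
#' @param geometry \code{"intermixed"} or \code{"shell"}.
#' @param radius ball radius R in voxels (>= 4; default 10).
#' @param shellThickness shell thickness in voxels (default 1.5; must be
#'   < radius).
#' @param intensityA,intensityB channel intensities (default 100).
#' @param shape stack dimensions; default \code{c(25, 55, 55)}.
#' @param voxelSize isotropic by default (\code{c(0.1, 0.1, 0.1)} um).
#' @param psfSigma in-plane blur sigma in voxels (default 1).
#' @inheritParams generateLLPS
#' @return list with \code{channelA}, \code{channelB} ([VoxelStack-class])
#'   and \code{truth}.
#' @export
generateTwoChannel <- function(geometry = c("intermixed", "shell"),
                               radius = 10, shellThickness = 1.5,
                               intensityA = 100, intensityB = 100,
                               shape = c(25L, 55L, 55L),
                               voxelSize = c(0.1, 0.1, 0.1),
                               psfSigma = 1, background = 5,
                               noise = c("gaussian", "poisson", "none"),
                               noiseSd = 0.05, seed = NULL) {
  geometry <- match.arg(geometry)
  noise <- match.arg(noise)
  if (radius < 4) stop("geometry error: radius must be >= 4 voxels")
  if (geometry == "shell" && shellThickness >= radius)
    stop("geometry error: shell thickness must be smaller than the radius")
  if (any(radius + 2 > (shape - 1) / 2))
    stop("geometry error: ball does not fit the stack with a 2-voxel margin")
  .withSeed(seed, {
    center <- (shape + 1) / 2
    d2 <- .physGrid(shape, c(1, 1, 1), center)   # voxel-unit distances
    d <- sqrt(d2)
    ball <- d <= radius
    maskA <- if (geometry == "intermixed") ball
             else (d > radius - shellThickness) & ball
    sigA <- .blurXY(array(intensityA * maskA, shape), psfSigma)
    sigB <- .blurXY(array(intensityB * ball, shape), psfSigma)
    imgA <- .addNoise(background + sigA, noise, noiseSd * intensityA)
    imgB <- .addNoise(background + sigB, noise, noiseSd * intensityB)
    list(
      channelA = VoxelStack(imgA, voxelSize = voxelSize,
                            channel = "synthetic-A"),
      channelB = VoxelStack(imgB, voxelSize = voxelSize,
                            channel = "synthetic-B"),
      truth = list(geometry = geometry, radius = radius,
                   shell_thickness = shellThickness,
                   center = unname(center),
                   volume_A = sum(maskA), volume_B = sum(ball),
                   intensity_A = intensityA, intensity_B = intensityB,
                   psf_sigma = psfSigma, background = background,
                   noise = noise, noise_sd = noiseSd, seed = seed))
  })
}

#' Generate a FRAP experiment with known kinetics
#'
#' Renders a pre-bleach image (a bright disk-shaped signal), a laser image
#' (the bleach spot inside the signal) and a post-bleach timelapse in which
#' the spot recovers as
#' \deqn{I(t) = [I_{post} + m (I_{pre} - I_{post})(1 - e^{-kt})] e^{-\beta t}}
#' while the rest of the signal bleaches as \eqn{I_{pre} e^{-\beta t}}.
#' With complete bleaching (\code{postBleachDepth = 1}, the default) the
#' asymptotic normalized recovery is exactly \eqn{m (1 - e^{-kT})}; with
#' partial bleaching it scales by \eqn{1 - I_{post}/I_{pre}}.
#'
#' @param m mobile fraction in [0, 1].
#' @param k recovery rate constant, 1/s (default 0.3).
#' @param beta photobleaching rate, 1/s (default 0).
#' @param postBleachDepth fraction of pre-bleach intensity removed by the
#'   bleach (default 1 = complete).
#' @param nFrames timelapse frames (default 50).
#' @param duration timelapse length in seconds (default 30; frame times are
#'   \code{(0:(nFrames-1)) * duration / nFrames}).
#' @param shape image (y, x) size (default \code{c(55, 55)}).
#' @param signalRadius radius of the signal disk in pixels (default 14).
#' @param spotRadius radius of the bleach spot (default 5).
#' @param spotOffset (y, x) offset of the spot center from the signal
#'   center (default \code{c(0, 4)}; the spot must stay inside the signal).
#' @param iPre pre-bleach signal intensity (default 100).
#' @param background image background level (default 10).
#' @param noiseSd Gaussian noise SD as a fraction of \code{iPre}
#'   (default 0.02).
#' @param seed integer seed.
#' @return list with \code{experiment} ([FrapExperiment-class]) and
#'   \code{truth} (parameters plus \code{expected_percent_recovery}
#'   evaluated at the final frame time).
#' @export
generateFRAP <- function(m = 0.5, k = 0.3, beta = 0, postBleachDepth = 1,
                         nFrames = 50L, duration = 30,
                         shape = c(55L, 55L), signalRadius = 14,
                         spotRadius = 5, spotOffset = c(0, 4),
                         iPre = 100, background = 10, noiseSd = 0.02,
                         seed = NULL) {
  if (m < 0 || m > 1) stop("mobile fraction m must lie in [0, 1]")
  if (k < 0 || beta < 0) stop("rates k and beta must be >= 0")
  .withSeed(seed, {
    cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
    yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
    xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    signalDisk <- (yy - cy)^2 + (xx - cx)^2 <= signalRadius^2
    spotDisk <- (yy - cy - spotOffset[1])^2 +
                (xx - cx - spotOffset[2])^2 <= spotRadius^2
    if (any(spotDisk & !signalDisk))
      stop("geometry error: bleach spot extends beyond the signal")
    sdAbs <- noiseSd * iPre
    noisy <- function(img) pmax(img + stats::rnorm(length(img), 0, sdAbs), 0)
    vs <- function(img, ft = NULL)
      VoxelStack(matrix(img, shape[1], shape[2]),
                 voxelSize = c(0.3, 0.0636, 0.0636),
                 channel = "synthetic-frap", frameTime = ft)

    prebleach <- vs(noisy(background * (!signalDisk) + iPre * signalDisk))
    laser <- vs(noisy(2 * (!spotDisk) + 200 * spotDisk))

    iPost <- (1 - postBleachDepth) * iPre
    dt <- duration / nFrames
    times <- (seq_len(nFrames) - 1) * dt
    frames <- array(0, c(nFrames, shape[1], shape[2]))
    for (i in seq_len(nFrames)) {
      decay <- exp(-beta * times[i])
      spotI <- (iPost + m * (iPre - iPost) * (1 - exp(-k * times[i]))) * decay
      # pixels take their model values; background fills non-signal pixels
      img <- background * (!signalDisk) +
             iPre * decay * (signalDisk & !spotDisk) + spotI * spotDisk
      frames[i, , ] <- noisy(img)
    }
    tl <- VoxelStack(frames, voxelSize = c(0.3, 0.0636, 0.0636),
                     channel = "synthetic-frap", frameTime = dt)
    tFinal <- times[nFrames]
    list(
      experiment = FrapExperiment(prebleach, laser, tl),
      truth = list(m = m, k = k, beta = beta,
                   post_bleach_depth = postBleachDepth,
                   n_frames = nFrames, duration = duration,
                   frame_time = dt, t_final = tFinal,
                   i_pre = iPre, i_post = iPost,
                   expected_percent_recovery =
                     m * (1 - exp(-k * tFinal)) * (1 - iPost / iPre),
                   noise_sd = noiseSd, seed = seed))
  })
}
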