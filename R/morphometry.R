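#' Signal volume in voxels
#'
#' The number of voxels strictly above the background threshold.
#'
#' @param f a [FilteredStack-class].
#' @return integer voxel count (>= 1).
#' @export
signalVolume <- function(f) {
  v <- foregroundVolume(f)
  if (v < 1L) stop("empty signal: no voxel above background")
  v
}

#' Mean intensity above background
#'
#' Foreground intensity sum divided by foreground voxel count, minus the
#' background threshold — the pipeline's proxy for in vivo concentration.
#' Strictly positive by the strict-inequality foreground rule.
#'
#' @param f a [FilteredStack-class].
#' @return numeric intensity.
#' @export
meanIntensityAboveBackground <- function(f) {
  m <- validMask(f)
  if (!any(m)) stop("empty signal: no voxel above background")
  mean(intensities(f)[m]) - threshold(f)
}

#' Compression of a signal
#'
#' Mean intensity above background divided by signal volume
#' (intensity per voxel); higher for tighter, denser signals. A polymer
#' condensate that compacts (gains crosslinks) loses volume and gains
#' concentration, so its compression rises on both counts.
#'
#' @param meanAboveBg numeric mean intensity above background.
#' @param volume integer signal volume in voxels.
#' @return numeric ratio.
#' @examples
#' signalCompression(30, 125)
#' @export
signalCompression <- function(meanAboveBg, volume) {
  if (any(volume < 1)) stop("volume must be >= 1")
  meanAboveBg / volume
}

#' Heterogeneity: SD of the min-max rescaled foreground
#'
#' Foreground intensities are rescaled to [0, 1] (min to 0, max to 1) and
#' their standard deviation is returned. Population SD (divide by N) is the
#' default, which makes the half-min/half-max two-point bound of 0.5 exact;
#' sample SD is available. Constant foregrounds score 0. The statistic is
#' invariant under affine transforms of the intensities.
#'
#' @param f a [FilteredStack-class].
#' @param type \code{"population"} (default) or \code{"sample"}.
#' @return numeric SD in [0, 0.5] (population convention).
#' @export
heterogeneitySD <- function(f, type = c("population", "sample")) {
  type <- match.arg(type)
  v <- intensities(f)[validMask(f)]
  if (length(v) < 1L) stop("empty signal")
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(0)
  r <- (v - lo) / (hi - lo)
  if (type == "population")
    sqrt(mean((r - mean(r))^2))
  else
    stats::sd(r)
}

#' Per-signal morphometric record
#'
#' Computes the full per-cell metric set from one stack: the stack is
#' Otsu-thresholded as a whole for volume, mean intensity above background,
#' compression, heterogeneity, integrated intensity and in-focus area; the
#' max and sum projections are thresholded independently (paralleling the
#' texture path) for their areas.
#'
#' \emph{In-focus area} is the above-threshold pixel count of the single
#' z-plane with the greatest integrated intensity.
#'
#' @param stack a [VoxelStack-class].
#' @param sdType SD convention passed to [heterogeneitySD()].
#' @return one-row \code{data.frame} with columns \code{volume},
#'   \code{mean_above_bg}, \code{compression}, \code{heterogeneity},
#'   \code{integrated_intensity}, \code{in_focus_area},
#'   \code{max_proj_area}, \code{sum_proj_area}, \code{threshold}.
#' @examples
#' g <- generateLLPS(dropletVolume = 1200, seed = 7)
#' signalMetrics(g$stack)
#' @export
signalMetrics <- function(stack, sdType = "population") {
  f <- filterStack(stack)
  a <- intensities(stack)
  m <- validMask(f)
  vol <- signalVolume(f)
  mab <- meanIntensityAboveBackground(f)
  planeSums <- apply(a, 1, sum)
  zFocus <- which.max(planeSums)
  inFocus <- sum(a[zFocus, , ] > threshold(f))
  projArea <- function(mode) {
    p <- project(stack, mode)
    sum(intensities(p) > otsuThreshold(intensities(p)))
  }
  data.frame(
    volume = vol,
    mean_above_bg = mab,
    compression = signalCompression(mab, vol),
    heterogeneity = heterogeneitySD(f, sdType),
    integrated_intensity = sum(a[m]),
    in_focus_area = inFocus,
    max_proj_area = projArea("max"),
    sum_proj_area = projArea("sum"),
    threshold = threshold(f)
  )
}

#' Flag population outliers on the gating measures
#'
#' A record is flagged when any of the six gating measures (volume,
#' in-focus area, max-projection area, sum-projection area, integrated
#' intensity, mean intensity above background) deviates from the population
#' median by more than \code{k} scaled median absolute deviations
#' (scale factor 1.4826). When a measure's MAD is zero, any value different
#' from the median counts as an outlier for that measure.
#'
#' @param records \code{data.frame} of [signalMetrics()] rows.
#' @param k MAD multiplier (default 3).
#' @param measures columns to gate on.
#' @return logical vector, TRUE for records to exclude.
#' @export
flagOutliers <- function(records, k = 3,
                         measures = c("volume", "in_focus_area",
                                      "max_proj_area", "sum_proj_area",
                                      "integrated_intensity",
                                      "mean_above_bg")) {
  if (nrow(records) < 5L)
    stop("insufficient population: need at least 5 records")
  missing <- setdiff(measures, names(records))
  if (length(missing))
    stop("records lack gating measure(s): ", paste(missing, collapse = ", "))
  flag <- rep(FALSE, nrow(records))
  for (m in measures) {
    x <- records[[m]]
    med <- stats::median(x)
    s <- stats::mad(x)        # scaled MAD, constant 1.4826
    flag <- flag | if (s == 0) x != med else abs(x - med) > k * s
  }
  flag
}

#' Volume versus mean-intensity correlation of a population
#'
#' Pearson correlation between signal volume and mean intensity above
#' background across a gated population, with the two-sided p-value from
#' the t-transform of r on n - 2 degrees of freedom. Liquid droplets grow
#' at constant concentration (r near 0); compressible polymer condensates
#' conserve material, so concentration falls as volume grows (strongly
#' negative r). Pearson's r is sensitive to outliers, so records flagged by
#' [flagOutliers()] are removed first (set \code{gate = FALSE} to skip).
#'
#' @param records \code{data.frame} of [signalMetrics()] rows.
#' @param gate apply MAD outlier gating first (default TRUE).
#' @param k MAD multiplier for gating.
#' @return list with \code{n_before}, \code{n_after}, \code{pearson_r},
#'   \code{p_value}, \code{metric_pair}.
#' @export
volumeIntensityCorrelation <- function(records, gate = TRUE, k = 3) {
  nBefore <- nrow(records)
  kept <- if (gate) records[!flagOutliers(records, k = k), , drop = FALSE]
          else records
  if (nrow(kept) < 3L)
    stop("need at least 3 records after gating")
  x <- kept$volume; y <- kept$mean_above_bg
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in a variable")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(n_before = nBefore, n_after = nrow(kept),
       pearson_r = unname(ct$estimate), p_value = ct$p.value,
       metric_pair = c("volume", "mean_above_bg"))
}
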