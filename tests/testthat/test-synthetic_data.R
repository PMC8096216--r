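test_that("generators are bit-identical for identical (model, seed)", {
  a <- generateLLPS(dropletVolume = 1200, seed = 71)
  b <- generateLLPS(dropletVolume = 1200, seed = 71)
  expect_identical(intensities(a$stack), intensities(b$stack))
  expect_identical(a$truth, b$truth)
  p1 <- generatePPPS(crosslinkDensity = 0.4, seed = 72)
  p2 <- generatePPPS(crosslinkDensity = 0.4, seed = 72)
  expect_identical(intensities(p1$stack), intensities(p2$stack))
  t1 <- generateTwoChannel("shell", seed = 73)
  t2 <- generateTwoChannel("shell", seed = 73)
  expect_identical(intensities(t1$channelA), intensities(t2$channelA))
  f1 <- generateFRAP(seed = 74); f2 <- generateFRAP(seed = 74)
  expect_identical(intensities(f1$experiment@timelapse),
                   intensities(f2$experiment@timelapse))
  # different seed, different field
  c2 <- generateLLPS(dropletVolume = 1200, seed = 75)
  expect_false(identical(intensities(a$stack), intensities(c2$stack)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateLLPS(dropletVolume = 800, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("noise-free LLPS droplets measure at their construction values", {
  g <- generateLLPS(concentration = 80, dropletVolume = 1500,
                    psfSigma = 0, noise = "none", seed = 76)
  m <- signalMetrics(g$stack)
  expect_identical(m$volume, as.integer(g$truth$realized_volume))
  expect_equal(m$mean_above_bg, 80 - m$threshold, tolerance = 1e-6)
  # target volume realized within discretization error
  expect_lt(abs(g$truth$realized_volume - 1500) / 1500, 0.1)
  # droplet too large for the stack
  expect_error(generateLLPS(dropletVolume = 1e6, seed = 1), "geometry")
})

test_that("LLPS mean intensity is conserved across droplet volumes", {
  means <- vapply(seq(500, 4000, length.out = 12), function(v) {
    g <- generateLLPS(dropletVolume = v, noise = "none", seed = round(v))
    signalMetrics(g$stack)$mean_above_bg
  }, numeric(1))
  expect_lt(diff(range(means)) / mean(means), 0.15)
})

test_that("PPPS conserves integrated intensity and compacts with density", {
  g <- generatePPPS(totalIntensity = 2e5, crosslinkDensity = 0.5,
                    noise = "none", seed = 77)
  expect_equal(g$truth$realized_integrated_intensity, 2e5, tolerance = 0.01)
  # conservation measured through the pipeline (noise off): foreground
  # integrated intensity close to the generator total
  m <- signalMetrics(g$stack)
  # foreground integrated intensity minus its background pedestal recovers
  # most of the conserved generator total (blob tails sit below Otsu)
  captured <- (m$integrated_intensity - 10 * m$volume) / 2e5
  expect_gt(captured, 0.5)
  expect_lt(captured, 1.01)
  # density sweep: volume falls, mean rises, monotonically in rank
  dens <- seq(0.1, 0.9, length.out = 12)
  met <- do.call(rbind, lapply(seq_along(dens), function(i)
    signalMetrics(generatePPPS(crosslinkDensity = dens[i],
                               seed = 780 + i)$stack)))
  expect_gt(cor(dens, met$mean_above_bg, method = "spearman"), 0.9)
  expect_lt(cor(dens, met$volume, method = "spearman"), -0.9)
  expect_error(generatePPPS(nPuncta = 0), "at least one")
})

test_that("compaction lowers texture homogeneity", {
  h <- function(d) mean(vapply(1:10, function(i)
    homogeneityScore(generatePPPS(nPuncta = 8, crosslinkDensity = d,
                                  seed = 790 + i)$stack)$score, numeric(1)))
  hd <- mean(vapply(1:10, function(i)
    homogeneityScore(generateLLPS(dropletVolume = 2500,
                                  seed = 790 + i)$stack)$score, numeric(1)))
  # sharper, denser puncta make adjacent gray levels jump more
  expect_lt(h(0.9), h(0.2))
  # the flat droplet is the most homogeneous regime
  expect_gt(hd, h(0.9))
})

test_that("two-channel geometries realize their construction volumes", {
  tc <- generateTwoChannel("intermixed", radius = 10, noise = "none",
                           psfSigma = 0, seed = 80)
  expect_identical(tc$truth$volume_A, tc$truth$volume_B)
  fa <- filterStack(tc$channelA)
  expect_identical(foregroundVolume(fa), as.integer(tc$truth$volume_A))
  sh <- generateTwoChannel("shell", radius = 10, shellThickness = 1.5,
                           noise = "none", psfSigma = 0, seed = 81)
  expect_lt(sh$truth$volume_A, sh$truth$volume_B)
  expect_error(generateTwoChannel("shell", radius = 5, shellThickness = 6),
               "geometry")
  expect_error(generateTwoChannel("intermixed", radius = 2), "geometry")
})

test_that("FRAP generator reports the analytic expected recovery", {
  g <- generateFRAP(m = 0.4, k = 0.3, beta = 0.01, nFrames = 50,
                    duration = 30, seed = 82)
  expect_equal(g$truth$frame_time, 0.6)
  expect_equal(g$truth$t_final, 29.4)
  expect_equal(g$truth$expected_percent_recovery,
               0.4 * (1 - exp(-0.3 * 29.4)))
  expect_identical(dim(intensities(g$experiment@timelapse))[1], 50L)
  expect_error(generateFRAP(m = 1.5), "mobile fraction")
})

test_that("poisson noise mode produces integer counts around the signal", {
  g <- generateLLPS(concentration = 80, dropletVolume = 1000,
                    noise = "poisson", seed = 83)
  a <- intensities(g$stack)
  expect_true(all(a == round(a)))
  expect_gt(max(a), 50)
})
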