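make_frap_images <- function(shape = c(41, 41), sigR = 12, spotR = 4,
                             spotOff = c(0, 3)) {
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  signal <- (yy - cy)^2 + (xx - cx)^2 <= sigR^2
  spot <- (yy - cy - spotOff[1])^2 + (xx - cx - spotOff[2])^2 <= spotR^2
  list(signal = signal, spot = spot,
       prebleach = VoxelStack(10 + 90 * signal),
       laser = VoxelStack(2 + 198 * spot))
}

test_that("recovery region is the signal/spot intersection", {
  im <- make_frap_images()
  reg <- recoveryRegion(im$prebleach, im$laser)
  # spot fully inside signal: region == spot mask, counted by brute force
  expect_identical(reg$mask, im$signal & im$spot)
  expect_identical(sum(reg$mask), sum(im$spot))
  expect_equal(reg$prebleachMean, 100)
  # half-overlapping spot: area equals the brute-force overlap count
  im2 <- make_frap_images(spotOff = c(0, 11))
  reg2 <- recoveryRegion(im2$prebleach, im2$laser)
  expect_identical(sum(reg2$mask), sum(im2$signal & im2$spot))
  expect_lt(sum(reg2$mask), sum(im2$spot))
  # disjoint spot misses the signal entirely
  im3 <- make_frap_images(sigR = 8, spotR = 3, spotOff = c(0, 15))
  expect_error(recoveryRegion(im3$prebleach, im3$laser), "misses")
})

test_that("bleach rate recovers exact and noisy linear slopes", {
  mk <- function(means) {
    a <- array(0, c(length(means), 5, 5))
    for (i in seq_along(means)) a[i, , ] <- means[i]
    VoxelStack(a, frameTime = 0.6)
  }
  expect_equal(bleachRate(mk(100 - 0.5 * (0:19)))$slope, -0.5)
  expect_equal(bleachRate(mk(rep(42, 10)))$slope, 0)
  # noisy decay: compare with the closed-form normal-equations solution
  set.seed(61)
  y <- 100 - 0.8 * (0:49) + rnorm(50, 0, 2)
  t <- 0:49
  slopeHand <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(bleachRate(mk(y))$slope, slopeHand, tolerance = 1e-10)
  expect_error(bleachRate(mk(5)), "2 frames")
})

test_that("limiting recovery curves behave as expected", {
  # instant full recovery, no bleaching: final normalized ~ 1, recovery ~ 1
  g <- generateFRAP(m = 1, k = 50, beta = 0, noiseSd = 0, seed = 62)
  rc <- normalizeWithCorrection(g$experiment)
  expect_equal(normalizedCurve(rc)[length(normalizedCurve(rc))], 1,
               tolerance = 1e-6)
  expect_equal(percentRecovery(rc), 1, tolerance = 1e-6)
  expect_false(rc@rateAdjusted)
  # immobile signal: percent recovery ~ 0, unrecovered fraction ~ 1
  g0 <- generateFRAP(m = 0, k = 0.3, beta = 0, noiseSd = 0, seed = 63)
  rc0 <- normalizeWithCorrection(g0$experiment)
  expect_equal(percentRecovery(rc0), 0, tolerance = 1e-6)
  expect_equal(unrecoveredFraction(rc0), 1, tolerance = 1e-6)
  # flat normalized curve -> zero recovery under the difference definition
  expect_equal(max(abs(diff(normalizedCurve(rc0)))), 0, tolerance = 1e-6)
})

test_that("noiseless beta = 0 recovery equals m(1 - exp(-kT)) exactly", {
  for (m in c(0.25, 0.6)) {
    g <- generateFRAP(m = m, k = 0.3, beta = 0, noiseSd = 0, seed = 64)
    rc <- normalizeWithCorrection(g$experiment)
    expect_equal(percentRecovery(rc), m * (1 - exp(-0.3 * g$truth$t_final)),
                 tolerance = 1e-9)
    expect_equal(rc@bleachRate, 0, tolerance = 1e-9)
  }
})

test_that("correction is idempotent on an unbleached constant-rate series", {
  g <- generateFRAP(m = 0.5, k = 0.3, beta = 0, noiseSd = 0, seed = 65)
  rc1 <- normalizeWithCorrection(g$experiment, correction = "ratio")
  rc2 <- normalizeWithCorrection(g$experiment, correction = "none")
  expect_equal(normalizedCurve(rc1), normalizedCurve(rc2), tolerance = 1e-9)
})

test_that("photobleach correction recovers kinetics under bleaching", {
  for (m in c(0.2, 0.8)) {
    pr <- vapply(1:8, function(i) {
      g <- generateFRAP(m = m, k = 0.3, beta = 0.01, seed = 660 + i + 100 * m)
      percentRecovery(normalizeWithCorrection(g$experiment))
    }, numeric(1))
    target <- m * (1 - exp(-0.3 * 29.4))
    expect_lt(max(abs(pr - target)), 0.1)
  }
})

test_that("negative percent recovery triggers the rate step-up loop", {
  # strongly bleaching immobile signal: raw final < raw first, so the
  # correction must be stepped up until percent recovery is non-negative
  g <- generateFRAP(m = 0.02, k = 0.3, beta = 0.04, noiseSd = 0.04,
                    seed = 67)
  rc <- normalizeWithCorrection(g$experiment, correction = "additive",
                                reference = "frame")
  expect_gte(percentRecovery(rc), 0)
  # the flag is consistent with the iteration count
  expect_identical(rc@rateAdjusted, rc@adjustIterations > 0L)
})

test_that("mobile-fraction groups order correctly and separate", {
  prs <- lapply(c(0.1, 0.5, 0.8), function(m)
    vapply(1:8, function(i) {
      g <- generateFRAP(m = m, k = 0.3, beta = 0, seed = 680 + i + 1000 * m)
      percentRecovery(normalizeWithCorrection(g$experiment))
    }, numeric(1)))
  expect_lt(mean(prs[[1]]), mean(prs[[2]]))
  expect_lt(mean(prs[[2]]), mean(prs[[3]]))
  p12 <- wilcox.test(prs[[1]], prs[[2]])$p.value
  p23 <- wilcox.test(prs[[2]], prs[[3]])$p.value
  expect_lt(p12, 0.01)
  expect_lt(p23, 0.01)
})
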