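test_that("volume, mean above background and compression arithmetic", {
  # 10 voxels of 50 above threshold 20 in a dim sea
  a <- array(10, c(5, 5, 5))
  a[1, 1, 1:5] <- 50; a[2, 1, 1:5] <- 50
  f <- filtered_at(a, 20)
  expect_identical(signalVolume(f), 10L)
  expect_equal(meanIntensityAboveBackground(f), 500 / 10 - 20)
  expect_equal(signalCompression(30, 125), 0.24)
  expect_equal(signalCompression(30, 250), 0.12)  # doubling volume halves it
  # single-voxel foreground
  b <- array(0, c(3, 3, 3)); b[2, 2, 2] <- 9
  expect_identical(signalVolume(filtered_at(b, 5)), 1L)
  # limiting case: all foreground just above the threshold
  d <- array(0, c(2, 2, 2)); d[1, , ] <- 20.001
  expect_equal(meanIntensityAboveBackground(filtered_at(d, 20)), 0.001)
})

test_that("volume equals an independent brute-force voxel count", {
  set.seed(31)
  a <- array(runif(4 * 8 * 8, 0, 100), c(4, 8, 8))
  f <- filtered_at(a, 60)
  cnt <- 0L
  for (z in 1:4) for (y in 1:8) for (x in 1:8)
    if (a[z, y, x] > 60) cnt <- cnt + 1L
  expect_identical(signalVolume(f), cnt)
})

test_that("heterogeneity SD fixed points and affine invariance", {
  a <- array(0, c(2, 4, 4)); a[1, , ] <- 70
  expect_identical(heterogeneitySD(filtered_at(a, 10)), 0)  # constant fg
  # half foreground at min, half at max -> population SD exactly 0.5
  b <- array(0, c(2, 4, 4)); b[1, , ] <- 30; b[2, , ] <- 90
  expect_identical(heterogeneitySD(filtered_at(b, 10)), 0.5)
  expect_equal(heterogeneitySD(filtered_at(b, 10), type = "sample"),
               sd(rep(c(0, 1), each = 16)))
  # direct-formula oracle + affine invariance
  set.seed(32)
  d <- array(runif(4 * 6 * 6, 20, 200), c(4, 6, 6))
  f <- filtered_at(d, 50)
  v <- d[d > 50]
  r <- (v - min(v)) / (max(v) - min(v))
  expect_equal(heterogeneitySD(f), sqrt(mean((r - mean(r))^2)))
  f2 <- filtered_at(3 * d + 11, 3 * 50 + 11)
  expect_equal(heterogeneitySD(f2), heterogeneitySD(f), tolerance = 1e-12)
  expect_lte(heterogeneitySD(f), 0.5)
})

test_that("signalMetrics satisfies the bookkeeping identity", {
  g <- generatePPPS(crosslinkDensity = 0.6, noise = "none", seed = 33)
  m <- signalMetrics(g$stack)
  expect_equal((m$mean_above_bg + m$threshold) * m$volume,
               m$integrated_intensity, tolerance = 1e-9)
  expect_equal(m$compression, m$mean_above_bg / m$volume)
  expect_gte(m$volume, 1)
  expect_true(all(c("in_focus_area", "max_proj_area", "sum_proj_area")
                  %in% names(m)))
})

test_that("outlier gating flags exactly the injected gross outliers", {
  set.seed(34)
  n <- 50
  base <- data.frame(
    volume = rnorm(n, 1000, 30), in_focus_area = rnorm(n, 150, 5),
    max_proj_area = rnorm(n, 200, 6), sum_proj_area = rnorm(n, 210, 6),
    integrated_intensity = rnorm(n, 5e4, 1500),
    mean_above_bg = rnorm(n, 40, 1.5))
  flags0 <- flagOutliers(base)
  planted <- c(3, 27)
  tampered <- base
  tampered$volume[planted[1]] <- 100 * median(base$volume)
  tampered$mean_above_bg[planted[2]] <-
    median(base$mean_above_bg) + 10 * mad(base$mean_above_bg)
  flags <- flagOutliers(tampered)
  expect_true(all(flags[planted]))
  expect_identical(which(flags & !flags0), as.integer(sort(planted)))
  # identical records: nothing can be flagged
  same <- base[rep(1, 10), ]
  expect_false(any(flagOutliers(same)))
  expect_error(flagOutliers(base[1:4, ]), "at least 5")
})

test_that("Pearson correlation matches a hand-computed 5-point table", {
  rec <- data.frame(volume = c(100, 200, 300, 400, 500),
                    mean_above_bg = c(50, 25, 16.7, 12.5, 10))
  # closed-form Pearson on the table
  x <- rec$volume; y <- rec$mean_above_bg
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- volumeIntensityCorrelation(rec, gate = FALSE)
  expect_equal(out$pearson_r, r_hand, tolerance = 1e-12)
  expect_lt(out$pearson_r, 0)
  # p-value via the t-transform with n - 2 df
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$p_value, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
})

test_that("independent volume and mean give r near zero at n = 200", {
  set.seed(35)
  rec <- data.frame(volume = runif(200, 500, 4000),
                    mean_above_bg = rnorm(200, 60, 3))
  rec$in_focus_area <- rec$volume * 0.2 + rnorm(200)
  rec$max_proj_area <- rec$volume * 0.25 + rnorm(200)
  rec$sum_proj_area <- rec$volume * 0.3 + rnorm(200)
  rec$integrated_intensity <- rec$volume * rec$mean_above_bg
  out <- volumeIntensityCorrelation(rec)
  expect_lt(abs(out$pearson_r), 0.2)
  expect_gt(out$p_value, 0.05)
  expect_lte(out$n_after, out$n_before)
  # degenerate variance errors
  bad <- data.frame(volume = rep(5, 10), mean_above_bg = 1:10)
  expect_error(volumeIntensityCorrelation(bad, gate = FALSE), "variance")
})
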