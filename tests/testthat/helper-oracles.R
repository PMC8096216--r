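# Independent brute-force oracles shared across tests. These deliberately
# use naive loops / direct formulas, never the package's own code paths.

# Otsu by exhaustive scan: over every candidate integer threshold, compute
# the pooled within-class variance of the raw values and pick the minimizer
# (smallest threshold on ties).
oracle_otsu_scan <- function(values) {
  u <- sort(unique(values))
  best_i <- NA
  best_w <- Inf
  popvar <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)
  for (i in seq_len(length(u) - 1)) {     # both classes must be non-empty
    lo <- values[values <= u[i]]
    hi <- values[values > u[i]]
    w <- length(lo) * popvar(lo) + length(hi) * popvar(hi)
    if (w < best_w - 1e-9) {
      best_w <- w
      best_i <- i
    }
  }
  # canonical threshold: midpoint of the gap between the two classes
  (u[best_i] + u[best_i + 1]) / 2
}

# Co-occurrence counts and homogeneity by explicit double loop over every
# horizontal neighbour pair.
oracle_glcm <- function(q, nLevels = 8) {
  cnt <- matrix(0, nLevels, nLevels)
  for (y in seq_len(nrow(q))) {
    for (x in seq_len(ncol(q) - 1)) {
      a <- q[y, x]; b <- q[y, x + 1]
      if (!is.na(a) && !is.na(b)) cnt[a, b] <- cnt[a, b] + 1
    }
  }
  cnt
}

oracle_homogeneity <- function(q, nLevels = 8) {
  cnt <- oracle_glcm(q, nLevels)
  n <- sum(cnt)
  s <- 0
  for (i in seq_len(nLevels)) for (j in seq_len(nLevels))
    s <- s + cnt[i, j] / (1 + abs(i - j))
  s / n
}

# Mann-Whitney U by direct pair counting, and its two-sided p-value by
# exhaustive enumeration of all group assignments.
oracle_ranksum <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  obs <- oracle_ranksum(x, y)
  mu <- length(x) * length(y) / 2
  stats <- apply(idx, 2, function(sel)
    oracle_ranksum(pooled[sel], pooled[-sel]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# A two-level stack with a bright axis-aligned box in dim background.
make_box_stack <- function(shape = c(9, 12, 12), box = 5, lo = 5, hi = 100) {
  a <- array(lo, shape)
  z0 <- (shape[1] - box) %/% 2
  y0 <- (shape[2] - box) %/% 2
  x0 <- (shape[3] - box) %/% 2
  a[z0 + seq_len(box), y0 + seq_len(box), x0 + seq_len(box)] <- hi
  VoxelStack(a)
}

# FilteredStack with a hand-picked threshold (bypasses Otsu).
filtered_at <- function(a, t) filterStack(VoxelStack(a), threshold = t)
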