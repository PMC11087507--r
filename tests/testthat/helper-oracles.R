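# Independent brute-force oracles, deliberately naive and separate from the
# package's compiled paths.

# minimum city-block (L1) distance from each row of `from` (arrayInd coords)
# to the voxel set `to`
bfMinL1 <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i)
    min(abs(to[, 1] - from[i, 1]) + abs(to[, 2] - from[i, 2]) +
        abs(to[, 3] - from[i, 3])), numeric(1))
}

# minimum Euclidean distance from each row of `from` to pixel set `to` (2D)
bfMinEuclid2d <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i)
    sqrt(min((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2)),
    numeric(1))
}

# voxel count of a digital ball by direct enumeration
bfBallCount <- function(center, r) {
  g <- expand.grid(z = floor(center[1] - r):ceiling(center[1] + r),
                   y = floor(center[2] - r):ceiling(center[2] + r),
                   x = floor(center[3] - r):ceiling(center[3] + r))
  sum((g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2 <=
        r^2 + 1e-9)
}

# exhaustive two-sided difference-of-means permutation p-value
bfExhaustivePermP <- function(a, b) {
  x <- c(a, b); na <- length(a); n <- length(x)
  obs <- abs(mean(x[seq_len(na)]) - mean(x[-seq_len(na)]))
  sel <- utils::combn(n, na)
  stats <- apply(sel, 2, function(ia) abs(mean(x[ia]) - mean(x[-ia])))
  mean(stats >= obs - 1e-12)
}

# prolate spheroid (a = b < c) surface area, closed form
bfProlateSA <- function(a, c0) {
  e <- sqrt(1 - a^2 / c0^2)
  2 * pi * a^2 * (1 + c0 / (a * e) * asin(e))
}

# random 2D binary blob (union of discs) for EDT property tests
bfRandomMask2d <- function(side, nDiscs = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, side, side)
    for (i in seq_len(nDiscs)) {
      r <- stats::runif(1, 4, side / 5)
      c0 <- stats::runif(2, r + 1, side - r)
      yy <- seq_len(side); xx <- seq_len(side)
      m <- m | (outer((yy - c0[1])^2, (xx - c0[2])^2, "+") <= r^2)
    }
    m
  })
}
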