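# Independent oracles used across the suite.

# exhaustive joint-histogram tally for small integer images
bruteJointTally <- function(f, g, bins, edgesF, edgesM) {
  counts <- matrix(0, bins, bins)
  for (k in seq_along(f)) {
    i <- findInterval(f[k], edgesF, rightmost.closed = TRUE)
    j <- findInterval(g[k], edgesM, rightmost.closed = TRUE)
    i <- min(max(i, 1L), bins); j <- min(max(j, 1L), bins)
    counts[i, j] <- counts[i, j] + 1
  }
  counts
}

# plain -sum p log2 p, written independently of the package
bruteEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# mutual information of a bivariate Gaussian by 2D numerical integration
gaussianMINumeric <- function(rho, lim = 8, n = 801) {
  x <- seq(-lim, lim, length.out = n)
  h <- x[2] - x[1]
  X <- matrix(x, n, n); Y <- t(X)
  det <- 1 - rho^2
  p <- exp(-(X^2 - 2 * rho * X * Y + Y^2) / (2 * det)) / (2 * pi * sqrt(det))
  px <- exp(-x^2 / 2) / sqrt(2 * pi)
  mar <- outer(px, px)
  ok <- p > 1e-300
  sum(p[ok] * log2(p[ok] / mar[ok])) * h^2
}

# small smooth blob image used in several transform tests
blobSlice <- function(n, cx = 0.4, cy = 0.55, s = 0.12) {
  g <- seq(0, 1, length.out = n)
  outer(g, g, function(x, y) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
}

bandEnergies <- function(dec) vapply(dec@bands, function(b) sum(b^2), 0)
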