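MI_MAX_BITS <- 30

#' Maximum-likelihood Gaussian fit of a matched band pair
#'
#' Fits a bivariate Gaussian to the coefficients of a matched pair of
#' curvelet bands by maximum likelihood: sample means, biased (1/n)
#' variances, and the Pearson correlation. A zero-variance band yields
#' \code{rho = 0} with the degenerate flag set rather than an error.
#'
#' @param pair a pair as produced by [matchBands()] (a list with elements
#'   \code{f} and \code{m} of equal shape), or two arrays given as
#'   \code{pair} and \code{m}.
#' @param m optional second band when \code{pair} is an array.
#' @param weight energy-share weight to record (normalized over bands by
#'   [adaptiveMI()]); default 0.
#' @return A [BandStats-class].
#' @examples
#' b <- array(rnorm(27), c(3, 3, 3))
#' fitBandStats(list(f = b, m = -b))@rho
#' @export
fitBandStats <- function(pair, m = NULL, weight = 0) {
  if (!is.null(m)) pair <- list(f = pair, m = m)
  f <- as.numeric(pair$f); g <- as.numeric(pair$m)
  if (length(f) != length(g)) stop("bands must have the same shape")
  n <- length(f)
  if (n < 2) stop("need at least 2 coefficients")
  mf <- mean(f); mm <- mean(g)
  vf <- mean((f - mf)^2); vm <- mean((g - mm)^2)
  degen <- (vf <= 0 || vm <= 0)
  rho <- if (degen) 0 else {
    r <- mean((f - mf) * (g - mm)) / sqrt(vf * vm)
    min(max(r, -1), 1)
  }
  new("BandStats", meanF = mf, meanM = mm, varF = vf, varM = vm,
      rho = rho, n = as.numeric(n), weight = as.numeric(weight),
      degenerate = degen)
}

#' Mutual information of a Gaussian band pair
#'
#' Closed-form mutual information of a bivariate Gaussian,
#' \code{-1/2 log2(1 - rho^2)} bits. Even in \code{rho}, so positive and
#' negative intensity correlations contribute equally. Degenerate bands
#' give 0; \code{|rho| = 1} saturates at 30 bits (attribute
#' \code{"saturated"} set).
#'
#' @param s a [BandStats-class], or a numeric correlation.
#' @return Non-negative mutual information in bits.
#' @export
bandMI <- function(s) {
  rho <- if (is(s, "BandStats")) {
    if (s@degenerate) return(0)
    s@rho
  } else as.numeric(s)
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  om <- 1 - rho^2
  if (om < 2^-60) return(structure(MI_MAX_BITS, saturated = TRUE))
  -0.5 * log2(om)
}

# energy-weighted Gaussian band MI from per-band moment summaries
amiFromMoments <- function(moments) {
  mi <- numeric(length(moments)); en <- numeric(length(moments))
  for (k in seq_along(moments)) {
    mo <- moments[[k]]
    n <- mo$n
    vf <- mo$sumsqF / n - (mo$sumF / n)^2
    vm <- mo$sumsqM / n - (mo$sumM / n)^2
    en[k] <- mo$sumsqF + mo$sumsqM
    if (vf <= 0 || vm <= 0) { mi[k] <- 0; next }
    rho <- (mo$cross / n - mo$sumF * mo$sumM / n^2) / sqrt(vf * vm)
    rho <- min(max(rho, -1), 1)
    mi[k] <- bandMI(rho)
  }
  tot <- sum(en)
  if (tot <= 0) return(0)
  sum(en / tot * mi)
}

#' Adaptive mutual information of two curvelet decompositions
#'
#' The registration objective: the energy-weighted sum over matched
#' curvelet band pairs of the Gaussian band mutual information, with each
#' pair weighted by its share of the pooled coefficient energy so that
#' bands carrying more structure dominate ("adaptive"). Symmetric in its
#' arguments.
#'
#' @param fixedDec,movingDec [CurveletDecomposition-class] objects of
#'   same-shape images with identical settings.
#' @return Mutual information in bits (non-negative).
#' @export
adaptiveMI <- function(fixedDec, movingDec) {
  pairs <- matchBands(fixedDec, movingDec)
  moments <- lapply(pairs, function(p) {
    f <- as.numeric(p$f); g <- as.numeric(p$m)
    list(n = length(f), sumF = sum(f), sumM = sum(g),
         sumsqF = sum(f^2), sumsqM = sum(g^2), cross = sum(f * g))
  })
  amiFromMoments(moments)
}

#' Joint intensity histogram of an image pair
#'
#' 2D count histogram over voxels on a common grid, with equal-width bins
#' spanning each image's robust (0.5-99.5 percentile) intensity range;
#' out-of-range intensities are clamped into the edge bins. An optional
#' Gaussian smoothing of the counts (sigma in bins) is available for
#' derivative-friendly probability estimates. When a logical \code{mask}
#' is given, only voxels where it is TRUE are tallied (e.g. the overlap
#' region after resampling).
#'
#' @param fixed,moving [Volume-class] objects (or arrays) on the same grid.
#' @param bins number of bins per axis (>= 2, default 64).
#' @param smoothingSigma Gaussian sigma in bins applied to the counts
#'   (default 1; use 0 for exact tallies).
#' @param mask optional logical array selecting the voxels to tally.
#' @return A [JointHistogram-class].
#' @export
jointHistogram <- function(fixed, moving, bins = 64L, smoothingSigma = 1,
                           mask = NULL) {
  f <- if (is(fixed, "Volume")) fixed@data else fixed
  g <- if (is(moving, "Volume")) moving@data else moving
  if (!identical(dim(f), dim(g))) stop("images must share a grid")
  if (bins < 2) stop("need at least 2 bins")
  f <- as.numeric(f); g <- as.numeric(g)
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    f <- f[keep]; g <- g[keep]
  }
  if (length(f) == 0) stop("empty overlap region")
  edges <- function(x) {
    r <- quantile(x, c(0.005, 0.995), names = FALSE)
    if (r[1] >= r[2]) r <- c(r[1] - 0.5, r[1] + 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  ef <- edges(f); em <- edges(g)
  bin <- function(x, e) {
    i <- findInterval(x, e, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), length(e) - 1L)
  }
  bi <- bin(f, ef); bj <- bin(g, em)
  counts <- matrix(0, bins, bins)
  tab <- tabulate((bj - 1L) * bins + bi, nbins = bins * bins)
  counts[] <- tab
  if (smoothingSigma > 0) {
    n0 <- sum(counts)
    sm <- .gaussSmoothCpp(as.numeric(counts), c(bins, bins, 1L),
                          c(smoothingSigma, smoothingSigma, 0))
    counts <- matrix(sm, bins, bins)
    counts <- counts * (n0 / sum(counts))
  }
  new("JointHistogram", counts = counts, edgesF = ef, edgesM = em,
      n = length(f))
}

#' Shannon entropy in bits
#'
#' \code{-sum(p * log2(p))} with \code{0 log 0 = 0}. Accepts a probability
#' vector or matrix (entries non-negative, summing to 1 within 1e-9).
#'
#' @param p probability vector or matrix.
#' @return Non-negative entropy in bits.
#' @examples
#' shannonEntropy(c(0.5, 0.25, 0.25))
#' @export
shannonEntropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

histEntropies <- function(jh) {
  p <- jh@counts / jh@n
  hj <- shannonEntropy(p)
  hf <- shannonEntropy(rowSums(p))
  hm <- shannonEntropy(colSums(p))
  list(hf = hf, hm = hm, hj = hj,
       hFgivenM = hj - hm, hMgivenF = hj - hf)
}

#' Normalized mutual information
#'
#' \code{2 (H(If) + H(Im)) / (H(If) + H(Im) + H(If|Im) + H(Im|If))}, with
#' all entropies estimated from the joint intensity histogram and
#' conditional entropies obtained as \code{H(A|B) = H(A,B) - H(B)}. Ranges
#' from 1 (independent) to 2 (identical); identical images give exactly 2.
#'
#' @param fixed,moving [Volume-class] objects (or arrays) on the same grid.
#' @param bins histogram bins per axis (default 64).
#' @param smoothingSigma histogram count smoothing in bins; default 0 so
#'   that identical images score exactly 2.
#' @param mask optional logical array restricting the tally (overlap
#'   region).
#' @return NMI in [1, 2].
#' @export
nmi <- function(fixed, moving, bins = 64L, smoothingSigma = 0, mask = NULL) {
  jh <- jointHistogram(fixed, moving, bins = bins,
                       smoothingSigma = smoothingSigma, mask = mask)
  e <- histEntropies(jh)
  2 * (e$hf + e$hm) / (e$hf + e$hm + e$hFgivenM + e$hMgivenF)
}

#' Normalized cross-correlation coefficient
#'
#' Pearson correlation of voxel intensities over the (optionally masked)
#' overlap region: insensitive to affine intensity changes, bounded by
#' [-1, 1], and 1 exactly when the images are linearly related with
#' positive slope.
#'
#' @param fixed,moving [Volume-class] objects (or arrays) on the same grid.
#' @param mask optional logical array restricting the sum (overlap region).
#' @return Correlation in [-1, 1].
#' @export
nccc <- function(fixed, moving, mask = NULL) {
  f <- if (is(fixed, "Volume")) fixed@data else fixed
  g <- if (is(moving, "Volume")) moving@data else moving
  if (!identical(dim(f), dim(g))) stop("images must share a grid")
  f <- as.numeric(f); g <- as.numeric(g)
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    f <- f[keep]; g <- g[keep]
  }
  if (length(f) < 2) stop("empty overlap region")
  f <- f - mean(f); g <- g - mean(g)
  df <- sum(f^2); dg <- sum(g^2)
  if (df <= 0 || dg <= 0)
    stop("correlation undefined: an image is constant over the overlap")
  sum(f * g) / sqrt(df * dg)
}
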