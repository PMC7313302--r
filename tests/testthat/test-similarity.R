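test_that("band statistics are the ML bivariate-Gaussian estimates", {
  b <- array(rnorm(27), c(3, 3, 3))
  s <- fitBandStats(list(f = b, m = b))
  expect_equal(s@rho, 1)
  expect_equal(s@meanF, s@meanM)
  expect_equal(fitBandStats(list(f = b, m = -b))@rho, -1)

  f <- matrix(c(1, 4, 2, 7, 3, 5, 8, 2, 6), 3)
  g <- matrix(c(2, 3, 1, 9, 4, 4, 7, 1, 8), 3)
  s <- fitBandStats(list(f = f, m = g))
  # direct evaluation of the ML formulas
  n <- 9
  expect_equal(s@meanF, sum(f) / n)
  expect_equal(s@varF, sum((f - sum(f) / n)^2) / n)
  expect_equal(s@varM, sum((g - sum(g) / n)^2) / n)
  covFM <- sum((f - mean(f)) * (g - mean(g))) / n
  expect_equal(s@rho, covFM / sqrt(s@varF * s@varM))
  expect_equal(s@n, 9)

  degen <- fitBandStats(list(f = matrix(1, 2, 2), m = matrix(rnorm(4), 2)))
  expect_true(degen@degenerate)
  expect_equal(degen@rho, 0)
})

test_that("Gaussian band MI matches theory and numerical integration", {
  expect_equal(bandMI(0), 0)
  expect_equal(bandMI(0.5), bandMI(-0.5))
  expect_equal(bandMI(0.5), -0.5 * log2(0.75))
  sat <- bandMI(1)
  expect_equal(as.numeric(sat), 30)
  expect_true(attr(sat, "saturated"))
  for (rho in c(0, 0.3, -0.3, 0.7, -0.7, 0.9, -0.9)) {
    expect_lt(abs(bandMI(rho) - gaussianMINumeric(rho)), 1e-4)
  }
})

test_that("adaptive MI prefers alignment and tolerates intensity remaps", {
  v <- makeBrainPhantom(phantomSpec(shape = c(48, 48, 32), seed = 21,
                                    noiseSigma = 0.02))
  decV <- curveletForward(v)
  shifted <- resampleVolume(v, affineParams(translation = c(2 * spacing(v)[1], 0, 0)))
  expect_gt(adaptiveMI(decV, decV), adaptiveMI(decV, curveletForward(shifted)))

  # against a constant image every moving band is degenerate
  expect_equal(adaptiveMI(decV, curveletForward(array(5, dim(v)))), 0)

  # symmetric in its arguments
  w <- makeBrainPhantom(phantomSpec(shape = c(48, 48, 32), seed = 22,
                                    modality = "pet_like"))
  decW <- curveletForward(w)
  expect_lt(abs(adaptiveMI(decV, decW) - adaptiveMI(decW, decV)), 1e-10)

  # an aligned cross-contrast (PET-like remap) pair still carries a clear
  # alignment signal: its AMI beats any misaligned copy by a wide margin
  multi <- makePhantomPair(phantomSpec(shape = c(48, 48, 48), seed = 31),
                           multimodal = TRUE)
  decF <- curveletForward(multi$fixed)
  amiAligned <- adaptiveMI(decF, curveletForward(multi$moving))
  shifted2 <- resampleVolume(multi$moving,
                             affineParams(translation = c(2 * spacing(multi$moving)[1], 0, 0)))
  amiShifted <- adaptiveMI(decF, curveletForward(shifted2))
  expect_gt(amiAligned, amiShifted * 1.02)
})

test_that("joint histograms equal an exhaustive tally", {
  one <- Volume(array(4, c(3, 3, 1)))
  jh <- jointHistogram(one, one, bins = 8, smoothingSigma = 0)
  expect_equal(sum(jh@counts > 0), 1)
  expect_equal(sum(jh@counts), 9)

  vals <- array(rep(c(1, 2, 3, 4), each = 4), c(4, 4, 1))
  jh <- jointHistogram(vals, vals, bins = 4, smoothingSigma = 0)
  expect_true(all(jh@counts[row(jh@counts) != col(jh@counts)] == 0))

  set.seed(8)
  for (rep in 1:3) {
    f <- array(sample(0:5, 9, replace = TRUE), c(3, 3, 1))
    g <- array(sample(0:5, 9, replace = TRUE), c(3, 3, 1))
    jh <- jointHistogram(f, g, bins = 6, smoothingSigma = 0)
    expect_equal(jh@counts,
                 bruteJointTally(as.numeric(f), as.numeric(g), 6,
                                 jh@edgesF, jh@edgesM))
    # marginals consistent with the joint by summation
    expect_equal(sum(jh@counts), jh@n)
  }
  expect_error(jointHistogram(one, Volume(array(0, c(2, 2, 1)))), "grid")
  expect_error(jointHistogram(one, one, bins = 1), "bins")
  expect_error(jointHistogram(one, one, mask = array(FALSE, c(3, 3, 1))),
               "empty overlap")
})

test_that("entropy follows the Shannon definition", {
  expect_equal(shannonEntropy(rep(0.25, 4)), 2)
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannonEntropy(c(0.5, -0.1, 0.6)), "non-negative")
  expect_error(shannonEntropy(c(0.5, 0.4)), "sum to 1")
})

test_that("NMI is 2 for identical images and near 1 for independent ones", {
  v <- makeBrainPhantom(phantomSpec(shape = c(48, 48, 48), seed = 13,
                                    noiseSigma = 0.03))
  expect_equal(nmi(v, v), 2, tolerance = 1e-9)

  set.seed(99)
  a <- volData(v)
  b <- array(sample(a), dim(a))            # voxel shuffle: independent
  expect_lt(abs(nmi(v, Volume(b)) - 1), 0.02)
  expect_gte(length(a), 1e5)

  # small joint histogram against the entropy oracle
  f <- array(c(0, 0, 1, 2, 2, 1, 0, 1, 2), c(3, 3, 1))
  g <- array(c(1, 1, 0, 2, 0, 0, 1, 2, 2), c(3, 3, 1))
  jh <- jointHistogram(f, g, bins = 3, smoothingSigma = 0)
  p <- jh@counts / jh@n
  hf <- bruteEntropy(rowSums(p)); hm <- bruteEntropy(colSums(p))
  hj <- bruteEntropy(p)
  expect_equal(nmi(f, g, bins = 3),
               2 * (hf + hm) / (hf + hm + (hj - hm) + (hj - hf)))
})

test_that("NMI stays within its [1, 2] bounds", {
  set.seed(3)
  for (rep in 1:5) {
    a <- array(rnorm(20^3), c(20, 20, 20))
    b <- 0.3 * a + array(rnorm(20^3), c(20, 20, 20))
    val <- nmi(a, b, bins = 16)
    expect_gte(val, 1); expect_lte(val, 2)
  }
})

test_that("NCCC is the overlap Pearson correlation", {
  v <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32), seed = 17,
                                    noiseSigma = 0.02))
  expect_equal(nccc(v, v), 1)
  neg <- Volume(-2.5 * volData(v) + 7)
  expect_equal(nccc(v, neg), -1)
  expect_equal(nccc(array(c(1, 2, 3, 4), c(2, 2, 1)),
                    array(c(2, 4, 6, 8), c(2, 2, 1))), 1)
  # invariant under positive affine rescaling
  resc <- Volume(3 * volData(v) + 100)
  expect_lt(abs(nccc(v, resc) - 1), 1e-12)
  expect_error(nccc(v, Volume(array(1, dim(v)))), "constant")
})
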