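test_that("diffusion leaves constants and zero-iteration inputs unchanged", {
  v <- Volume(array(3.7, c(12, 12, 12)))
  out <- diffuseVolume(v, diffusionConfig(iterations = 4, kappa = 1))
  expect_equal(volData(out), volData(v))

  v2 <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32), seed = 1,
                                     noiseSigma = 0.05))
  expect_identical(diffuseVolume(v2, diffusionConfig(iterations = 0)), v2)
})

test_that("a single explicit update matches the hand-evaluated scheme", {
  # 1x1x5 line [0,0,10,0,0], dt 0.1, rational conductance, kappa 5:
  # g((10/5)^2) = 1/5 at both centre-facing differences, so the centre
  # loses 0.1*(2+2) = 0.4 and each neighbour gains 0.1*2 = 0.2.
  v <- Volume(array(c(0, 0, 10, 0, 0), c(1, 1, 5)))
  out <- diffuseVolume(v, diffusionConfig(iterations = 1, timeStep = 0.1,
                                          kappa = 5))
  expect_equal(as.numeric(volData(out)), c(0, 0.2, 9.6, 0.2, 0),
               tolerance = 1e-12)
  expect_lt(abs(sum(volData(out)) - sum(volData(v))) / sum(volData(v)), 1e-10)
})

test_that("extremum principle and mass conservation hold across phantoms", {
  for (sd in 1:3) {
    v <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32), seed = sd,
                                      noiseSigma = 0.08))
    cfg <- diffusionConfig(iterations = 5,
                           conductance = if (sd == 2) "exponential" else "rational")
    out <- diffuseVolume(v, cfg)
    rng <- diff(intensityRange(v))
    expect_gte(min(volData(out)), intensityRange(v)[1] - 1e-9 * rng)
    expect_lte(max(volData(out)), intensityRange(v)[2] + 1e-9 * rng)
    expect_lt(abs(sum(volData(out)) - sum(volData(v))) / abs(sum(volData(v))),
              5 * 1e-8)
  }
})

test_that("with a huge kappa one step is one explicit heat step", {
  v <- Volume(volData(makeBrainPhantom(phantomSpec(shape = c(32, 32, 32),
                                                   seed = 7, noiseSigma = 0.1))))
  dt <- 1 / 6   # unit spacing: the explicit heat step is dt * laplacian
  out <- diffuseVolume(v, diffusionConfig(iterations = 1, timeStep = dt,
                                          kappa = 1e9))
  # independent explicit heat step with replicate boundaries
  u <- volData(v)
  lap <- 0
  for (ax in 1:3) {
    d <- dim(u)
    fwd <- pmin(seq_len(d[ax]) + 1L, d[ax])
    bwd <- pmax(seq_len(d[ax]) - 1L, 1L)
    takes <- function(idx) switch(ax, u[idx, , ], u[, idx, ], u[, , idx])
    lap <- lap + takes(fwd) + takes(bwd) - 2 * u
  }
  expect_lt(max(abs(volData(out) - (u + dt * lap))), 1e-6)
})

test_that("edges survive diffusion better than a matched Gaussian blur", {
  set.seed(31)
  a <- array(0, c(48, 24, 4))
  a[25:48, , ] <- 10
  a <- a + array(rnorm(length(a), sd = 0.8), dim(a))
  v <- Volume(a)
  dif <- diffuseVolume(v, diffusionConfig(iterations = 8, kappa = 4))
  # match the noise-variance reduction in a flat region with a Gaussian
  flat <- function(x) var(as.numeric(volData(x)[5:18, , ]))
  target <- flat(dif)
  sig <- uniroot(function(s) flat(smoothVolume(v, c(s, s, s))) - target,
                 c(0.2, 3))$root
  gau <- smoothVolume(v, c(sig, sig, sig))
  edgeGrad <- function(x) mean(abs(volData(x)[25, , ] - volData(x)[24, , ]))
  expect_gt(edgeGrad(dif), edgeGrad(gau))
})

test_that("unstable time steps are refused before any computation", {
  v <- Volume(array(rnorm(27), c(3, 3, 3)))
  expect_error(diffuseVolume(v, diffusionConfig(timeStep = 0.3)), "stability")
  expect_error(diffusionConfig(iterations = -1), "iterations")
  expect_error(diffusionConfig(timeStep = 0), "positive")
})
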