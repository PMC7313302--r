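test_that("perfect reconstruction and tight frame hold on varied inputs", {
  set.seed(11)
  phantoms <- list(
    constant = array(4.2, c(64, 64, 2)),
    blob = array(rep(blobSlice(64), 2), c(64, 64, 2)),
    noise = array(rnorm(64 * 64 * 2), c(64, 64, 2))
  )
  for (nm in names(phantoms)) {
    a <- phantoms[[nm]]
    dec <- curveletForward(a)
    rec <- curveletInverse(dec)
    rng <- max(diff(range(a)), 1)
    expect_lt(max(abs(volData(rec) - a)), 1e-8 * rng)
    expect_lt(abs(sum(bandEnergies(dec)) / sum(a^2) - 1), 1e-6)
  }
})

test_that("a constant image puts all energy in the coarsest band", {
  dec <- curveletForward(array(3, c(64, 64, 1)))
  en <- bandEnergies(dec)
  sc <- dec@meta$index$scale
  expect_lt(sum(en[sc > 1]), 1e-10 * sum(en))
})

test_that("a centred impulse excites every band", {
  a <- array(0, c(64, 64, 1))
  a[33, 33, 1] <- 1
  en <- bandEnergies(curveletForward(a))
  expect_true(all(en > 0))
})

test_that("the transform is linear", {
  set.seed(4)
  A <- array(rnorm(64 * 64), c(64, 64, 1))
  B <- array(rnorm(64 * 64), c(64, 64, 1))
  dA <- curveletForward(A); dB <- curveletForward(B)
  dC <- curveletForward(2.5 * A - 1.25 * B)
  for (k in seq_along(dA@bands)) {
    expect_lt(max(abs(dC@bands[[k]] - (2.5 * dA@bands[[k]] - 1.25 * dB@bands[[k]]))),
              1e-10 * max(1, max(abs(dC@bands[[k]]))))
  }
})

test_that("integer shifts leave band energies nearly unchanged", {
  a <- array(0, c(64, 64, 1))
  a[, , 1] <- blobSlice(64, cx = 0.5, cy = 0.5, s = 0.08)
  sh <- array(0, c(64, 64, 1))
  sh[, , 1] <- blobSlice(64, cx = 0.5 + 3 / 64, cy = 0.5, s = 0.08)
  e1 <- bandEnergies(curveletForward(a))
  e2 <- bandEnergies(curveletForward(sh))
  expect_true(all(abs(e2 - e1) / (e1 + 1e-12) < 0.05))
})

test_that("zeroing the finest scale removes high-frequency power", {
  set.seed(12)
  a <- array(rep(blobSlice(64), 1), c(64, 64, 1)) +
    array(rnorm(64 * 64, sd = 0.2), c(64, 64, 1))
  dec <- curveletForward(a)
  fine <- which(dec@meta$index$scale == dec@meta$scales)
  dec@bands[[fine]][] <- 0
  rec <- volData(curveletInverse(dec))[, , 1]
  hfPower <- function(img) {
    F <- fft(img)
    n <- nrow(img)
    k <- c(0:(n / 2), (n / 2 - 1):1) / (n / 2)
    R <- sqrt(outer(k^2, k^2, `+`))
    sum(Mod(F[R > 0.5])^2)
  }
  expect_lt(hfPower(rec), 0.5 * hfPower(a[, , 1]))
})

test_that("decompositions of same-shape images align band for band", {
  set.seed(5)
  a <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  b <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  da <- curveletForward(a); db <- curveletForward(b)
  pairs <- matchBands(da, db)
  expect_length(pairs, length(da@bands))
  for (k in seq_along(pairs))
    expect_identical(dim(pairs[[k]]$f), dim(pairs[[k]]$m))
  self <- matchBands(da, da)
  expect_identical(self[[2]]$f, self[[2]]$m)

  dc <- curveletForward(a, scales = 4)
  expect_error(matchBands(da, dc), "settings differ")
  dd <- curveletForward(array(rnorm(16 * 16), c(16, 16, 1)))
  expect_error(matchBands(da, dd), "shapes differ")
})

test_that("tampered bands and undersized images are refused", {
  a <- array(rnorm(32 * 32), c(32, 32, 1))
  dec <- curveletForward(a)
  dec@bands[[2]] <- dec@bands[[2]][-1, , , drop = FALSE]
  expect_error(curveletInverse(dec), "tampered")
  expect_error(curveletForward(array(0, c(16, 16, 1)), scales = 5),
               "too small")
  expect_error(curveletForward(a, orientations = 6), "multiple of 4")
})

test_that("frequency-domain moments equal spatial band statistics", {
  v <- makeBrainPhantom(phantomSpec(shape = c(48, 48, 32), seed = 3))
  w <- makeBrainPhantom(phantomSpec(shape = c(48, 48, 32), seed = 4,
                                    modality = "pet_like"))
  dv <- curveletForward(v); dw <- curveletForward(w)
  ref <- adaptiveMI(dv, dw)
  sys <- curvemi:::curveletSystem(48, 48, dv@meta$scales, 8L)
  moF <- curvemi:::bandMomentsFast(curvemi:::fft2Slices(volData(v)),
                                   curvemi:::fft2Slices(volData(w)), sys)
  expect_equal(curvemi:::amiFromMoments(moF), ref, tolerance = 1e-10)
})
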