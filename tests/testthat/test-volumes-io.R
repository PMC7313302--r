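test_that("NIfTI round trip preserves data, spacing and origin", {
  v <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32),
                                    spacing = c(1.25, 1.28, 4),
                                    seed = 5, noiseSigma = 0.05))
  v@origin <- c(-20, 5.5, 3.25)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  r <- readVolume(f)
  expect_identical(volData(r)[seq_along(volData(v))],
                   volData(v)[seq_along(volData(v))])
  expect_identical(spacing(r), c(1.25, 1.28, 4))
  expect_lt(max(abs(origin(r) - v@origin)), 1e-6)
  expect_equal(intensityRange(r), range(volData(v)))

  # overwriting replaces the content
  v2 <- Volume(array(7, c(4, 4, 4)))
  writeVolume(v2, f)
  expect_equal(dim(readVolume(f)), c(4L, 4L, 4L))
})

test_that("2D images are promoted to one-slice volumes", {
  img <- blobSlice(64)
  f <- tempfile(fileext = ".png")
  png::writePNG(img, f)
  v <- readVolume(f)
  expect_equal(dim(v), c(64L, 64L, 1L))
  expect_equal(spacing(v), c(1, 1, 1))

  ft <- tempfile(fileext = ".tif")
  tiff::writeTIFF(img, ft)
  vt <- readVolume(ft)
  expect_equal(dim(vt), c(64L, 64L, 1L))
})

test_that("volumes with non-finite voxels are rejected with a count", {
  a <- array(1, c(8, 8, 2))
  a[3, 4, 1] <- NaN
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a), f)
  expect_error(readVolume(f), "1 non-finite voxel")
  expect_error(Volume(array(c(1, Inf), c(2, 1, 1))), "non-finite")
})

test_that("resampling honours the identity and integer shifts", {
  v <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32), seed = 9,
                                    noiseSigma = 0.05))
  idn <- resampleVolume(v, affineParams(), interpolation = "nearest")
  expect_identical(as.numeric(volData(idn)), as.numeric(volData(v)))
  idt <- resampleVolume(v, affineParams())
  expect_lt(max(abs(volData(idt) - volData(v))),
            1e-12 * diff(intensityRange(v)))

  # +3 voxels along x, nearest: content shifted three columns
  sh <- resampleVolume(v, affineParams(translation = c(3 * spacing(v)[1], 0, 0)),
                       interpolation = "nearest")
  d <- dim(v)
  expect_identical(volData(sh)[1:(d[1] - 3), , ],
                   volData(v)[4:d[1], , ])
  expect_true(all(volData(sh)[(d[1] - 2):d[1], , ] == min(volData(v))))
})

test_that("half-voxel trilinear interpolation averages flanking values", {
  a <- array(2, c(10, 6, 6))
  a[6:10, , ] <- 8                           # step between columns 5 and 6
  v <- Volume(a)
  half <- resampleVolume(v, affineParams(translation = c(0.5, 0, 0)))
  expect_equal(volData(half)[5, 3, 3], 5)    # mean of 2 and 8
  expect_equal(volData(half)[2, 3, 3], 2)
  expect_equal(volData(half)[8, 3, 3], 8)
})

test_that("warp and inverse warp return close to the original", {
  v <- smoothVolume(makeBrainPhantom(phantomSpec(shape = c(48, 48, 48),
                                                 seed = 2, noiseSigma = 0)), 2.5)
  ctr <- origin(v) + (dim(v) - 1) / 2 * spacing(v)
  p <- affineParams(translation = c(3, -2, 1.5), rotation = c(4, -3, 6),
                    center = ctr)
  fwd <- resampleVolume(v, p)
  back <- resampleVolume(fwd, invertAffine(p))
  # interior: away from the band contaminated by out-of-field fill, which
  # for this transform reaches ~3 voxels in from the faces
  core <- 5:44
  err <- abs(volData(back)[core, core, core] - volData(v)[core, core, core])
  expect_lt(max(err), 0.02 * diff(intensityRange(v)))
})

test_that("singular transforms are refused", {
  v <- Volume(array(0, c(8, 8, 8)))
  m <- diag(4); m[1, 1] <- 0
  expect_error(resampleVolume(v, m), "singular")
})
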