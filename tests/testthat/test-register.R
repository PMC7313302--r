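# Fast registration checks at reduced size; the full-scale recovery study
# lives in test-acceptance.R.

smallControl <- function() registrationControl(maxIter = c(150L, 80L))

test_that("an already-aligned pair stays at the identity", {
  pr <- makePhantomPair(phantomSpec(shape = c(48, 48, 48), seed = 51))
  res <- registerVolumes(pr$fixed, pr$moving, control = smallControl())
  p <- resultParams(res)
  expect_lt(max(abs(p@translation)) / 2, 0.1)   # voxels
  expect_lt(max(abs(p@rotation)), 0.1)          # degrees
})

test_that("a known translation is recovered on a small phantom", {
  sp <- phantomSpec(shape = c(48, 48, 48), seed = 52,
                    transform = affineParams(translation = c(4, -3, 2) * 2))
  pr <- makePhantomPair(sp)
  res <- registerVolumes(pr$fixed, pr$moving, control = smallControl())
  p <- resultParams(res)
  expect_lt(max(abs(p@translation - pr$truth@translation)) / 2, 0.5)
  m <- resultMetrics(res)
  expect_gte(m[["nmiAfter"]], m[["nmiBefore"]])
  expect_gte(m[["ncccAfter"]], abs(m[["ncccBefore"]]) - 0.01)
})

test_that("registration is deterministic", {
  sp <- phantomSpec(shape = c(48, 48, 48), seed = 53,
                    transform = affineParams(translation = c(5, 2, -4),
                                             rotation = c(0, 0, 4)))
  pr <- makePhantomPair(sp)
  r1 <- registerVolumes(pr$fixed, pr$moving, control = smallControl())
  r2 <- registerVolumes(pr$fixed, pr$moving, control = smallControl())
  expect_identical(paramsToCheck <- c(resultParams(r1)@translation,
                                      resultParams(r1)@rotation,
                                      resultParams(r1)@scale,
                                      resultParams(r1)@shear),
                   c(resultParams(r2)@translation, resultParams(r2)@rotation,
                     resultParams(r2)@scale, resultParams(r2)@shear))
  expect_identical(volData(registeredVolume(r1))[1:100],
                   volData(registeredVolume(r2))[1:100])
})

test_that("the objective trace never decreases within a level", {
  sp <- phantomSpec(shape = c(48, 48, 48), seed = 54,
                    transform = affineParams(translation = c(6, 0, -2)))
  pr <- makePhantomPair(sp)
  res <- registerVolumes(pr$fixed, pr$moving, control = smallControl())
  tr <- resultTrace(res)
  for (lev in unique(tr$level)) {
    am <- tr$ami[tr$level == lev]
    if (length(am) > 1) expect_true(all(diff(am) >= -1e-12))
  }
})

test_that("non-overlapping initializations raise an initialization error", {
  pr <- makePhantomPair(phantomSpec(shape = c(32, 32, 32), seed = 55))
  far <- affineParams(translation = c(5000, 0, 0))
  expect_error(registerVolumes(pr$fixed, pr$moving, init = far),
               "do not overlap")
})

test_that("batch evaluation tabulates and summarizes correctly", {
  v <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32), seed = 56,
                                    noiseSigma = 0))
  ev <- evaluateBatch(list(list(fixed = v, moving = v)),
                      control = registrationControl(maxIter = c(40L, 20L)))
  expect_equal(ev$perPair$nmiAfter, 2, tolerance = 1e-9)
  expect_equal(unname(ev$means["nmiAfter"]), 2, tolerance = 1e-9)

  expect_equal(stats::fivenum(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))

  # means are the arithmetic means of the per-pair values
  prs <- lapply(57:59, function(sd) {
    pr <- makePhantomPair(phantomSpec(shape = c(32, 32, 32), seed = sd,
                                      transform = affineParams(translation = c(2, 0, 0))))
    list(fixed = pr$fixed, moving = pr$moving)
  })
  ev3 <- evaluateBatch(prs, control = registrationControl(maxIter = c(40L, 20L)))
  expect_equal(unname(ev3$means["ncccAfter"]), mean(ev3$perPair$ncccAfter),
               tolerance = 1e-12)
  expect_equal(ev3$fiveNumber$statistic,
               c("min", "q1", "median", "q3", "max"))

  # a failing pair is recorded, not fatal
  bad <- list(fixed = prs[[1]]$fixed,
              moving = Volume(array(1, c(32, 32, 32))))
  evb <- evaluateBatch(list(prs[[1]], bad),
                       control = registrationControl(maxIter = c(40L, 20L)))
  expect_equal(sum(evb$perPair$status == "ok"), 1)
})
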