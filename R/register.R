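#' Control settings for the hybrid registration pipeline
#'
#' @param diffusion a [DiffusionConfig-class] for denoising the moving
#'   image (step 1).
#' @param scales,orientations curvelet settings (NULL = per-level default).
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param stages which parameter groups are optimized at each level, from
#'   \code{"translation"} (3 dof), \code{"rigid"} (6), \code{"affine"}
#'   (12); a list as long as \code{pyramid}. The default runs the full
#'   staged search at the coarse levels and a refinement of all 12
#'   parameters at full resolution.
#' @param maxIter cap on line minimizations per pyramid level (scalar or
#'   one value per level).
#' @param tolObjective convergence threshold on AMI improvement (bits).
#' @param tolParam convergence threshold on parameter change (scaled
#'   units; 1 unit is about one voxel of boundary motion).
#' @param bins histogram bins for the reported NMI.
#' @param objectiveBands which curvelet bands enter the search objective:
#'   \code{"all"}, \code{"directional"} (wedge bands only), or
#'   \code{"mixed"} (mean of the two AMIs).
#' @param searchRange capture range of the search, relative to the initial
#'   transform: a list with \code{rotation} (degrees), \code{translation}
#'   (voxels), \code{scale} (multiplicative window) and \code{shear};
#'   candidates outside it are rejected. Misalignments beyond the capture
#'   range require a manual initial transform.
#' @param resolutionMatch smooth the sharper image of the pair at each
#'   pyramid level until its high-frequency power fraction matches the
#'   blurrier one's, so a sharp MRI and a low-resolution PET contribute
#'   comparable band structure; inert for same-resolution pairs.
#' @param regularization Gaussian prior pulling the affine part towards
#'   rigidity, as in SPM-style affine registration: a list with
#'   \code{logScaleSd} and \code{shearSd} (prior standard deviations of
#'   log-zooms and shears; anatomically plausible inter-scan variation)
#'   and \code{weight} (bits subtracted from the objective per squared
#'   standardized deviation). Discourages the zoom/shear combinations
#'   that map a smooth head outline onto its own rotated copy.
#' @return A named list of settings.
#' @export
registrationControl <- function(diffusion = diffusionConfig(),
                                scales = NULL, orientations = 8L,
                                pyramid = c(4L, 2L),
                                stages = NULL,
                                maxIter = c(200L, 160L),
                                tolObjective = 1e-5,
                                tolParam = 1e-3, bins = 64L,
                                objectiveBands = c("mixed", "all",
                                                   "directional"),
                                searchRange = list(rotation = 15,
                                                   translation = 20,
                                                   scale = c(0.85, 1.18),
                                                   shear = 0.2),
                                regularization = list(logScaleSd = 0.07,
                                                      shearSd = 0.07,
                                                      weight = 0.02),
                                resolutionMatch = TRUE) {
  if (is.null(stages)) {
    # full affine dof only at the finer levels: at the coarsest level the
    # smoothed head outline cannot disambiguate zoom/shear from rotation
    stages <- rep(list(c("rigid", "affine")), length(pyramid))
    stages[[1]] <- if (length(pyramid) > 1) c("translation", "rigid")
                   else c("translation", "rigid", "affine")
  }
  list(diffusion = diffusion, scales = scales,
       orientations = as.integer(orientations),
       pyramid = as.integer(pyramid), stages = stages,
       maxIter = rep_len(as.integer(maxIter), length(pyramid)),
       tolObjective = tolObjective,
       tolParam = tolParam, bins = as.integer(bins),
       objectiveBands = match.arg(objectiveBands),
       searchRange = searchRange, regularization = regularization,
       resolutionMatch = isTRUE(resolutionMatch))
}

# Fraction of non-DC spectral power above half-Nyquist, slice-wise: a
# one-number summary of apparent resolution.
highFreqFraction <- function(arr) {
  F <- fft2Slices(arr)
  P <- Re(F)^2 + Im(F)^2
  d <- dim(arr)
  kx <- c(0:floor(d[1] / 2), -(ceiling(d[1] / 2) - 1):-1) / (d[1] / 2)
  ky <- c(0:floor(d[2] / 2), -(ceiling(d[2] / 2) - 1):-1) / (d[2] / 2)
  R <- sqrt(outer(kx^2, ky^2, `+`))
  hi <- as.vector(R > 0.5)
  lo <- as.vector(R > 1e-9)
  Pm <- matrix(P, d[1] * d[2], d[3])
  hiP <- sum(Pm[hi, ])
  allP <- sum(Pm[lo, ])
  if (allP <= 0) 0 else hiP / allP
}

# Resolution matching: smooth the sharper image of a pair until its
# high-frequency power fraction matches the blurrier one's (as when a
# sharp MRI is paired with a low-resolution PET). Returns the pair.
matchResolution <- function(fixedL, movL) {
  hF <- highFreqFraction(fixedL@data)
  hM <- highFreqFraction(movL@data)
  smoothTo <- function(vol, target) {
    f <- function(s) highFreqFraction(smoothVolume(vol, c(s, s, s))@data) - target
    if (f(0) <= 0) return(vol)
    lo <- 0; hi <- 4
    for (i in 1:12) {                    # bisection on the smoothing sigma
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    smoothVolume(vol, rep((lo + hi) / 2, 3))
  }
  if (hF > hM * 1.05) fixedL <- smoothTo(fixedL, hM)
  else if (hM > hF * 1.05) movL <- smoothTo(movL, hF)
  list(fixedL = fixedL, movL = movL)
}

paramsToVec <- function(p) c(p@translation, p@rotation, p@scale, p@shear)
vecToParams <- function(v, center) {
  affineParams(translation = v[1:3], rotation = v[4:6], scale = v[7:9],
               shear = v[10:12], center = center)
}

stageIndices <- function(stage) {
  switch(stage, translation = 1:3, rigid = 1:6, affine = 1:12,
         stop("unknown stage: ", stage))
}

# scaled parameter units: 1 unit moves the head boundary by ~1 voxel
paramUnits <- function(spacingL, halfExtent) {
  vox <- mean(spacingL)
  ang <- atan2(vox, halfExtent) * 180 / pi
  c(spacingL, rep(ang, 3), rep(vox / halfExtent, 6))
}

# deterministic bracket + parabolic line search; returns best step and value
lineSearch <- function(fn, f0, step = 1, maxExpand = 4L) {
  evalAt <- function(a) fn(a)
  best <- list(a = 0, f = f0)
  triple <- NULL
  for (s in c(step, -step)) {
    f1 <- evalAt(s)
    if (f1 < best$f) {
      a0 <- 0; f0c <- best$f; a1 <- s
      best <- list(a = s, f = f1)
      for (e in seq_len(maxExpand)) {   # expand while improving
        a2 <- a1 * 2
        f2 <- evalAt(a2)
        if (f2 < best$f) {
          a0 <- a1; f0c <- f1; f1 <- f2; a1 <- a2
          best <- list(a = a2, f = f2)
        } else {
          triple <- list(a = c(a0, a1, a2), f = c(f0c, f1, f2))
          break
        }
      }
      if (is.null(triple)) return(best)
      break
    }
  }
  if (is.null(triple)) {                 # both directions worse: refine inward
    s <- step / 2
    for (e in seq_len(3L)) {
      fs <- evalAt(s); fsm <- evalAt(-s)
      if (fs < best$f) best <- list(a = s, f = fs)
      if (fsm < best$f) best <- list(a = -s, f = fsm)
      if (best$a != 0) break
      s <- s / 2
    }
    return(best)
  }
  # one parabolic refinement through the bracketing triple
  a <- triple$a; f <- triple$f
  den <- (a[2] - a[1]) * (f[2] - f[3]) - (a[2] - a[3]) * (f[2] - f[1])
  if (abs(den) > 1e-30) {
    num <- (a[2] - a[1])^2 * (f[2] - f[3]) - (a[2] - a[3])^2 * (f[2] - f[1])
    cand <- a[2] - 0.5 * num / den
    if (is.finite(cand) && cand > min(a) && cand < max(a)) {
      fc <- evalAt(cand)
      if (fc < best$f) best <- list(a = cand, f = fc)
    }
  }
  best
}

# Powell-style direction-set minimization of fn over the active indices of
# the scaled parameter vector x0. Returns x, f, iterations, converged.
directionSetSearch <- function(fn, x0, active, maxIter, tolF, tolX,
                               step = 1) {
  x <- x0
  f <- fn(x)
  dirs <- lapply(active, function(i) {
    d <- numeric(length(x0)); d[i] <- 1; d
  })
  iter <- 0L
  converged <- FALSE
  stepFloor <- 0.1
  repeat {
    xStart <- x; fStart <- f
    for (d in dirs) {
      if (iter >= maxIter) break
      iter <- iter + 1L
      ls <- lineSearch(function(a) fn(x + a * d), f, step = step)
      if (ls$f < f) { x <- x + ls$a * d; f <- ls$f }
    }
    # Powell extension: move along the cycle's net displacement
    if (iter < maxIter && any(x != xStart)) {
      iter <- iter + 1L
      d <- x - xStart
      ls <- lineSearch(function(a) fn(x + a * d), f, step = 1)
      if (ls$f < f) { x <- x + ls$a * d; f <- ls$f }
    }
    dx <- max(abs(x - xStart))
    if (fStart - f < tolF && dx < tolX) {
      # only accept convergence once the step has been refined
      if (step <= stepFloor) { converged <- TRUE; break }
      step <- step / 4
    } else {
      step <- max(step * 0.5, stepFloor)
    }
    if (iter >= maxIter) break
  }
  list(x = x, f = f, iterations = iter, converged = converged)
}

#' Register a moving volume to a fixed volume
#'
#' The five-step hybrid pipeline: (1) anisotropic diffusion denoising of
#' the moving image; (2) an initial affine transform (identity unless
#' \code{init} is given); (3) slice-wise curvelet decomposition of the
#' fixed image and of the currently resampled moving image; (4)
#' maximization of the adaptive (energy-weighted Gaussian band) mutual
#' information over the 12 affine parameters by a derivative-free
#' direction-set search within a coarse-to-fine pyramid, recomputing the
#' moving image's decomposition after every candidate transform
#' (transform-then-decompose); (5) a final resampling of the original,
#' undiffused moving image onto the fixed grid at cubic interpolation.
#' Deterministic given inputs and control settings.
#'
#' @param fixed,moving [Volume-class] objects.
#' @param init optional initial [AffineParams-class] (its centre is
#'   ignored; rotation/scale act about the fixed image's world centre).
#' @param control see [registrationControl()].
#' @param seed integer recorded in the result (the optimizer itself is
#'   deterministic; the seed governs only stochastic phantom generation
#'   upstream).
#' @param verbose print per-level objective values.
#' @return A [RegistrationResult-class].
#' @examples
#' pr <- makePhantomPair(phantomSpec(shape = c(48, 48, 48),
#'   transform = affineParams(translation = c(6, -4, 2))))
#' \donttest{
#' res <- registerVolumes(pr$fixed, pr$moving)
#' resultParams(res)
#' }
#' @export
registerVolumes <- function(fixed, moving, init = NULL,
                            control = registrationControl(), seed = 1L,
                            verbose = FALSE) {
  stopifnot(is(fixed, "Volume"), is(moving, "Volume"))
  center <- volumeCenter(fixed)
  p0 <- if (is.null(init)) affineParams(center = center)
  else affineParams(init@translation, init@rotation, init@scale,
                    init@shear, center = center)
  # step 1: denoise the moving image only
  movingD <- diffuseVolume(moving, control$diffusion)
  # step 2: initial transform; check the fields of view overlap
  init0 <- resampleVolume(movingD, affineMatrix(p0), reference = fixed)
  if (!any(attr(init0@data, "inside")))
    stop("initialization error: fixed and moving fields of view do not overlap")

  vec <- paramsToVec(p0)
  trace <- list()
  converged <- TRUE
  for (li in seq_along(control$pyramid)) {
    fac <- control$pyramid[li]
    fixedL <- downsampleVolume(fixed, fac)
    movL <- downsampleVolume(movingD, fac)
    if (isTRUE(control$resolutionMatch)) {
      rm <- matchResolution(fixedL, movL)
      fixedL <- rm$fixedL; movL <- rm$movL
    }
    dL <- dim(fixedL@data)
    scalesL <- if (is.null(control$scales)) defaultScales(dL[1], dL[2])
    else control$scales
    sys <- curveletSystem(dL[1], dL[2], scalesL, control$orientations)
    FFixed <- fft2Slices(fixedL@data)
    units <- paramUnits(fixedL@spacing,
                        max(dim(fixedL@data) * fixedL@spacing) / 2)
    # Band selection for the search objective. Directional wedge bands
    # locate edges regardless of contrast polarity (robust when tissue
    # contrasts are permuted between modalities); the isotropic bands
    # anchor the global pose. "mixed" averages the two AMIs.
    directional <- vapply(sys$wins, function(w) w$l > 0L, TRUE)
    mode <- control$objectiveBands
    sr <- control$searchRange
    vox <- mean(fixedL@spacing)
    p0v <- paramsToVec(p0)
    inRange <- function(v) {
      all(abs(v[1:3] - p0v[1:3]) <= sr$translation * vox + 1e-9) &&
        all(abs(v[4:6] - p0v[4:6]) <= sr$rotation + 1e-9) &&
        all(v[7:9] >= p0v[7:9] * sr$scale[1] - 1e-9) &&
        all(v[7:9] <= p0v[7:9] * sr$scale[2] + 1e-9) &&
        all(abs(v[10:12] - p0v[10:12]) <= sr$shear + 1e-9)
    }
    reg <- control$regularization
    rigidityPenalty <- function(v) {
      reg$weight * (sum((log(v[7:9]) / reg$logScaleSd)^2) +
                      sum((v[10:12] / reg$shearSd)^2))
    }
    # raw fast path: no S4 construction inside the search loop
    srcArr <- movL@data; srcDim <- dim(srcArr)
    srcSp <- movL@spacing; srcOr <- movL@origin
    fillVal <- movL@range[1]
    refDim <- dim(fixedL@data); refSp <- fixedL@spacing
    refOr <- fixedL@origin
    objective <- function(xs) {
      v <- vec + xs * units
      if (!inRange(v)) return(Inf)
      M <- affineMatrixCore(v[1:3], v[4:6], v[7:9], v[10:12], center)
      res <- .resampleCpp(srcArr, srcDim, srcSp, srcOr,
                          refDim, refSp, refOr, M, 1L, fillVal)
      FMov <- fft2Slices(array(res$data, refDim))
      mo <- bandMomentsFast(FFixed, FMov, sys)
      ami <- switch(mode,
                    all = amiFromMoments(mo),
                    directional = amiFromMoments(mo[directional]),
                    mixed = 0.5 * (amiFromMoments(mo) +
                                     amiFromMoments(mo[directional])))
      rigidityPenalty(v) - ami
    }
    x <- numeric(12)
    levConverged <- TRUE
    iterUsed <- 0L
    for (stage in control$stages[[li]]) {
      act <- stageIndices(stage)
      fit <- directionSetSearch(objective, x, act,
                                maxIter = control$maxIter[li] - iterUsed,
                                tolF = control$tolObjective,
                                tolX = control$tolParam,
                                step = if (li == 1L) 1 else 0.5)
      x <- fit$x
      iterUsed <- iterUsed + fit$iterations
      levConverged <- fit$converged
      trace[[length(trace) + 1]] <-
        data.frame(level = fac, stage = stage, iterations = fit$iterations,
                   ami = -fit$f)
      if (verbose)
        message(sprintf("level x%d %-11s AMI %.5f bits (%d line searches)",
                        fac, stage, -fit$f, fit$iterations))
    }
    vec <- vec + x * units
    converged <- converged && levConverged
  }
  pOpt <- vecToParams(vec, center)
  M <- affineMatrix(pOpt)
  # step 5: resample the original (undiffused) moving image, cubic
  registered <- resampleVolume(moving, M, reference = fixed,
                               interpolation = "cubic")
  maskAfter <- attr(registered@data, "inside")
  maskBefore <- attr(init0@data, "inside")
  before <- resampleVolume(moving, affineMatrix(p0), reference = fixed)
  decF <- curveletForward(fixed, scales = control$scales,
                          orientations = control$orientations)
  metrics <- c(
    nmiBefore = nmi(fixed, before, bins = control$bins, mask = maskBefore),
    nmiAfter = nmi(fixed, registered, bins = control$bins, mask = maskAfter),
    ncccBefore = nccc(fixed, before, mask = maskBefore),
    ncccAfter = nccc(fixed, registered, mask = maskAfter),
    amiBefore = adaptiveMI(decF, curveletForward(before,
      scales = control$scales, orientations = control$orientations)),
    amiAfter = adaptiveMI(decF, curveletForward(registered,
      scales = control$scales, orientations = control$orientations)))
  new("RegistrationResult", params = pOpt, matrix = M,
      trace = do.call(rbind, trace), registered = registered,
      metrics = metrics, converged = converged, seed = as.integer(seed))
}

#' Register and score a batch of volume pairs
#'
#' Runs [registerVolumes()] on each pair and tabulates NMI, NCCC and AMI
#' before and after registration, with column means and five-number
#' summaries (min, lower hinge, median, upper hinge, max) for
#' boxplot-style reporting. A pair that fails is recorded with its error
#' message rather than aborting the batch.
#'
#' @param pairs a list; each element a list with \code{fixed} and
#'   \code{moving} [Volume-class] objects.
#' @param control see [registrationControl()].
#' @return A list: \code{perPair} (data.frame of metrics and status),
#'   \code{means} (named numeric), \code{fiveNumber} (data.frame, one row
#'   per statistic).
#' @export
evaluateBatch <- function(pairs, control = registrationControl()) {
  stopifnot(length(pairs) >= 1)
  cols <- c("nmiBefore", "nmiAfter", "ncccBefore", "ncccAfter",
            "amiBefore", "amiAfter")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    out <- tryCatch({
      res <- registerVolumes(p$fixed, p$moving, control = control)
      c(as.list(res@metrics[cols]),
        list(converged = res@converged, status = "ok"))
    }, error = function(e) {
      c(setNames(as.list(rep(NA_real_, length(cols))), cols),
        list(converged = FALSE, status = conditionMessage(e)))
    })
    cbind(data.frame(pair = i), as.data.frame(out, stringsAsFactors = FALSE))
  })
  perPair <- do.call(rbind, rows)
  ok <- perPair$status == "ok"
  means <- colMeans(perPair[ok, cols, drop = FALSE])
  fn <- vapply(cols, function(cn) stats::fivenum(perPair[ok, cn]),
               numeric(5))
  fiveNumber <- data.frame(statistic = c("min", "q1", "median", "q3", "max"),
                           fn, row.names = NULL, check.names = FALSE)
  list(perPair = perPair, means = means, fiveNumber = fiveNumber)
}
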