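# Deterministic piecewise-smooth "brain" phantoms: nested ellipsoids
# (skull shell, gray matter, white matter, ventricles) plus two fixed
# off-centre lesion blobs that break the head's symmetry so rotations are
# identifiable. Tissue membership is evaluated analytically at arbitrary
# world points, so a misaligned phantom is generated without interpolation
# error. Tissue intensity tables are frozen; the seed governs noise and
# the bias field only, making phantoms bit-reproducible.

.tissueTables <- list(
  # labels: 1 skull, 2 gray, 3 white, 4 csf, 5 lesion; background 0
  mri_t1   = c(0, 30, 60, 90, 15, 110),
  mri_pd   = c(0, 20, 85, 70, 95, 60),
  pet_like = c(0, 5, 90, 40, 10, 120),
  ct_like  = c(0, 100, 35, 30, 10, 45)
)

#' Describe a synthetic brain phantom
#'
#' @param shape voxels per axis (each >= 32); default 96^3.
#' @param spacing voxel size in mm; default isotropic 2 mm (a ~150 mm
#'   head fits the field of view with margin for misalignments). RIRE-like
#'   anisotropic spacings such as \code{c(1.25, 1.28, 4)} are honoured
#'   end-to-end.
#' @param modality "mri_t1" (default), "mri_pd", "pet_like" (blurred,
#'   metabolic contrast) or "ct_like" (high skull contrast).
#' @param transform ground-truth misalignment as an [AffineParams-class];
#'   identity by default.
#' @param noiseSigma additive Gaussian noise as a fraction of the
#'   intensity range (default 0.02).
#' @param biasField add a smooth low-order multiplicative bias field.
#' @param seed integer; fully determines the generated data.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(96, 96, 96), spacing = c(2, 2, 2),
                        modality = "mri_t1", transform = affineParams(),
                        noiseSigma = 0.02, biasField = FALSE, seed = 1L) {
  new("PhantomSpec", shape = as.integer(rep_len(shape, 3L)),
      spacing = as.numeric(rep_len(spacing, 3L)), modality = modality,
      transform = transform, noiseSigma = as.numeric(noiseSigma),
      biasField = isTRUE(biasField), seed = as.integer(seed))
}

withPhantomSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# tissue label at head-frame coordinates (mm, origin at head centre)
phantomLabels <- function(x, y, z, rb) {
  inEll <- function(cx, cy, cz, ax, ay, az)
    ((x - cx) / ax)^2 + ((y - cy) / ay)^2 + ((z - cz) / az)^2 <= 1
  A <- rb * c(0.85, 1.0, 0.8)                       # brain envelope
  lab <- integer(length(x))
  lab[inEll(0, 0, 0, A[1] * 1.18, A[2] * 1.18, A[3] * 1.18)] <- 1L  # skull
  lab[inEll(0, 0, 0, A[1] * 1.08, A[2] * 1.08, A[3] * 1.08)] <- 0L  # csf gap
  lab[inEll(0, 0, 0, A[1], A[2], A[3])] <- 2L                        # gray
  lab[inEll(0, 0, 0, A[1] * 0.72, A[2] * 0.78, A[3] * 0.72)] <- 3L   # white
  # lateral ventricles, deliberately unequal (left larger)
  lab[inEll(-0.16 * rb, 0.10 * rb, 0.05 * rb,
            0.11 * rb, 0.26 * rb, 0.13 * rb)] <- 4L
  lab[inEll(0.16 * rb, 0.08 * rb, 0.05 * rb,
            0.08 * rb, 0.20 * rb, 0.10 * rb)] <- 4L
  # fixed asymmetric blobs (orientation anchors)
  lab[inEll(0.34 * rb, -0.28 * rb, 0.18 * rb,
            0.12 * rb, 0.10 * rb, 0.11 * rb)] <- 5L
  lab[inEll(-0.30 * rb, 0.30 * rb, -0.24 * rb,
            0.09 * rb, 0.09 * rb, 0.10 * rb)] <- 5L
  lab
}

# intensities of a phantom evaluated at the voxel centres of `spec`'s grid
# after mapping world points through `worldMap` (a 4x4 matrix or NULL)
phantomIntensities <- function(spec, modality, worldMap = NULL,
                               gamma = 1) {
  d <- spec@shape; sp <- spec@spacing
  ctr <- (d - 1) / 2 * sp
  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  X <- rep(gx, times = d[2] * d[3])
  Y <- rep(rep(gy, each = d[1]), times = d[3])
  Z <- rep(gz, each = d[1] * d[2])
  if (!is.null(worldMap)) {
    W <- worldMap
    Xn <- W[1, 1] * X + W[1, 2] * Y + W[1, 3] * Z + W[1, 4]
    Yn <- W[2, 1] * X + W[2, 2] * Y + W[2, 3] * Z + W[2, 4]
    Zn <- W[3, 1] * X + W[3, 2] * Y + W[3, 3] * Z + W[3, 4]
    X <- Xn; Y <- Yn; Z <- Zn
  }
  rb <- 0.4 * min(d * sp)
  lab <- phantomLabels(X - ctr[1], Y - ctr[2], Z - ctr[3], rb)
  tab <- .tissueTables[[modality]]
  v <- array(tab[lab + 1L], d)
  if (modality == "pet_like") {
    v <- array(.gaussSmoothCpp(as.numeric(v), d, rep(2, 3)), d)
  }
  if (gamma != 1) {
    mx <- max(v)
    if (mx > 0) v <- mx * (v / mx)^gamma
  }
  list(data = v, labels = array(lab, d))
}

#' Generate a synthetic brain phantom
#'
#' Deterministic nested-ellipsoid head with modality-specific tissue
#' intensities; PET-like phantoms are additionally blurred to emulate
#' coarse resolution. Gaussian noise (\code{noiseSigma} of the intensity
#' range) and an optional smooth multiplicative bias field are added under
#' the spec's seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [Volume-class] with origin 0 and the spec's spacing.
#' @examples
#' v <- makeBrainPhantom(phantomSpec(shape = c(48, 48, 32), seed = 7))
#' @export
makeBrainPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  gen <- phantomIntensities(spec, spec@modality)
  v <- gen$data
  withPhantomSeed(spec@seed, {
    if (spec@biasField) v <- v * biasFieldArray(spec@shape)
    if (spec@noiseSigma > 0) {
      rng <- diff(range(v))
      v <- v + array(rnorm(length(v), sd = spec@noiseSigma * rng), dim(v))
    }
  })
  Volume(v, spacing = spec@spacing, origin = c(0, 0, 0))
}

biasFieldArray <- function(d) {
  cf <- runif(6, -0.15, 0.15)
  x <- seq(-1, 1, length.out = d[1])
  y <- seq(-1, 1, length.out = d[2])
  z <- seq(-1, 1, length.out = d[3])
  X <- rep(x, times = d[2] * d[3])
  Y <- rep(rep(y, each = d[1]), times = d[3])
  Z <- rep(z, each = d[1] * d[2])
  array(1 + cf[1] * X + cf[2] * Y + cf[3] * Z +
          cf[4] * X * Y + cf[5] * X^2 + cf[6] * Z^2, d)
}

#' Generate a fixed/moving phantom pair with known ground truth
#'
#' The fixed image is the phantom at identity. The moving image is the
#' same head observed under the ground-truth misalignment: its tissue
#' membership is evaluated analytically at inverse-transformed voxel
#' centres (equivalent to resampling the continuous phantom, with no
#' interpolation error), so that registering moving to fixed should
#' recover exactly \code{spec@transform}. Multimodal pairs re-map the
#' moving image to PET-like contrast (tissue-wise mean swap), blur it and
#' bend it with a smooth gamma curve; both images receive independent
#' noise realizations.
#'
#' @param spec a [PhantomSpec-class]; \code{spec@transform} is the ground
#'   truth (rotation/scale centre taken at the volume centre when unset).
#' @param multimodal logical; FALSE gives a monomodal (same-contrast) pair.
#' @return A list with elements \code{fixed}, \code{moving} (both
#'   [Volume-class]) and \code{truth} ([AffineParams-class]).
#' @examples
#' pr <- makePhantomPair(phantomSpec(shape = c(48, 48, 48),
#'   transform = affineParams(translation = c(6, 0, 0))))
#' @export
makePhantomPair <- function(spec, multimodal = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  fixed <- makeBrainPhantom(spec)
  truth <- spec@transform
  if (all(truth@center == 0))
    truth <- affineParams(truth@translation, truth@rotation, truth@scale,
                          truth@shear, center = volumeCenter(fixed))
  Tinv <- invertAffine(affineMatrix(truth))
  movModality <- if (multimodal) "pet_like" else spec@modality
  gen <- phantomIntensities(spec, movModality, worldMap = Tinv,
                            gamma = if (multimodal) 0.7 else 1)
  # guard: the transform must keep most of the head in the field of view
  nFix <- sum(phantomIntensities(spec, spec@modality)$labels > 0)
  nMov <- sum(gen$labels > 0)
  if (nMov < 0.5 * nFix)
    stop("transform pushes the head mostly out of the field of view")
  v <- gen$data
  withPhantomSeed(spec@seed + 1000L, {
    if (spec@biasField) v <- v * biasFieldArray(spec@shape)
    if (spec@noiseSigma > 0) {
      rng <- diff(range(v))
      v <- v + array(rnorm(length(v), sd = spec@noiseSigma * rng), dim(v))
    }
  })
  moving <- Volume(v, spacing = spec@spacing, origin = c(0, 0, 0))
  list(fixed = fixed, moving = moving, truth = truth)
}

#' Draw a random ground-truth misalignment
#'
#' Uniform translation up to \code{maxTransVox} voxels per axis, Euler
#' rotations up to \code{maxRotDeg} degrees, per-axis scale in
#' \code{scaleRange}; no shear. Deterministic in \code{seed}.
#'
#' @param seed integer.
#' @param spacing voxel size (mm) used to convert voxel translations to mm.
#' @param center rotation/scale centre (mm).
#' @param maxTransVox,maxRotDeg,scaleRange misalignment ranges.
#' @return An [AffineParams-class].
#' @export
randomAffine <- function(seed, spacing = c(2, 2, 2), center = c(0, 0, 0),
                         maxTransVox = 8, maxRotDeg = 10,
                         scaleRange = c(0.95, 1.05)) {
  withPhantomSeed(seed, {
    affineParams(
      translation = runif(3, -maxTransVox, maxTransVox) * spacing,
      rotation = runif(3, -maxRotDeg, maxRotDeg),
      scale = runif(3, scaleRange[1], scaleRange[2]),
      center = center)
  })
}
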