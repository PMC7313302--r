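#' @import methods
#' @importFrom stats fft mvfft rnorm runif quantile sd median optimize setNames
#' @useDynLib curvemi, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Volume: a 3D scalar image on a regular grid
#'
#' A 3D scalar grid with per-axis voxel spacing (mm) and the world-space
#' position of the centre of voxel (1,1,1). 2D images are stored as
#' single-slice volumes. World coordinates are axis-aligned:
#' \code{world = origin + (index - 1) * spacing} (RAS; any oblique
#' orientation is normalized away at load).
#'
#' @slot data numeric 3D array of intensities; no non-finite values.
#' @slot spacing numeric(3), voxel size in mm per axis, strictly positive.
#' @slot origin numeric(3), world coordinates (mm) of the first voxel centre.
#' @slot range numeric(2), cached (min, max) of \code{data}.
#'
#' @seealso [readVolume()], [writeVolume()], [resampleVolume()]
#' @export
setClass("Volume", representation(
  data = "array",
  spacing = "numeric",
  origin = "numeric",
  range = "numeric"
))

setValidity("Volume", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive values (mm)")
  if (length(object@origin) != 3L)
    msgs <- c(msgs, "origin must have 3 components (mm)")
  nbad <- sum(!is.finite(object@data))
  if (nbad > 0)
    msgs <- c(msgs, sprintf("data contains %d non-finite voxel(s)", nbad))
  else if (!isTRUE(all.equal(object@range, range(object@data), tolerance = 0)))
    msgs <- c(msgs, "cached intensity range does not match data")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Volume
#'
#' @param data numeric array (2D arrays are promoted to one-slice 3D).
#' @param spacing voxel size in mm per axis.
#' @param origin world position (mm) of the first voxel centre.
#' @return A [Volume-class] object.
#' @examples
#' v <- Volume(array(0, c(8, 8, 4)), spacing = c(1.25, 1.28, 4))
#' spacing(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), range = suppressWarnings(range(data)))
}

#' AffineParams: 12-parameter affine transform
#'
#' Translation (mm), rotation (degrees, Euler angles applied in x, y, z
#' order and composed as Rz Ry Rx), per-axis scale factors, shears
#' (upper-triangular unit-diagonal entries xy, xz, yz), and the world-space
#' centre (mm) about which rotation/scale/shear act. The derived 4x4
#' homogeneous matrix maps fixed-image world points into moving-image world
#' space (backward warping).
#'
#' @slot translation numeric(3), mm.
#' @slot rotation numeric(3), degrees.
#' @slot scale numeric(3), dimensionless, strictly positive.
#' @slot shear numeric(3), dimensionless (xy, xz, yz).
#' @slot center numeric(3), mm.
#' @seealso [affineParams()], [affineMatrix()]
#' @export
setClass("AffineParams", representation(
  translation = "numeric",
  rotation = "numeric",
  scale = "numeric",
  shear = "numeric",
  center = "numeric"
))

setValidity("AffineParams", function(object) {
  msgs <- character()
  for (s in c("translation", "rotation", "scale", "shear", "center")) {
    v <- slot(object, s)
    if (length(v) != 3L || any(!is.finite(v)))
      msgs <- c(msgs, sprintf("%s must be 3 finite values", s))
  }
  if (length(object@scale) == 3L && any(object@scale <= 0))
    msgs <- c(msgs, "scale components must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' CurveletDecomposition: multiscale, multidirectional coefficient bands
#'
#' Coefficient bands of a slice-wise 2D curvelet decomposition of a volume,
#' indexed by (scale, orientation) with the slice index stacked as the third
#' array dimension. Bands are real (antipodal frequency wedges are
#' symmetrized). The frequency-wedge windows and crop boxes retained in
#' \code{meta} make the transform exactly invertible.
#'
#' @slot bands list of numeric 3D arrays, one per (scale, orientation).
#' @slot meta list: per-band wedge definitions (\code{windows}), image
#'   \code{dim}, \code{scales}, \code{orientations} per scale, band index
#'   table (\code{index}).
#' @seealso [curveletForward()], [curveletInverse()], [matchBands()]
#' @export
setClass("CurveletDecomposition", representation(
  bands = "list",
  meta = "list"
))

#' BandStats: bivariate Gaussian ML fit of a matched band pair
#'
#' Maximum-likelihood estimates (sample means, biased 1/n variances,
#' Pearson correlation) for a bivariate Gaussian model of a matched pair of
#' curvelet coefficient bands, plus the pair's share of total coefficient
#' energy used as its adaptive-MI weight.
#'
#' @slot meanF,meanM means of the fixed/moving band coefficients.
#' @slot varF,varM biased (1/n) variances.
#' @slot rho Pearson correlation in [-1, 1]; 0 when degenerate.
#' @slot n sample count.
#' @slot weight non-negative energy share (normalized over bands).
#' @slot degenerate flag: TRUE when either band has zero variance.
#' @seealso [fitBandStats()], [bandMI()]
#' @export
setClass("BandStats", representation(
  meanF = "numeric", meanM = "numeric",
  varF = "numeric", varM = "numeric",
  rho = "numeric", n = "numeric",
  weight = "numeric", degenerate = "logical"
))

setValidity("BandStats", function(object) {
  msgs <- character()
  if (abs(object@rho) > 1 + 1e-12) msgs <- c(msgs, "|rho| must be <= 1")
  if (object@varF < 0 || object@varM < 0) msgs <- c(msgs, "variances must be >= 0")
  if (object@weight < 0) msgs <- c(msgs, "weight must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' JointHistogram: 2D intensity histogram of an image pair
#'
#' Counts over a bins x bins grid of intensity pairs, the bin edges used for
#' each image, and the number of voxels tallied. Marginals obtained by
#' summation are exactly consistent with the joint.
#'
#' @slot counts numeric matrix, non-negative.
#' @slot edgesF,edgesM numeric bin edges per image.
#' @slot n total voxel count.
#' @seealso [jointHistogram()], [nmi()]
#' @export
setClass("JointHistogram", representation(
  counts = "matrix", edgesF = "numeric", edgesM = "numeric", n = "numeric"
))

#' DiffusionConfig: Perona-Malik anisotropic diffusion settings
#'
#' @slot iterations non-negative integer; 0 is the identity.
#' @slot timeStep explicit-scheme step; must satisfy the stability bound
#'   timeStep <= 1/(2 D) for D spatial dimensions.
#' @slot kappa conductance edge threshold in intensity units; NA means
#'   estimate from the data (90th percentile of gradient magnitudes).
#' @slot conductance "rational" (1/(1+x^2)) or "exponential" (exp(-x^2)).
#' @seealso [diffusionConfig()], [diffuseVolume()]
#' @export
setClass("DiffusionConfig", representation(
  iterations = "integer", timeStep = "numeric",
  kappa = "numeric", conductance = "character"
))

#' RegistrationResult: output of the hybrid registration pipeline
#'
#' @slot params estimated [AffineParams-class].
#' @slot matrix derived 4x4 homogeneous matrix.
#' @slot trace data.frame of (level, iteration, ami) at accepted steps.
#' @slot registered moving volume resampled onto the fixed grid.
#' @slot metrics named numeric: nmiBefore, nmiAfter, ncccBefore, ncccAfter,
#'   amiBefore, amiAfter.
#' @slot converged logical.
#' @slot seed integer seed recorded for reproducibility.
#' @seealso [registerVolumes()]
#' @export
setClass("RegistrationResult", representation(
  params = "AffineParams", matrix = "matrix", trace = "data.frame",
  registered = "Volume", metrics = "numeric", converged = "logical",
  seed = "integer"
))

#' PhantomSpec: synthetic brain phantom description
#'
#' Everything needed to deterministically generate a phantom pair: grid
#' shape and spacing, modality, the ground-truth misalignment, noise level
#' (as a fraction of the intensity range), bias-field flag, and the seed
#' that fully determines the output.
#'
#' @slot shape integer(3), voxels per axis (each >= 32).
#' @slot spacing numeric(3), mm.
#' @slot modality one of "mri_t1", "mri_pd", "pet_like", "ct_like".
#' @slot transform ground-truth [AffineParams-class].
#' @slot noiseSigma numeric, fraction of the intensity range.
#' @slot biasField logical.
#' @slot seed integer.
#' @seealso [phantomSpec()], [makeBrainPhantom()], [makePhantomPair()]
#' @export
setClass("PhantomSpec", representation(
  shape = "integer", spacing = "numeric", modality = "character",
  transform = "AffineParams", noiseSigma = "numeric",
  biasField = "logical", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@shape) != 3L || any(object@shape < 32L))
    msgs <- c(msgs, "shape must be 3 integers, each >= 32")
  if (!object@modality %in% c("mri_t1", "mri_pd", "pet_like", "ct_like"))
    msgs <- c(msgs, "unknown modality")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (length(msgs)) msgs else TRUE
})
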