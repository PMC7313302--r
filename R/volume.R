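#' Read a volume from disk
#'
#' Reads NIfTI-1 (\code{.nii}/\code{.nii.gz}) volumes, or 2D PNG/TIFF
#' images which are promoted to one-slice volumes with spacing
#' (1, 1, 1) mm. Spacing is taken from the NIfTI header (column norms of
#' the stored transform, falling back to \code{pixdim}) and the origin from
#' its translation; any oblique orientation is normalized to an
#' axis-aligned RAS grid. Volumes containing non-finite voxels are
#' rejected.
#'
#' @param path file path.
#' @return A [Volume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]          # first channel
    a <- t(a)[, rev(seq_len(nrow(a))), drop = FALSE] # row-major image -> x,y grid
    return(Volume(array(a, c(dim(a), 1L))))
  }
  if (grepl("\\.tiff?$", low)) {
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    a <- t(a)[, rev(seq_len(nrow(a))), drop = FALSE]
    return(Volume(array(a, c(dim(a), 1L))))
  }
  if (!grepl("\\.nii(\\.gz)?$", low))
    stop("unsupported format (expect .nii, .nii.gz, .png, .tif): ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))          # strip the niftiImage class
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (length(dim(a)) != 3L) stop("expected a 2D or 3D image, got ",
                                 length(dim(a)), "D: ", path)
  nbad <- sum(!is.finite(a))
  if (nbad > 0)
    stop(sprintf("volume contains %d non-finite voxel(s): %s", nbad, path))
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4, 4))) {
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))
    if (any(sp <= 0)) sp <- abs(RNifti::pixdim(img)[1:3])
    org <- xf[1:3, 4]
  } else {
    sp <- abs(RNifti::pixdim(img)[1:3])
    org <- c(0, 0, 0)
  }
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  # undo float32 header quantization (NIfTI-1 stores spacing as float):
  # any spacing stated to 7 significant digits round-trips exactly
  sp <- signif(sp, 7)
  Volume(a, spacing = sp, origin = org)
}

#' Write a volume as NIfTI-1
#'
#' Spacing and origin are stored in both qform and sform; a written file
#' read back with [readVolume()] reproduces the data and spacing exactly
#' and the origin to well below 1e-6 mm.
#'
#' @param vol a [Volume-class].
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  m <- diag(c(vol@spacing, 1))
  m[1:3, 4] <- vol@origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume under an affine transform
#'
#' Backward warping: each voxel of the \code{reference} grid is mapped
#' through \code{transform} (reference-world to source-world, mm) and the
#' source volume is interpolated there. Points falling outside the source
#' field of view receive the source minimum (background). The
#' validity mask is attached as attribute \code{"inside"} on the returned
#' volume's data.
#'
#' @param vol source [Volume-class] (the moving image).
#' @param transform an [AffineParams-class] or 4x4 matrix mapping
#'   reference world coordinates into \code{vol}'s world space.
#' @param reference [Volume-class] defining the output grid; defaults to
#'   \code{vol}.
#' @param interpolation "nearest", "trilinear" (default) or "cubic".
#' @param fill out-of-field value; defaults to \code{min(vol)}.
#' @return A [Volume-class] on the reference grid.
#' @examples
#' v <- makeBrainPhantom(phantomSpec(shape = c(32, 32, 32)))
#' shifted <- resampleVolume(v, affineParams(translation = c(3, 0, 0)))
#' @export
resampleVolume <- function(vol, transform, reference = vol,
                           interpolation = c("trilinear", "nearest", "cubic"),
                           fill = NULL) {
  stopifnot(is(vol, "Volume"), is(reference, "Volume"))
  interpolation <- match.arg(interpolation)
  m <- asMatrix4(transform)
  if (abs(det(m[1:3, 1:3])) <= 1e-12)
    stop("transform is singular or near-singular")
  if (is.null(fill)) fill <- vol@range[1]
  code <- c(nearest = 0L, trilinear = 1L, cubic = 3L)[[interpolation]]
  res <- .resampleCpp(vol@data, dim(vol@data),
                      vol@spacing, vol@origin,
                      dim(reference@data), reference@spacing,
                      reference@origin, m, code, fill)
  d <- array(res$data, dim(reference@data))
  out <- Volume(d, spacing = reference@spacing, origin = reference@origin)
  attr(out@data, "inside") <- array(res$inside, dim(reference@data))
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with replicate boundaries; sigma is in
#' voxel units per axis.
#'
#' @param vol a [Volume-class].
#' @param sigma numeric, scalar or per-axis, in voxels.
#' @return A smoothed [Volume-class].
#' @export
smoothVolume <- function(vol, sigma) {
  stopifnot(is(vol, "Volume"))
  sigma <- rep_len(as.numeric(sigma), 3L)
  d <- array(.gaussSmoothCpp(vol@data, dim(vol@data), sigma),
             dim(vol@data))
  Volume(d, spacing = vol@spacing, origin = vol@origin)
}

# Smooth + decimate by an integer factor per axis (pyramid level).
# Anti-alias sigma ~ factor/2 voxels before taking every factor-th sample;
# spacing and origin updated so world coordinates are preserved.
downsampleVolume <- function(vol, factor) {
  factor <- rep_len(as.integer(factor), 3L)
  if (all(factor == 1L)) return(vol)
  sm <- smoothVolume(vol, ifelse(factor > 1L, factor / 2, 0))
  d <- dim(vol@data)
  ix <- seq(1L, d[1], by = factor[1])
  iy <- seq(1L, d[2], by = factor[2])
  iz <- seq(1L, d[3], by = factor[3])
  Volume(sm@data[ix, iy, iz, drop = FALSE],
         spacing = vol@spacing * factor, origin = vol@origin)
}

# World-space centre of a volume (mm), the default rotation centre.
volumeCenter <- function(vol) {
  vol@origin + (dim(vol@data) - 1) / 2 * vol@spacing
}
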