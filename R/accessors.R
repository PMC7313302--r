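#' Accessors for Volume objects
#'
#' @param object,x a [Volume-class].
#' @return \code{volData} the 3D array; \code{spacing} the voxel size (mm);
#'   \code{origin} the world position of the first voxel centre (mm);
#'   \code{intensityRange} the cached (min, max).
#' @name Volume-accessors
NULL

#' @rdname Volume-accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname Volume-accessors
#' @export
setMethod("volData", "Volume", function(object) object@data)

#' @rdname Volume-accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname Volume-accessors
#' @export
setMethod("spacing", "Volume", function(object) object@spacing)

#' @rdname Volume-accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname Volume-accessors
#' @export
setMethod("origin", "Volume", function(object) object@origin)

#' @rdname Volume-accessors
#' @export
setGeneric("intensityRange", function(object) standardGeneric("intensityRange"))
#' @rdname Volume-accessors
#' @export
setMethod("intensityRange", "Volume", function(object) object@range)

#' @rdname Volume-accessors
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; intensity range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              object@range[1], object@range[2]))
})

setMethod("show", "AffineParams", function(object) {
  cat("AffineParams (12-dof):\n")
  cat(sprintf("  translation (mm): %s\n", paste(signif(object@translation, 6), collapse = ", ")))
  cat(sprintf("  rotation (deg):   %s\n", paste(signif(object@rotation, 6), collapse = ", ")))
  cat(sprintf("  scale:            %s\n", paste(signif(object@scale, 6), collapse = ", ")))
  cat(sprintf("  shear (xy,xz,yz): %s\n", paste(signif(object@shear, 6), collapse = ", ")))
  cat(sprintf("  center (mm):      %s\n", paste(signif(object@center, 6), collapse = ", ")))
})

setMethod("show", "CurveletDecomposition", function(object) {
  idx <- object@meta$index
  cat(sprintf("CurveletDecomposition: %d bands, %d scales, image %s\n",
              length(object@bands), object@meta$scales,
              paste(object@meta$dim, collapse = " x ")))
  cat(sprintf("  orientations per scale: %s\n",
              paste(object@meta$orientations, collapse = ", ")))
  cat(sprintf("  coefficients: %d (%.2fx redundant)\n",
              sum(vapply(object@bands, length, 0)),
              sum(vapply(object@bands, length, 0)) / prod(object@meta$dim)))
})

setMethod("show", "BandStats", function(object) {
  cat(sprintf(paste0("BandStats: n = %d, rho = %.4f%s, weight = %.4g\n",
                     "  fixed:  mean %.4g, var %.4g\n  moving: mean %.4g, var %.4g\n"),
              object@n, object@rho, if (object@degenerate) " (degenerate)" else "",
              object@weight, object@meanF, object@varF, object@meanM, object@varM))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult (%sconverged):\n",
              if (object@converged) "" else "NOT "))
  show(object@params)
  m <- object@metrics
  cat(sprintf("  NMI  %.4f -> %.4f\n  NCCC %.4f -> %.4f\n  AMI  %.4f -> %.4f bits\n",
              m["nmiBefore"], m["nmiAfter"], m["ncccBefore"], m["ncccAfter"],
              m["amiBefore"], m["amiAfter"]))
})

#' Extract fields of a registration result
#'
#' @param object a [RegistrationResult-class].
#' @return \code{resultParams}: the estimated [AffineParams-class];
#'   \code{resultMetrics}: named numeric vector of before/after NMI, NCCC
#'   and AMI; \code{resultTrace}: data.frame of accepted objective values;
#'   \code{registeredVolume}: the resampled moving image.
#' @name RegistrationResult-accessors
NULL

#' @rdname RegistrationResult-accessors
#' @export
setGeneric("resultParams", function(object) standardGeneric("resultParams"))
#' @rdname RegistrationResult-accessors
#' @export
setMethod("resultParams", "RegistrationResult", function(object) object@params)

#' @rdname RegistrationResult-accessors
#' @export
setGeneric("resultMetrics", function(object) standardGeneric("resultMetrics"))
#' @rdname RegistrationResult-accessors
#' @export
setMethod("resultMetrics", "RegistrationResult", function(object) object@metrics)

#' @rdname RegistrationResult-accessors
#' @export
setGeneric("resultTrace", function(object) standardGeneric("resultTrace"))
#' @rdname RegistrationResult-accessors
#' @export
setMethod("resultTrace", "RegistrationResult", function(object) object@trace)

#' @rdname RegistrationResult-accessors
#' @export
setGeneric("registeredVolume", function(object) standardGeneric("registeredVolume"))
#' @rdname RegistrationResult-accessors
#' @export
setMethod("registeredVolume", "RegistrationResult", function(object) object@registered)
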