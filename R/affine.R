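#' Create a 12-parameter affine transform
#'
#' Translation in mm, rotation as Euler angles in degrees (applied
#' intrinsically in x, y, z order, composed as Rz Ry Rx), per-axis scale
#' factors and shears (upper-triangular entries xy, xz, yz). Rotation, scale
#' and shear act about \code{center} (world mm); by convention the fixed
#' image's world-space centre, which decouples rotation from translation in
#' the optimizer.
#'
#' @param translation,rotation,scale,shear,center numeric(3) each (scalars
#'   are recycled).
#' @return An [AffineParams-class] object.
#' @examples
#' p <- affineParams(translation = c(2, -1, 0.5))
#' affineMatrix(p)
#' @export
affineParams <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                         scale = c(1, 1, 1), shear = c(0, 0, 0),
                         center = c(0, 0, 0)) {
  new("AffineParams",
      translation = rep_len(as.numeric(translation), 3L),
      rotation = rep_len(as.numeric(rotation), 3L),
      scale = rep_len(as.numeric(scale), 3L),
      shear = rep_len(as.numeric(shear), 3L),
      center = rep_len(as.numeric(center), 3L))
}

rotMat <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

affineMatrixCore <- function(translation, rotation, scale, shear, center) {
  Sh <- diag(3)
  Sh[1, 2] <- shear[1]; Sh[1, 3] <- shear[2]; Sh[2, 3] <- shear[3]
  A <- rotMat(rotation) %*% Sh %*% diag(scale, 3)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- translation + center - A %*% center
  m
}

#' Homogeneous matrix of an affine transform
#'
#' Builds the 4x4 matrix
#' \code{T(translation) C(center) Rz Ry Rx Shear Scale C(-center)}.
#' Angles are converted from degrees to radians internally.
#'
#' @param p an [AffineParams-class].
#' @return 4x4 numeric matrix.
#' @export
affineMatrix <- function(p) {
  stopifnot(is(p, "AffineParams"))
  if (any(p@scale <= 0)) stop("scale components must be strictly positive")
  affineMatrixCore(p@translation, p@rotation, p@scale, p@shear, p@center)
}

asMatrix4 <- function(x) {
  if (is(x, "AffineParams")) return(affineMatrix(x))
  if (is.matrix(x) && all(dim(x) == c(4, 4))) return(x)
  stop("expected AffineParams or a 4x4 matrix")
}

#' Compose two affine transforms
#'
#' Returns the matrix of "apply \code{b}, then \code{a}", i.e. the product
#' \code{A \%*\% B}.
#'
#' @param a,b [AffineParams-class] objects or 4x4 matrices.
#' @return 4x4 matrix.
#' @export
composeAffine <- function(a, b) asMatrix4(a) %*% asMatrix4(b)

#' Invert an affine transform
#'
#' @param m an [AffineParams-class] or 4x4 matrix.
#' @return 4x4 matrix, the exact homogeneous inverse.
#' @export
invertAffine <- function(m) {
  m <- asMatrix4(m)
  if (abs(det(m[1:3, 1:3])) <= 1e-12)
    stop("transform is singular or near-singular (|det| <= 1e-12)")
  A <- solve(m[1:3, 1:3])
  out <- diag(4)
  out[1:3, 1:3] <- A
  out[1:3, 4] <- -A %*% m[1:3, 4]
  out
}

#' Decompose an affine matrix into named parameters
#'
#' Recovers translation, Euler angles (degrees), scales and shears from a
#' 4x4 matrix built by [affineMatrix()] with the given \code{center}.
#' Assumes no reflection (positive determinant).
#'
#' @param m 4x4 matrix.
#' @param center rotation/scale centre (mm) used when the matrix was built.
#' @return An [AffineParams-class].
#' @export
decomposeAffine <- function(m, center = c(0, 0, 0)) {
  m <- asMatrix4(m)
  A <- m[1:3, 1:3]
  if (det(A) <= 0) stop("cannot decompose a reflecting or singular transform")
  # A = R %*% Sh %*% S : RQ-style decomposition via Gram-Schmidt on columns.
  # Column 1 of Sh %*% S is (s1, 0, 0), so A[,1] = s1 * R[,1], etc.
  s1 <- sqrt(sum(A[, 1]^2)); r1 <- A[, 1] / s1
  u2 <- A[, 2] - sum(A[, 2] * r1) * r1
  s2 <- sqrt(sum(u2^2)); r2 <- u2 / s2
  u3 <- A[, 3] - sum(A[, 3] * r1) * r1 - sum(A[, 3] * r2) * r2
  s3 <- sqrt(sum(u3^2)); r3 <- u3 / s3
  R <- cbind(r1, r2, r3)
  if (det(R) < 0) stop("cannot decompose a reflecting transform")
  U <- t(R) %*% A                       # upper triangular = Sh %*% S
  sc <- c(U[1, 1], U[2, 2], U[3, 3])
  sh <- c(U[1, 2] / sc[2], U[1, 3] / sc[3], U[2, 3] / sc[3])
  # Euler angles from R = Rz Ry Rx
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {                              # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  rot <- c(rx, ry, rz) * 180 / pi
  A <- R %*% U
  tr <- m[1:3, 4] - center + A %*% center
  affineParams(translation = as.numeric(tr), rotation = rot, scale = sc,
               shear = sh, center = center)
}

#' Write / read a transform as plain text
#'
#' Versioned plain-text format: a header line, the 16 matrix entries
#' row-major, and the 12 named parameters plus centre.
#'
#' @param p an [AffineParams-class].
#' @param path file path.
#' @return \code{readAffine} returns an [AffineParams-class];
#'   \code{writeAffine} returns \code{path} invisibly.
#' @export
writeAffine <- function(p, path) {
  stopifnot(is(p, "AffineParams"))
  m <- affineMatrix(p)
  lines <- c(
    "curvemi-transform v1",
    paste("matrix:", paste(format(t(m), digits = 17), collapse = " ")),
    paste("translation:", paste(format(p@translation, digits = 17), collapse = " ")),
    paste("rotation:", paste(format(p@rotation, digits = 17), collapse = " ")),
    paste("scale:", paste(format(p@scale, digits = 17), collapse = " ")),
    paste("shear:", paste(format(p@shear, digits = 17), collapse = " ")),
    paste("center:", paste(format(p@center, digits = 17), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeAffine
#' @export
readAffine <- function(path) {
  lines <- readLines(path)
  if (!grepl("^curvemi-transform v1", lines[1]))
    stop("not a curvemi transform file: ", path)
  getv <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(paste0("^", key, ":"), "", ln)), "\\s+")[[1]])
  }
  affineParams(translation = getv("translation"), rotation = getv("rotation"),
               scale = getv("scale"), shear = getv("shear"),
               center = getv("center"))
}
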