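# Slice-wise 2D curvelet transform built from smooth frequency-domain
# windows: Meyer-type radial coronae (dyadic, doubling) times an angular
# partition whose wedge count doubles every other scale. The windows'
# squares sum to exactly 1 over the frequency plane, so the transform is a
# tight frame with exact inversion. Antipodal wedges are symmetrized, which
# keeps all coefficients real for real images. Each band is cropped to the
# (centre-symmetric) bounding box of its frequency support and carried back
# to space by an inverse FFT on that small grid.

smoothstep01 <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}
risingEdge <- function(x, a, b) sin(pi / 2 * smoothstep01((x - a) / (b - a)))

fftshiftIdx <- function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2))
ifftshiftIdx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))

# batched 2D FFT over the slices of a 3D array
fft2Slices <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  m <- mvfft(matrix(arr, d[1], d[2] * d[3]), inverse = inverse)
  a2 <- aperm(array(m, d), c(2, 1, 3))
  m2 <- mvfft(matrix(a2, d[2], d[1] * d[3]), inverse = inverse)
  out <- aperm(array(m2, c(d[2], d[1], d[3])), c(2, 1, 3))
  if (inverse) out / (d[1] * d[2]) else out
}

# orientations at directional scale js (1 = coarsest directional):
# doubling every other scale
orientationsAt <- function(norient, js)
  as.integer(norient * 2^ceiling((js - 1) / 2))

.curveletCache <- new.env(parent = emptyenv())

# Build (and cache) the window system for a slice geometry.
curveletSystem <- function(nx, ny, scales, norient) {
  key <- paste(nx, ny, scales, norient, sep = "x")
  if (!is.null(.curveletCache[[key]])) return(.curveletCache[[key]])
  if (min(nx, ny) < 2^scales)
    stop(sprintf("slice dimensions %dx%d too small for %d scales (need >= %d)",
                 nx, ny, scales, 2^scales))
  if (norient %% 4 != 0 || norient < 4)
    stop("orientations at the coarsest directional scale must be a positive multiple of 4")
  kx <- (seq_len(nx) - (floor(nx / 2) + 1)) / (nx / 2)
  ky <- (seq_len(ny) - (floor(ny / 2) + 1)) / (ny / 2)
  RX <- outer(kx, rep(1, ny)); RY <- outer(rep(1, nx), ky)
  r <- sqrt(RX^2 + RY^2)
  th <- atan2(RY, RX) %% (2 * pi)
  cuts <- rev(0.5 * 2^(-(seq_len(scales - 1) - 1)))  # ascending dyadic cutoffs
  tw <- 2^(1 / 3)
  S <- lapply(cuts, function(cc) risingEdge(r, cc / tw, cc * tw))
  radial <- vector("list", scales)
  radial[[1]] <- sqrt(pmax(1 - S[[1]]^2, 0))
  if (scales > 2)
    for (j in 2:(scales - 1)) radial[[j]] <- S[[j - 1]] * sqrt(pmax(1 - S[[j]]^2, 0))
  radial[[scales]] <- S[[scales - 1]]
  wins <- list()
  addWin <- function(j, l, W) wins[[length(wins) + 1]] <<- list(j = j, l = l, W = W)
  for (j in seq_len(scales)) {
    if (j == 1 || j == scales) {
      addWin(j, 0L, radial[[j]])
    } else {
      L <- orientationsAt(norient, j - 1)
      w <- pi / L * 0.9
      bnd <- 2 * pi * (seq_len(L) - 1) / L - pi / L
      Sang <- lapply(seq_len(L), function(l) {
        dth <- ((th - bnd[l] + pi) %% (2 * pi)) - pi
        risingEdge(dth, -w, w)
      })
      for (l in seq_len(L / 2)) {
        A1 <- Sang[[l]] * sqrt(pmax(1 - Sang[[l %% L + 1]]^2, 0))
        l2 <- l + L / 2
        A2 <- Sang[[l2]] * sqrt(pmax(1 - Sang[[l2 %% L + 1]]^2, 0))
        addWin(j, l, radial[[j]] * sqrt(A1^2 + A2^2))
      }
    }
  }
  ci <- floor(nx / 2) + 1; cj <- floor(ny / 2) + 1
  N <- nx * ny
  for (k in seq_along(wins)) {
    b <- wins[[k]]
    if (b$j == scales) {          # highpass reaches the grid corners
      ix <- seq_len(nx); iy <- seq_len(ny)
    } else {
      nz <- which(b$W > 1e-14, arr.ind = TRUE)
      kxm <- min(max(abs(nz[, 1] - ci)), ci - 1)
      kym <- min(max(abs(nz[, 2] - cj)), cj - 1)
      ix <- (ci - kxm):(ci + kxm); iy <- (cj - kym):(cj + kym)
    }
    Wc <- b$W[ix, iy]
    m <- length(ix) * length(iy)
    sx <- fftshiftIdx(nx); sy <- fftshiftIdx(ny)
    idx0 <- as.integer(outer(sx[ix] - 1L, (sy[iy] - 1L) * nx, `+`))
    dci <- match(ci, ix); dcj <- match(cj, iy)
    wins[[k]] <- list(j = b$j, l = b$l, ix = ix, iy = iy, Wc = Wc,
                      Wc2 = as.vector(Wc)^2, scaleFac = sqrt(m / N),
                      unshiftX = ifftshiftIdx(length(ix)),
                      unshiftY = ifftshiftIdx(length(iy)),
                      idx0 = idx0,
                      dcPos = if (is.na(dci)) -1L
                              else (dci - 1L) + (dcj - 1L) * length(ix),
                      wdc = if (is.na(dci)) 0 else Wc[dci, dcj])
  }
  sys <- list(nx = nx, ny = ny, scales = scales, norient = norient,
              wins = wins,
              idxList = lapply(wins, `[[`, "idx0"),
              w2List = lapply(wins, `[[`, "Wc2"),
              dcPos = vapply(wins, `[[`, 0L, "dcPos"),
              wdcVec = vapply(wins, `[[`, 0, "wdc"),
              orientations = c(1L, if (scales > 2)
                vapply(2:(scales - 1), function(j) orientationsAt(norient, j - 1) %/% 2L, 1L),
                1L),
              shiftX = fftshiftIdx(nx), shiftY = fftshiftIdx(ny))
  .curveletCache[[key]] <- sys
  sys
}

defaultScales <- function(nx, ny) max(3L, floor(log2(min(nx, ny))) - 3L)

# shifted (DC-centred) slice spectra of a 3D array
sliceSpectra <- function(a, sys) {
  F <- fft2Slices(a)
  F[sys$shiftX, sys$shiftY, , drop = FALSE]
}

#' Forward curvelet transform
#'
#' Decomposes a volume slice-wise (along the third axis) into multiscale,
#' multidirectional curvelet coefficient bands. The coarsest and finest
#' scales are isotropic; intermediate scales are split into angular wedges
#' whose count doubles every other scale. Coefficients are real
#' (antipodal wedges symmetrized); the decomposition is an exactly tight
#' frame and [curveletInverse()] reconstructs the input to machine
#' precision.
#'
#' @param vol a [Volume-class] or 3D array (a matrix is promoted to one
#'   slice).
#' @param scales total number of dyadic scales including the isotropic
#'   coarsest and finest; default \code{max(3, floor(log2(min slice dim)) - 3)}.
#'   Slice dimensions must be at least \code{2^scales}.
#' @param orientations wedge count at the coarsest directional scale
#'   (multiple of 4, default 8); stored bands pair antipodal wedges, so a
#'   scale with \code{L} wedges yields \code{L/2} real bands.
#' @return A [CurveletDecomposition-class].
#' @examples
#' v <- makeBrainPhantom(phantomSpec(shape = c(64, 64, 32)))
#' dec <- curveletForward(v)
#' rec <- curveletInverse(dec)
#' max(abs(volData(rec) - volData(v)))
#' @export
curveletForward <- function(vol, scales = NULL, orientations = 8L) {
  sp <- c(1, 1, 1); org <- c(0, 0, 0)
  if (is(vol, "Volume")) {
    sp <- vol@spacing; org <- vol@origin
    a <- vol@data
  } else {
    a <- vol
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  }
  d <- dim(a)
  if (is.null(scales)) scales <- defaultScales(d[1], d[2])
  sys <- curveletSystem(d[1], d[2], scales, orientations)
  Fs <- sliceSpectra(a, sys)
  bands <- lapply(sys$wins, function(b) {
    sub <- Fs[b$ix, b$iy, , drop = FALSE] * as.vector(b$Wc)
    sub <- sub[b$unshiftX, b$unshiftY, , drop = FALSE]
    Re(fft2Slices(sub, inverse = TRUE)) * b$scaleFac
  })
  idx <- data.frame(scale = vapply(sys$wins, `[[`, 1L, "j"),
                    orientation = vapply(sys$wins, `[[`, 1L, "l"))
  new("CurveletDecomposition", bands = bands,
      meta = list(dim = d, scales = scales, norient = orientations,
                  orientations = sys$orientations, index = idx,
                  spacing = sp, origin = org, is_complex = FALSE))
}

#' Inverse curvelet transform
#'
#' Exact inversion of [curveletForward()]: each band is carried back to the
#' frequency plane, re-weighted by its wedge window, and accumulated;
#' because the window squares sum to 1 the reconstruction error is at
#' machine precision.
#'
#' @param dec a [CurveletDecomposition-class].
#' @return The reconstructed [Volume-class].
#' @export
curveletInverse <- function(dec) {
  stopifnot(is(dec, "CurveletDecomposition"))
  d <- dec@meta$dim
  sys <- curveletSystem(d[1], d[2], dec@meta$scales, dec@meta$norient)
  if (length(dec@bands) != length(sys$wins))
    stop("decomposition is inconsistent: band count does not match its settings")
  Fs <- array(0 + 0i, d)
  for (k in seq_along(sys$wins)) {
    b <- sys$wins[[k]]
    band <- dec@bands[[k]]
    if (!identical(dim(band), c(length(b$ix), length(b$iy), d[3])))
      stop(sprintf("band %d has been tampered with: expected %s, got %s",
                   k, paste(c(length(b$ix), length(b$iy), d[3]), collapse = "x"),
                   paste(dim(band), collapse = "x")))
    v <- fft2Slices(band / b$scaleFac)
    m1 <- length(b$ix)
    v <- v[fftshiftIdx(m1), fftshiftIdx(length(b$iy)), , drop = FALSE]
    Fs[b$ix, b$iy, ] <- Fs[b$ix, b$iy, , drop = FALSE] + v * as.vector(b$Wc)
  }
  F <- Fs[ifftshiftIdx(d[1]), ifftshiftIdx(d[2]), , drop = FALSE]
  Volume(Re(fft2Slices(F, inverse = TRUE)),
         spacing = dec@meta$spacing, origin = dec@meta$origin)
}

#' Pair the bands of two decompositions
#'
#' Matches the coefficient bands of two decompositions of same-shape
#' images taken with the same transform settings, in canonical
#' (scale, orientation) order with slices stacked inside each band.
#'
#' @param a,b [CurveletDecomposition-class] objects.
#' @return A list of pairs; each element has \code{f} and \code{m}
#'   coefficient arrays plus \code{scale} and \code{orientation}.
#' @export
matchBands <- function(a, b) {
  stopifnot(is(a, "CurveletDecomposition"), is(b, "CurveletDecomposition"))
  if (!identical(a@meta$dim, b@meta$dim))
    stop("cannot align decompositions: image shapes differ")
  if (a@meta$scales != b@meta$scales || a@meta$norient != b@meta$norient)
    stop("cannot align decompositions: transform settings differ")
  lapply(seq_along(a@bands), function(k) {
    list(f = a@bands[[k]], m = b@bands[[k]],
         scale = a@meta$index$scale[k], orientation = a@meta$index$orientation[k])
  })
}

# Fast per-band moments from raw (unshifted) slice spectra via the C++
# accumulator; algebraically identical to bandMomentsFromSpectra below.
bandMomentsFast <- function(Ff, Fm, sys) {
  d <- dim(Ff)
  acc <- .bandMomentsCpp(Ff, Fm, d[1] * d[2], d[3],
                         sys$idxList, sys$w2List, sys$dcPos, sys$wdcVec)
  lapply(seq_along(sys$wins), function(k) {
    b <- sys$wins[[k]]
    m <- length(b$Wc)
    s2m <- b$scaleFac^2 / m
    list(n = m * d[3],
         sumF = acc[k, 4] * b$scaleFac, sumM = acc[k, 5] * b$scaleFac,
         sumsqF = acc[k, 1] * s2m, sumsqM = acc[k, 2] * s2m,
         cross = acc[k, 3] * s2m)
  })
}

# Frequency-domain band moments (n, sum, sum of squares) of one image and
# the cross products between two images, per band. By Parseval these equal
# the spatial-band statistics computed by curveletForward() exactly; used
# as the registration objective's fast path (no inverse FFTs). The DC
# sample of the shifted sub-spectrum sits at the window's centre position.
bandMomentsFromSpectra <- function(FsF, FsM, sys) {
  nz <- dim(FsF)[3]
  lapply(sys$wins, function(b) {
    m <- length(b$Wc)
    vF <- FsF[b$ix, b$iy, , drop = FALSE]
    vM <- FsM[b$ix, b$iy, , drop = FALSE]
    w2 <- b$Wc2                          # recycles over stacked slices
    s2m <- b$scaleFac^2 / m
    rF <- Re(vF); iF <- Im(vF); rM <- Re(vM); iM <- Im(vM)
    sumsqF <- sum(w2 * (rF * rF + iF * iF)) * s2m
    sumsqM <- sum(w2 * (rM * rM + iM * iM)) * s2m
    cross <- sum(w2 * (rF * rM + iF * iM)) * s2m
    # the full-grid DC sits at the centre of every (centre-symmetric) box
    dci <- which(b$ix == floor(sys$nx / 2) + 1)
    dcj <- which(b$iy == floor(sys$ny / 2) + 1)
    wdc <- b$Wc[dci, dcj]
    sumF <- sum(rF[dci, dcj, ]) * wdc * b$scaleFac
    sumM <- sum(rM[dci, dcj, ]) * wdc * b$scaleFac
    list(n = m * nz, sumF = sumF, sumM = sumM,
         sumsqF = sumsqF, sumsqM = sumsqM, cross = cross)
  })
}
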