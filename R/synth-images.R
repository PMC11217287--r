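#' @include AllClasses.R
NULL

standardizeImage <- function(m) {
  s <- stats::sd(as.numeric(m))
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

anisotropicKernel <- function(thetaDeg, sigmaAlong, sigmaAcross,
                              rmax = Inf) {
  r <- min(ceiling(3 * max(sigmaAlong, sigmaAcross)), rmax)
  xs <- -r:r
  kx <- matrix(xs, 2L * r + 1L, 2L * r + 1L)
  ky <- t(kx)
  th <- thetaDeg * pi / 180
  u <- kx * cos(th) + ky * sin(th)
  w <- -kx * sin(th) + ky * cos(th)
  K <- exp(-u^2 / (2 * sigmaAlong^2) - w^2 / (2 * sigmaAcross^2))
  K / sum(K)
}

#' Synthetic oriented fibril texture
#'
#' Generates a fibril-like 2D texture of controlled order: white noise is
#' filtered with an elongated Gaussian kernel along the ground-truth axis
#' (streaks along \code{orientationDeg}) and band-passed by subtracting a
#' broad isotropic blur, then blended with an independently smoothed
#' isotropic noise field with weight \code{1 - anisotropyLevel}. The
#' ground-truth orientation and anisotropy level are recorded on the
#' returned \linkS4class{FibrilImage} for loop-back tests against
#' \code{\link{fibrilTensor}}. Bitwise reproducible for a fixed seed.
#'
#' @param sizePx integer pair, image size in px (>= 16)
#' @param orientationDeg ground-truth fibril axis in [0, 180)
#' @param anisotropyLevel blend weight in [0, 1]; 0 is pure isotropic noise
#' @param rngSeed integer RNG seed
#' @param pixelSize µm per pixel
#' @param sigmaAlong,sigmaAcross streak kernel scales in px
#' @return a \linkS4class{FibrilImage}
#' @export
makeFibrilImage <- function(sizePx = c(256L, 256L), orientationDeg = 0,
                            anisotropyLevel = 1, rngSeed = 1L,
                            pixelSize = 0.2, sigmaAlong = 12, sigmaAcross = 2.5) {
  if (orientationDeg < 0 || orientationDeg >= 180)
    stop("invalid spec: orientation must lie in [0, 180)")
  if (anisotropyLevel < 0 || anisotropyLevel > 1)
    stop("invalid spec: anisotropy level must lie in [0, 1]")
  nx <- sizePx[1L]; ny <- sizePx[2L]
  rmax <- (min(nx, ny) - 1L) %/% 2L    # kernels may not exceed the image
  withSeed(rngSeed, {
    noise1 <- matrix(stats::rnorm(nx * ny), nx, ny)
    noise2 <- matrix(stats::rnorm(nx * ny), nx, ny)
    streak <- EBImage::filter2(noise1,
                               anisotropicKernel(orientationDeg, sigmaAlong,
                                                 sigmaAcross, rmax))
    streak <- streak - EBImage::filter2(
      streak, anisotropicKernel(0, sigmaAlong, sigmaAlong, rmax))
    iso <- EBImage::filter2(noise2,
                            anisotropicKernel(0, 1.5, 1.5, rmax))
    img <- anisotropyLevel * standardizeImage(as.matrix(streak)) +
      (1 - anisotropyLevel) * standardizeImage(as.matrix(iso))
    new("FibrilImage", pixels = img, pixelSize = pixelSize,
        trueOrientation = orientationDeg, trueAnisotropy = anisotropyLevel)
  })
}

#' Silhouette image specification
#'
#' Parameters for a synthetic cleared-seed image: one or more ellipses of
#' common half axes on a dark background, with smooth radial boundary
#' noise. Emulates the DIC images consumed by mature-seed shape
#' measurement.
#'
#' @param halfLength,halfWidth ellipse half axes in px (halfLength >=
#'   halfWidth > 0)
#' @param centers n x 2 matrix of ellipse centers (px); no rows = empty image
#' @param sizePx integer pair, image size
#' @param noiseAmp relative boundary-noise amplitude
#' @param maxOverlap maximum tolerated pairwise overlap as a fraction of an
#'   ellipse's area
#' @return a list of class "silhouetteSpec"
#' @export
silhouetteSpec <- function(halfLength, halfWidth, centers,
                           sizePx = c(512L, 512L), noiseAmp = 0.01,
                           maxOverlap = 0.05) {
  if (!(halfLength >= halfWidth && halfWidth > 0))
    stop("invalid spec: require halfLength >= halfWidth > 0")
  centers <- matrix(centers, ncol = 2L)
  structure(list(halfLength = halfLength, halfWidth = halfWidth,
                 centers = centers, sizePx = as.integer(sizePx),
                 noiseAmp = noiseAmp, maxOverlap = maxOverlap),
            class = "silhouetteSpec")
}

#' Synthetic seed silhouette image
#'
#' Rasterizes the ellipses of a \code{\link{silhouetteSpec}} as bright
#' foreground (0.9) over a dark noisy background (0.1), with per-seed
#' smooth radial boundary perturbations of relative amplitude
#' \code{noiseAmp}. Ground-truth per-seed axes and centers are attached as
#' the \code{"groundTruth"} attribute. Seeds may touch but not overlap by
#' more than \code{maxOverlap}.
#'
#' @param spec a \code{\link{silhouetteSpec}}
#' @param rngSeed integer RNG seed
#' @return numeric intensity matrix with a \code{groundTruth} attribute
#' @export
makeSilhouetteImage <- function(spec, rngSeed = 1L) {
  stopifnot(inherits(spec, "silhouetteSpec"))
  nx <- spec$sizePx[1L]; ny <- spec$sizePx[2L]
  ctr <- spec$centers
  if (nrow(ctr)) {
    bad <- ctr[, 1L] - spec$halfLength * (1 + 2 * spec$noiseAmp) < 1 |
      ctr[, 1L] + spec$halfLength * (1 + 2 * spec$noiseAmp) > nx |
      ctr[, 2L] - spec$halfWidth * (1 + 2 * spec$noiseAmp) < 1 |
      ctr[, 2L] + spec$halfWidth * (1 + 2 * spec$noiseAmp) > ny
    if (any(bad)) stop("invalid spec: seed outside the image canvas")
  }
  withSeed(rngSeed, {
    img <- matrix(0.1 + stats::rnorm(nx * ny, sd = 0.02), nx, ny)
    xs <- matrix(seq_len(nx), nx, ny)
    ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
    masks <- vector("list", nrow(ctr))
    for (k in seq_len(nrow(ctr))) {
      dx <- (xs - ctr[k, 1L]) / spec$halfLength
      dy <- (ys - ctr[k, 2L]) / spec$halfWidth
      phi <- atan2(dy, dx)
      rho <- rep(1, length(phi))
      ## harmonics >= 3 only: h = 2 is the elliptic-distortion mode and
      ## would silently change the recorded ground-truth axes
      if (spec$noiseAmp > 0) {
        for (h in 3:7) {
          amp <- stats::rnorm(1, sd = spec$noiseAmp / h)
          ph <- stats::runif(1, 0, 2 * pi)
          rho <- rho + amp * cos(h * phi + ph)
        }
      }
      masks[[k]] <- (dx^2 + dy^2) <= rho^2
    }
    if (length(masks) > 1L) {
      area1 <- pi * spec$halfLength * spec$halfWidth
      for (i in seq_len(length(masks) - 1L)) for (j in (i + 1L):length(masks)) {
        if (sum(masks[[i]] & masks[[j]]) > spec$maxOverlap * area1)
          stop("invalid spec: seeds overlap by more than the allowed fraction")
      }
    }
    for (m in masks) img[m] <- 0.9
    attr(img, "groundTruth") <- data.frame(
      seed = seq_len(nrow(ctr)),
      center_x = ctr[, 1L], center_y = ctr[, 2L],
      half_length = rep(spec$halfLength, nrow(ctr)),
      half_width = rep(spec$halfWidth, nrow(ctr)))
    img
  })
}
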