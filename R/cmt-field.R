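#' @include curvature.R
NULL

## Von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
## back to the uniform circle. Used on doubled angles for axial draws.
rVonMises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3L] - 0.5) * acos(pmax(-1, pmin(1, f)))
      i <- i + 1L
    }
  }
  out
}

#' Sample an axial CMT orientation field around the curvature axes
#'
#' Draws one axial (sign-free) CMT orientation per cell from a von Mises
#' distribution on doubled angles (period 180°, the standard axial-statistics
#' device) with concentration \code{kappa}, centered on the cell's
#' maximum-curvature axis rotated by \code{offsetDeg} within the tangent
#' plane. \code{kappa = 0} gives uniform axial orientations; large
#' \code{kappa} gives tight alignment. The per-cell organization score is
#' the mean resultant length of the doubled-angle distribution,
#' \eqn{I_1(\kappa)/I_0(\kappa)}. Emulates CMT arrays orienting along the
#' main curvature axis at each cell location.
#'
#' @param curv a \linkS4class{CurvatureField} providing per-cell axes
#' @param kappa von Mises concentration on the doubled angle, >= 0
#' @param offsetDeg rotation of the distribution center away from the
#'   maximum-curvature axis (degrees, within the tangent plane)
#' @param rngSeed integer RNG seed
#' @return an \linkS4class{OrientationField} of unit tangent vectors
#' @export
sampleCMTField <- function(curv, kappa, offsetDeg = 0, rngSeed = 1L) {
  stopifnot(is(curv, "CurvatureField"))
  if (kappa < 0) stop("kappa must be >= 0")
  a1 <- curv@axis1; a2 <- curv@axis2
  if (!all(is.finite(a1)) || !all(is.finite(a2)))
    stop("incomplete field: missing curvature axes")
  n <- length(curv@cellId)
  delta <- withSeed(rngSeed, rVonMises(n, 0, kappa)) / 2
  ang <- offsetDeg * pi / 180 + delta
  nrm <- crossProduct(a1, a2)          # cell normal from the axis pair
  e2 <- crossProduct(nrm, a1)
  vec <- a1 * cos(ang) + e2 * sin(ang)
  score <- if (kappa < 1e-8) 0 else
    besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
  new("OrientationField", cellId = curv@cellId, vectors = normalizeRows(vec),
      score = rep(score, n))
}

#' @rdname accessors
#' @export
setMethod("orientationVectors", "OrientationField", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("organizationScore", "OrientationField", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("cellIds", "OrientationField", function(x) x@cellId)

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %d cells, mean organization score %.3g\n",
              length(object@cellId), mean(object@score)))
})

#' @rdname asDataFrame
#' @export
setMethod("asDataFrame", "OrientationField", function(x, ...) {
  data.frame(cell_id = x@cellId, x_mt = x@vectors[, 1L],
             y_mt = x@vectors[, 2L], z_mt = x@vectors[, 3L],
             organization = x@score)
})
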