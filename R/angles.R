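#' @include AllClasses.R
NULL

#' Axial angle between two orientation axes
#'
#' The sign-free angle between two axes (unit 3-vectors where \code{v} and
#' \code{-v} are the same orientation):
#' \deqn{\theta = \cos^{-1}(|u \cdot v|) \in [0°, 90°].}
#' Symmetric in its arguments and invariant to a sign flip of either
#' vector. Inputs within 1\% of unit norm are normalized; other norms are
#' rejected.
#'
#' @param u,v numeric 3-vectors
#' @return θ in degrees
#' @export
axisAngle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined orientation: zero vector")
  if (abs(nu - 1) > 0.01 || abs(nv - 1) > 0.01)
    stop("axis vectors must be unit norm (within 1%)")
  acos(pmin(1, abs(sum((u / nu) * (v / nv))))) * 180 / pi
}

#' Correlate CMT orientation with the maximum-curvature direction
#'
#' Computes, for every cell present in both fields, the axial angle θ
#' between the mean CMT axis and the maximum-curvature axis (both tangent
#' to the surface at the cell center), and summarizes the distribution
#' with a fixed-width histogram on [0°, 90°] plus median, mean and the
#' fraction of cells below 30°. Cells missing from either field are
#' excluded and counted.
#'
#' @param orient an \linkS4class{OrientationField}
#' @param curv a \linkS4class{CurvatureField}
#' @param bins number of equal-width histogram bins on [0, 90] (default 18)
#' @return an \linkS4class{AngleDistribution}
#' @export
correlateOrientationWithCurvature <- function(orient, curv, bins = 18L) {
  stopifnot(is(orient, "OrientationField"), is(curv, "CurvatureField"))
  shared <- intersect(orient@cellId, curv@cellId)
  if (length(shared) == 0L) stop("empty join: the fields share no cells")
  nExcl <- length(union(orient@cellId, curv@cellId)) - length(shared)
  io <- match(shared, orient@cellId)
  ic <- match(shared, curv@cellId)
  theta <- vapply(seq_along(shared), function(k)
    axisAngle(orient@vectors[io[k], ], curv@axis1[ic[k], ]), numeric(1))
  names(theta) <- shared
  breaks <- seq(0, 90, length.out = bins + 1L)
  counts <- as.integer(table(cut(theta, breaks, include.lowest = TRUE)))
  new("AngleDistribution", theta = theta, breaks = breaks, counts = counts,
      summary = list(median = stats::median(theta), mean = mean(theta),
                     frac_below_30 = mean(theta < 30)),
      nExcluded = as.integer(nExcl))
}

#' @rdname accessors
#' @export
setMethod("thetaValues", "AngleDistribution", function(x) x@theta)

setMethod("show", "AngleDistribution", function(object) {
  cat(sprintf(paste0("AngleDistribution: %d cells (%d excluded), median %.2f",
                     " deg, mean %.2f deg, %.0f%% below 30 deg\n"),
              length(object@theta), object@nExcluded, object@summary$median,
              object@summary$mean, 100 * object@summary$frac_below_30))
})

#' CMT orientation relative to a focal point (2D)
#'
#' For each cell, the axial deviation between its CMT axis and the local
#' circumferential direction around a focal point (e.g. an ablation site):
#' 0° means the CMT axis is perfectly circumferential (tangent to the
#' circle through the cell centered on the focus), 90° means radial.
#'
#' @param orientationsDeg per-cell CMT axis angles in degrees (axial, mod 180)
#' @param centroids n x 2 matrix of cell centroids
#' @param focus length-2 focal point, distinct from every centroid
#' @return per-cell deviation in degrees, in [0, 90]
#' @export
orientationRelativeToPoint <- function(orientationsDeg, centroids, focus) {
  centroids <- matrix(centroids, ncol = 2L)
  stopifnot(length(orientationsDeg) == nrow(centroids), length(focus) == 2L)
  dx <- centroids[, 1L] - focus[1L]
  dy <- centroids[, 2L] - focus[2L]
  if (any(dx == 0 & dy == 0))
    stop("undefined direction: a centroid coincides with the focus")
  circDeg <- atan2(dy, dx) * 180 / pi + 90   # perpendicular to the radius
  axialDiffDeg(orientationsDeg, circDeg)
}
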