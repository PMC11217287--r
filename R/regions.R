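#' @include shell-fem.R
NULL

#' Classify cells into tip, flank and flat-face regions
#'
#' Geometric partition of the seed surface used for region-wise anisotropy
#' comparisons: cells whose centroid lies at \code{|x| > (1 - tipFraction) a}
#' are \code{tip}; of the rest, cells whose surface normal is within
#' \code{flankAngleDeg} of the ±y (width) axis are \code{flank} (the narrow
#' sides), the others \code{flat_face} (the flattened z-facing sides).
#'
#' @param mesh the \linkS4class{SurfaceMesh} the tessellation lives on
#' @param tess a \linkS4class{CellTessellation}
#' @param spec the \linkS4class{EllipsoidSpec} the mesh was generated from
#' @param tipFraction cap extent as a fraction of a, in (0, 0.5)
#' @param flankAngleDeg normal-to-y-axis angle bound, in (0, 90)
#' @return a \linkS4class{RegionLabels}
#' @export
classifyRegions <- function(mesh, tess, spec, tipFraction = 0.15,
                            flankAngleDeg = 45) {
  stopifnot(is(tess, "CellTessellation"), is(spec, "EllipsoidSpec"))
  if (tipFraction <= 0 || tipFraction >= 0.5)
    stop("domain error: tipFraction must lie in (0, 0.5)")
  if (flankAngleDeg <= 0 || flankAngleDeg >= 90)
    stop("domain error: flankAngleDeg must lie in (0, 90)")
  ctr <- tess@centroids
  rad <- sqrt((ctr[, 1L] / spec@a)^2 + (ctr[, 2L] / spec@b)^2 +
                (ctr[, 3L] / spec@c)^2)
  if (any(abs(rad - 1) > 0.01))
    stop("inconsistency error: cell centroids are off the ellipsoid by > 1%")
  n <- cellNormals(tess)
  lab <- rep("flat_face", nCells(tess))
  lab[abs(n[, 2L]) > cos(flankAngleDeg * pi / 180)] <- "flank"
  lab[abs(ctr[, 1L]) > (1 - tipFraction) * spec@a] <- "tip"
  new("RegionLabels", cellId = seq_len(nCells(tess)),
      label = factor(lab, levels = c("flat_face", "flank", "tip")))
}

#' @rdname accessors
#' @export
setMethod("regionLabel", "RegionLabels", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("cellIds", "RegionLabels", function(x) x@cellId)

setMethod("show", "RegionLabels", function(object) {
  tab <- table(object@label)
  cat("RegionLabels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Region-wise summary of a tensor field
#'
#' Per-region count, mean, median and SD of the anisotropy of a stress or
#' curvature field, plus the mean axial angle between the major principal
#' axis and the long (x) seed axis. Cells with undefined (NaN/NA) anisotropy
#' are excluded and counted in \code{n_excluded}.
#'
#' @param field a \linkS4class{StressField} or \linkS4class{CurvatureField}
#' @param labels a \linkS4class{RegionLabels} covering the field's cells
#' @return a data.frame with one row per region
#' @export
fieldSummary <- function(field, labels) {
  stopifnot(is(field, "TangentTensorField"), is(labels, "RegionLabels"))
  if (!all(field@cellId %in% labels@cellId))
    stop("coverage error: labels are missing cells present in the field")
  lab <- labels@label[match(field@cellId, labels@cellId)]
  angle <- vapply(seq_along(field@cellId), function(i)
    axisAngle(field@axis1[i, ], c(1, 0, 0)), numeric(1))
  do.call(rbind, lapply(levels(lab), function(lv) {
    sel <- lab == lv
    a <- field@anisotropy[sel]
    ang <- angle[sel]
    bad <- !is.finite(a)
    a <- a[!bad]; ang <- ang[!bad]
    data.frame(region = lv, n = length(a), n_excluded = sum(bad),
               mean_anisotropy = if (length(a)) mean(a) else NA_real_,
               median_anisotropy = if (length(a)) stats::median(a) else NA_real_,
               sd_anisotropy = if (length(a) > 1L) stats::sd(a) else NA_real_,
               mean_axis_angle_to_long_axis =
                 if (length(ang)) mean(ang) else NA_real_)
  }))
}
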