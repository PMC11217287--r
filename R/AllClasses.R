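#' @import methods
NULL

#' Triaxial ellipsoid specification
#'
#' Semi-axes of the idealized seed surface, in micrometers. The convention is
#' \code{a >= b >= c}: \code{a} is the semi-length (the main seed axis,
#' global x), \code{b} the semi-width (y) and \code{c} the semi-thickness
#' (z). The default two-days-post-anthesis ("2DPA") seed used throughout the
#' package has \code{a/b = 1.7} and \code{c/b = 0.85}, i.e. a seed whose
#' aspect ratio is 1.7 and whose thickness is 15\% below its width.
#'
#' @slot a semi-length (µm)
#' @slot b semi-width (µm)
#' @slot c semi-thickness (µm)
#' @export
setClass("EllipsoidSpec",
  representation(a = "numeric", b = "numeric", c = "numeric"),
  validity = function(object) {
    if (length(object@a) != 1L || length(object@b) != 1L || length(object@c) != 1L)
      return("semi-axes must be scalars")
    if (!all(is.finite(c(object@a, object@b, object@c))))
      return("semi-axes must be finite")
    if (object@c <= 0) return("invalid ellipsoid spec: semi-axes must be positive")
    if (object@a < object@b || object@b < object@c)
      return("invalid ellipsoid spec: require a >= b >= c")
    TRUE
  })

#' Triangulated surface mesh
#'
#' A triangle mesh standing in for the outer surface of the seed coat,
#' coordinates in micrometers. Face normals are stored per face and oriented
#' away from the mesh centroid for closed surfaces. The mesh may be an open
#' patch (e.g. a planar sheet used for cell-growth analysis); operations that
#' require a closed 2-manifold (the shell solver) check closure themselves.
#'
#' @slot vertices numeric matrix, one 3D point per row (µm)
#' @slot faces integer matrix, one triangle of vertex indices per row
#' @slot faceNormals numeric matrix of outward unit normals, one per face
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", faceNormals = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
    if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
    if (min(f) < 1L || max(f) > nrow(v)) return("face indices out of range")
    if (nrow(object@faceNormals) != nrow(f)) return("one normal per face required")
    ## every edge must be shared by at most 2 faces (2-manifold)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (any(table(key) > 2L)) return("non-manifold edge (shared by > 2 faces)")
    if (any(faceAreasRaw(v, f) <= 0)) return("degenerate face with zero area")
    TRUE
  })

#' Cell tessellation of a surface mesh
#'
#' Partition of the faces of a \linkS4class{SurfaceMesh} into cells (the
#' synthetic analogue of segmented epidermal cells). Every face carries
#' exactly one cell id; per-cell centroids (area-weighted, µm) and areas
#' (µm²) are precomputed. An optional lineage maps each cell of an earlier
#' tessellation to its offspring in this one.
#'
#' @slot mesh the underlying \linkS4class{SurfaceMesh}
#' @slot faceCell integer vector, cell id of each face
#' @slot centroids numeric matrix of per-cell centroids (one row per cell)
#' @slot areas numeric vector of per-cell areas (µm²)
#' @slot lineage list mapping parent cell id (name) to offspring ids, or empty
#' @export
setClass("CellTessellation",
  representation(mesh = "SurfaceMesh", faceCell = "integer",
                 centroids = "matrix", areas = "numeric", lineage = "list"),
  validity = function(object) {
    if (length(object@faceCell) != nrow(object@mesh@faces))
      return("every face needs exactly one cell id")
    ids <- sort(unique(object@faceCell))
    if (!identical(ids, seq_along(ids))) return("cell ids must be 1..n_cells")
    if (nrow(object@centroids) != length(ids) || length(object@areas) != length(ids))
      return("centroids/areas must have one entry per cell")
    total <- sum(faceAreasRaw(object@mesh@vertices, object@mesh@faces))
    if (abs(sum(object@areas) - total) > 1e-6 * total)
      return("per-cell areas must sum to the mesh area")
    TRUE
  })

#' Symmetric tangent-plane tensor field (per cell)
#'
#' Common representation of per-cell surface tensors: principal values
#' \code{value1 >= value2}, two orthogonal tangent unit axes, and a scalar
#' anisotropy. \linkS4class{StressField} (principal membrane stresses, MPa)
#' and \linkS4class{CurvatureField} (principal curvatures, 1/µm) extend it.
#'
#' @slot cellId integer cell ids
#' @slot value1,value2 principal values, \code{value1 >= value2}
#' @slot axis1,axis2 unit tangent 3-vectors (rows), axis1 belongs to value1
#' @slot anisotropy scalar in [0, 1] per cell
#' @export
setClass("TangentTensorField",
  representation(cellId = "integer", value1 = "numeric", value2 = "numeric",
                 axis1 = "matrix", axis2 = "matrix", anisotropy = "numeric"),
  validity = function(object) {
    n <- length(object@cellId)
    if (length(object@value1) != n || length(object@value2) != n ||
        nrow(object@axis1) != n || nrow(object@axis2) != n ||
        length(object@anisotropy) != n)
      return("all slots must have one entry per cell")
    ok <- is.finite(object@value1) & is.finite(object@value2)
    if (any(object@value1[ok] < object@value2[ok] - 1e-9))
      return("value1 must be >= value2")
    dots <- abs(rowSums(object@axis1 * object@axis2))
    if (any(dots[ok] > 1e-3)) return("principal axes must be orthogonal")
    TRUE
  })

#' @rdname TangentTensorField-class
#' @export
setClass("StressField", contains = "TangentTensorField")

#' @rdname TangentTensorField-class
#' @slot neighborhoodRadius geodesic fitting radius used (µm)
#' @export
setClass("CurvatureField", contains = "TangentTensorField",
  representation(neighborhoodRadius = "numeric"))

#' Axial orientation field (per cell)
#'
#' Per-cell mean cortical-microtubule (CMT) orientation as a sign-free
#' (axial) unit tangent 3-vector, with an organization score in [0, 1].
#' \code{v} and \code{-v} are the same orientation.
#'
#' @slot cellId integer cell ids
#' @slot vectors numeric matrix of unit tangent 3-vectors (rows)
#' @slot score per-cell organization score in [0, 1]
#' @export
setClass("OrientationField",
  representation(cellId = "integer", vectors = "matrix", score = "numeric"),
  validity = function(object) {
    n <- length(object@cellId)
    if (nrow(object@vectors) != n || length(object@score) != n)
      return("one vector and one score per cell required")
    nv <- sqrt(rowSums(object@vectors^2))
    if (any(abs(nv - 1) > 1e-6)) return("orientation vectors must be unit norm")
    if (any(object@score < -1e-9 | object@score > 1 + 1e-9))
      return("organization score must lie in [0, 1]")
    TRUE
  })

#' Region labels on a tessellation
#'
#' Per-cell geometric region of the seed surface: \code{flat_face} (the
#' flattened z-facing sides), \code{flank} (the narrow y-facing sides) or
#' \code{tip} (caps at the ends of the long axis).
#'
#' @slot cellId integer cell ids
#' @slot label factor with levels flat_face, flank, tip
#' @export
setClass("RegionLabels",
  representation(cellId = "integer", label = "factor"),
  validity = function(object) {
    if (length(object@label) != length(object@cellId))
      return("every cell must be labelled exactly once")
    if (!all(levels(object@label) %in% c("flat_face", "flank", "tip")))
      return("labels must be flat_face, flank or tip")
    if (anyNA(object@label)) return("every cell must be labelled")
    TRUE
  })

#' Shell material and load
#'
#' Linear elastic wall properties and internal pressure of the pressurized
#' shell. Stress directions and anisotropy on a convex pressurized membrane
#' are statically determinate to leading order, so the elastic constants
#' mainly set the displacement scale, not the stress pattern.
#'
#' @slot youngModulus Young's modulus E (MPa)
#' @slot poissonRatio Poisson ratio, in [0, 0.5)
#' @slot thickness wall thickness t (µm)
#' @slot pressure internal pressure p (MPa)
#' @export
setClass("ShellMaterial",
  representation(youngModulus = "numeric", poissonRatio = "numeric",
                 thickness = "numeric", pressure = "numeric"),
  validity = function(object) {
    if (object@youngModulus <= 0) return("young_modulus must be > 0")
    if (object@poissonRatio < 0 || object@poissonRatio >= 0.5)
      return("poisson_ratio must lie in [0, 0.5)")
    if (object@thickness <= 0) return("thickness must be > 0")
    if (object@pressure <= 0) return("pressure must be > 0")
    TRUE
  })

#' 2D fibril texture image
#'
#' Grayscale raster (first index = x, second = y, arbitrary intensity units)
#' standing in for a projected CMT signal image, with pixel size in µm/px.
#' Synthetic images record their ground-truth orientation (degrees in
#' [0, 180)) and anisotropy level.
#'
#' @slot pixels numeric matrix of intensities
#' @slot pixelSize µm per pixel
#' @slot trueOrientation ground-truth fibril axis (degrees), NA if unknown
#' @slot trueAnisotropy ground-truth anisotropy level in [0, 1], NA if unknown
#' @export
setClass("FibrilImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 trueOrientation = "numeric", trueAnisotropy = "numeric"),
  validity = function(object) {
    if (nrow(object@pixels) < 16L || ncol(object@pixels) < 16L)
      return("image must be at least 16 x 16 px")
    if (!all(is.finite(object@pixels))) return("pixel values must be finite")
    if (object@pixelSize <= 0) return("pixel size must be positive")
    TRUE
  })

#' Distribution of CMT-to-curvature angles
#'
#' Per-cell angle θ (degrees in [0, 90]) between the mean CMT axis and the
#' maximum-curvature axis, with a fixed-width histogram on [0, 90] and
#' summary statistics (median, mean, fraction below 30°).
#'
#' @slot theta per-cell θ in degrees, named by cell id
#' @slot breaks histogram bin edges on [0, 90]
#' @slot counts histogram counts (sum = number of cells with θ)
#' @slot summary list with elements median, mean, frac_below_30
#' @slot nExcluded cells missing from either input field
#' @export
setClass("AngleDistribution",
  representation(theta = "numeric", breaks = "numeric", counts = "integer",
                 summary = "list", nExcluded = "integer"),
  validity = function(object) {
    if (any(object@theta < -1e-9 | object@theta > 90 + 1e-9))
      return("theta must lie in [0, 90] degrees")
    if (sum(object@counts) != length(object@theta))
      return("histogram counts must sum to the number of cells")
    TRUE
  })
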