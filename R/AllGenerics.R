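#' @include AllClasses.R
NULL

#' Accessors for seedmech objects
#'
#' Slot access for the package's S4 containers. \code{vertices} and
#' \code{faces} return the mesh geometry; \code{faceNormals} the outward
#' unit normals; \code{nCells}, \code{cellAreas}, \code{cellCentroids} and
#' \code{faceCell} describe a tessellation; \code{principalValues},
#' \code{principalAxes} and \code{anisotropy} the per-cell tensor fields;
#' \code{orientationVectors} and \code{organizationScore} an orientation
#' field; \code{regionLabel} the per-cell region factor; \code{pixelValues}
#' the raster of a \linkS4class{FibrilImage}; \code{thetaValues} the
#' per-cell angles of an \linkS4class{AngleDistribution}.
#'
#' @param x a seedmech object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("faceNormals", function(x) standardGeneric("faceNormals"))
#' @rdname accessors
#' @export
setGeneric("faceAreas", function(x) standardGeneric("faceAreas"))
#' @rdname accessors
#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))
#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))
#' @rdname accessors
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))
#' @rdname accessors
#' @export
setGeneric("faceCell", function(x) standardGeneric("faceCell"))
#' @rdname accessors
#' @export
setGeneric("cellLineage", function(x) standardGeneric("cellLineage"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("principalValues", function(x) standardGeneric("principalValues"))
#' @rdname accessors
#' @export
setGeneric("principalAxes", function(x) standardGeneric("principalAxes"))
#' @rdname accessors
#' @export
setGeneric("anisotropy", function(x) standardGeneric("anisotropy"))
#' @rdname accessors
#' @export
setGeneric("orientationVectors", function(x) standardGeneric("orientationVectors"))
#' @rdname accessors
#' @export
setGeneric("organizationScore", function(x) standardGeneric("organizationScore"))
#' @rdname accessors
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))
#' @rdname accessors
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))
#' @rdname accessors
#' @export
setGeneric("thetaValues", function(x) standardGeneric("thetaValues"))
#' @rdname accessors
#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))

#' Convert a per-cell object to a data.frame
#'
#' @param x a seedmech field object
#' @param ... unused
#' @export
setGeneric("asDataFrame", function(x, ...) standardGeneric("asDataFrame"))
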