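#' @include AllClasses.R AllGenerics.R
NULL

## Raw per-face areas from vertex/face matrices (also used by class validity).
faceAreasRaw <- function(v, f) {
  p1 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - p1
  e2 <- v[f[, 3L], , drop = FALSE] - p1
  0.5 * rowNorms(crossProduct(e1, e2))
}

faceCentroidsRaw <- function(v, f) {
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

#' Construct a surface mesh
#'
#' Builds a \linkS4class{SurfaceMesh} from vertex coordinates and triangle
#' indices. With \code{orient = "outward"} (the default, for closed
#' star-shaped surfaces) each face winding is flipped if needed so that its
#' normal points away from the mesh centroid; \code{orient = "keep"} trusts
#' the given winding (use for open patches such as planar sheets).
#'
#' @param vertices n x 3 numeric matrix (µm)
#' @param faces m x 3 integer matrix of vertex indices
#' @param orient "outward" or "keep"
#' @return a \linkS4class{SurfaceMesh}
#' @export
surfaceMesh <- function(vertices, faces, orient = c("outward", "keep")) {
  orient <- match.arg(orient)
  vertices <- as.matrix(vertices)
  storage.mode(faces) <- "integer"
  p1 <- vertices[faces[, 1L], , drop = FALSE]
  nrm <- crossProduct(vertices[faces[, 2L], , drop = FALSE] - p1,
                      vertices[faces[, 3L], , drop = FALSE] - p1)
  len <- rowNorms(nrm)
  if (any(len == 0)) stop("degenerate face with zero area")
  nrm <- nrm / len
  if (orient == "outward") {
    ctr <- colMeans(vertices)
    out <- faceCentroidsRaw(vertices, faces) - rep(ctr, each = nrow(faces))
    flip <- rowSums(nrm * out) < 0
    if (any(flip)) {
      faces[flip, c(2L, 3L)] <- faces[flip, c(3L, 2L)]
      nrm[flip, ] <- -nrm[flip, ]
    }
  }
  new("SurfaceMesh", vertices = vertices, faces = faces, faceNormals = nrm)
}

#' Ellipsoid surface specification and mesh generation
#'
#' \code{ellipsoidSpec} validates semi-axes; \code{spec2DPA} is the default
#' seed shape at two days post anthesis: aspect ratio a/b = 1.7 with
#' thickness 15\% below width (c/b = 0.85), at an absolute scale of
#' b = 100 µm (all direction and anisotropy outputs are scale-free).
#' \code{makeEllipsoidMesh} subdivides an icosahedron \code{refinement}
#' times (face count 20 * 4^refinement), projects to the unit sphere and
#' scales anisotropically, so every vertex satisfies the ellipsoid equation
#' to machine precision and triangles stay near-uniform (no pole artifacts).
#'
#' @param a,b,c semi-axes in µm, \code{a >= b >= c > 0}
#' @return \code{ellipsoidSpec}: an \linkS4class{EllipsoidSpec}
#' @export
ellipsoidSpec <- function(a, b, c) new("EllipsoidSpec", a = a, b = b, c = c)

#' @rdname ellipsoidSpec
#' @export
spec2DPA <- function() ellipsoidSpec(170, 100, 85)

icosahedronBase <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

subdivideTriangles <- function(v, f) {
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  e <- unique(rbind(cbind(f[, 1L], f[, 2L]), cbind(f[, 2L], f[, 3L]),
                    cbind(f[, 3L], f[, 1L]))[, , drop = FALSE])
  ek <- key(e[, 1L], e[, 2L])
  keep <- !duplicated(ek)
  e <- e[keep, , drop = FALSE]; ek <- ek[keep]
  mid <- (v[e[, 1L], , drop = FALSE] + v[e[, 2L], , drop = FALSE]) / 2
  midIdx <- stats::setNames(nrow(v) + seq_len(nrow(e)), ek)
  v2 <- rbind(v, mid)
  m12 <- midIdx[key(f[, 1L], f[, 2L])]
  m23 <- midIdx[key(f[, 2L], f[, 3L])]
  m31 <- midIdx[key(f[, 3L], f[, 1L])]
  f2 <- rbind(cbind(f[, 1L], m12, m31), cbind(f[, 2L], m23, m12),
              cbind(f[, 3L], m31, m23), cbind(m12, m23, m31))
  dimnames(f2) <- NULL
  list(v = v2, f = f2)
}

#' @rdname ellipsoidSpec
#' @param spec an \linkS4class{EllipsoidSpec}
#' @param refinement icosahedral subdivision level, >= 1
#' @return \code{makeEllipsoidMesh}: a closed \linkS4class{SurfaceMesh}
#' @export
makeEllipsoidMesh <- function(spec, refinement = 4L) {
  stopifnot(is(spec, "EllipsoidSpec"))
  validObject(spec)
  if (refinement < 1L) stop("refinement must be >= 1")
  base <- icosahedronBase()
  for (i in seq_len(refinement)) {
    base <- subdivideTriangles(base$v, base$f)
    base$v <- base$v / rowNorms(base$v)   # radial projection to unit sphere
  }
  v <- base$v %*% diag(c(spec@a, spec@b, spec@c))
  surfaceMesh(v, base$f, orient = "outward")
}

#' Planar sheet mesh
#'
#' A flat rectangular triangle mesh in the z = 0 plane with +z normals,
#' used as the test substrate for in-plane cell growth analysis (the
#' near-planar flat face of the seed).
#'
#' @param width,height extents in µm, centered on the origin
#' @param nx,ny number of grid squares per side (each split in 2 triangles)
#' @return an open \linkS4class{SurfaceMesh}
#' @export
makePlanarMesh <- function(width = 100, height = 100, nx = 20L, ny = 20L) {
  stopifnot(width > 0, height > 0, nx >= 1L, ny >= 1L)
  xs <- seq(-width / 2, width / 2, length.out = nx + 1L)
  ys <- seq(-height / 2, height / 2, length.out = ny + 1L)
  v <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L), 0)
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  surfaceMesh(v, f, orient = "keep")
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("faceNormals", "SurfaceMesh", function(x) x@faceNormals)
#' @rdname accessors
#' @export
setMethod("faceAreas", "SurfaceMesh", function(x) faceAreasRaw(x@vertices, x@faces))
#' @rdname accessors
#' @export
setMethod("meshArea", "SurfaceMesh", function(x) sum(faceAreas(x)))
#' @rdname accessors
#' @export
setMethod("isClosed", "SurfaceMesh", function(x) {
  f <- x@faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
})
#' @rdname accessors
#' @export
setMethod("semiAxes", "EllipsoidSpec", function(x) c(a = x@a, b = x@b, c = x@c))

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, %s, area %.4g um^2\n",
              nrow(object@vertices), nrow(object@faces),
              if (isClosed(object)) "closed" else "open", meshArea(object)))
})

setMethod("show", "EllipsoidSpec", function(object) {
  cat(sprintf("EllipsoidSpec: a=%.4g b=%.4g c=%.4g um (a/b=%.3g, c/b=%.3g)\n",
              object@a, object@b, object@c, object@a / object@b,
              object@c / object@b))
})

#' Shell material constructor
#'
#' @param youngModulus Young's modulus E (MPa)
#' @param poissonRatio Poisson ratio in [0, 0.5)
#' @param thickness wall thickness t (µm)
#' @param pressure internal pressure p (MPa)
#' @return a \linkS4class{ShellMaterial}
#' @export
shellMaterial <- function(youngModulus = 100, poissonRatio = 0.3,
                          thickness = 1, pressure = 0.2) {
  new("ShellMaterial", youngModulus = youngModulus,
      poissonRatio = poissonRatio, thickness = thickness, pressure = pressure)
}

setMethod("show", "ShellMaterial", function(object) {
  cat(sprintf("ShellMaterial: E=%.4g MPa, nu=%.3g, t=%.4g um, p=%.4g MPa\n",
              object@youngModulus, object@poissonRatio, object@thickness,
              object@pressure))
})

## ---- mesh text IO (OBJ / ASCII PLY) ----

#' Read and write surface meshes as OBJ or ASCII PLY
#'
#' Minimal text-format mesh IO. \code{writeSurfaceMesh} picks the format
#' from the file extension (.obj or .ply); per-face cell ids, when a
#' tessellation is supplied, go to a sidecar CSV with columns
#' \code{face_id, cell_id}.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param path output file (.obj or .ply)
#' @param tess optional \linkS4class{CellTessellation} for the sidecar CSV
#' @export
writeSurfaceMesh <- function(mesh, path, tess = NULL) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh@vertices; f <- mesh@faces
  if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]))
    writeLines(lines, path)
  } else if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    writeLines(c(header,
                 sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
                 sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
               path)
  } else stop("unsupported mesh format: ", ext)
  if (!is.null(tess)) {
    utils::write.csv(data.frame(face_id = seq_along(tess@faceCell),
                                cell_id = tess@faceCell),
                     paste0(tools::file_path_sans_ext(path), "_cells.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeSurfaceMesh
#' @param orient passed to \code{\link{surfaceMesh}}
#' @export
readSurfaceMesh <- function(path, orient = "outward") {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  } else if (ext == "ply") {
    end <- which(lines == "end_header")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    v <- do.call(rbind, lapply(strsplit(lines[end + seq_len(nv)], "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(lines[end + nv + seq_len(nf)], "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
  } else stop("unsupported mesh format: ", ext)
  surfaceMesh(v, f, orient = orient)
}
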