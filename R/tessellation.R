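#' @include mesh.R
NULL

## face adjacency (faces sharing an edge) as an edge list matrix
faceAdjacency <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  fid <- rep(seq_len(nrow(f)), 3L)
  pairs <- split(fid, key)
  pairs <- pairs[lengths(pairs) == 2L]
  do.call(rbind, pairs)
}

#' Build a tessellation from a face-to-cell assignment
#'
#' Low-level constructor: computes per-cell area-weighted centroids and
#' areas from a per-face cell-id vector. Cell ids must be 1..n with every
#' id present. \code{\link{tessellateSurface}} is the usual entry point.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param faceCell integer vector assigning each face to a cell
#' @param lineage optional parent-to-offspring map (named list)
#' @return a \linkS4class{CellTessellation}
#' @export
cellTessellation <- function(mesh, faceCell, lineage = list()) {
  faceCell <- as.integer(faceCell)
  fa <- faceAreasRaw(mesh@vertices, mesh@faces)
  fc <- faceCentroidsRaw(mesh@vertices, mesh@faces)
  ids <- sort(unique(faceCell))
  areas <- vapply(ids, function(i) sum(fa[faceCell == i]), numeric(1))
  cent <- t(vapply(ids, function(i) {
    w <- fa[faceCell == i]
    colSums(fc[faceCell == i, , drop = FALSE] * w) / sum(w)
  }, numeric(3)))
  new("CellTessellation", mesh = mesh, faceCell = faceCell,
      centroids = cent, areas = areas, lineage = lineage)
}

## Reassign minority connected components so every cell is face-connected.
## `adj` is the face adjacency edge list. Faces of non-largest components are
## handed to the adjacent cell owning most of their neighboring faces.
enforceConnectivity <- function(faceCell, adj, maxIter = 100L) {
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(faceCell) - igraph::vcount(g)))
  for (iter in seq_len(maxIter)) {
    changed <- FALSE
    for (id in unique(faceCell)) {
      fset <- which(faceCell == id)
      if (length(fset) <= 1L) next
      comp <- igraph::components(igraph::induced_subgraph(g, fset))
      if (comp$no == 1L) next
      main <- which.max(comp$csize)
      stray <- fset[comp$membership != main]
      for (fi in stray) {
        nb <- c(adj[adj[, 1L] == fi, 2L], adj[adj[, 2L] == fi, 1L])
        other <- faceCell[nb][faceCell[nb] != id]
        if (length(other)) {
          faceCell[fi] <- as.integer(names(which.max(table(other))))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  faceCell
}

#' Tessellate a surface mesh into cells
#'
#' Partitions the faces of a mesh into \code{nCells} face-connected cells
#' emulating segmented epidermal cells: random surface seeds followed by
#' Lloyd-style centroidal relaxation, with faces assigned to the nearest
#' cell seed (Euclidean distance between face centroids and seed points as
#' the geodesic surrogate on a smooth surface). Deterministic for a fixed
#' \code{rngSeed}.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param nCells number of cells, between 1 and the face count
#' @param rngSeed integer RNG seed (mandatory)
#' @param relaxIters Lloyd relaxation sweeps, >= 0 (default 5)
#' @return a \linkS4class{CellTessellation}
#' @export
tessellateSurface <- function(mesh, nCells, rngSeed, relaxIters = 5L) {
  stopifnot(is(mesh, "SurfaceMesh"))
  nf <- nrow(mesh@faces)
  if (nCells > nf) stop("capacity error: more cells requested than mesh faces")
  if (nCells < 1L) stop("nCells must be >= 1")
  if (relaxIters < 0L) stop("relaxIters must be >= 0")
  fc <- faceCentroidsRaw(mesh@vertices, mesh@faces)
  fa <- faceAreasRaw(mesh@vertices, mesh@faces)
  assign0 <- withSeed(rngSeed, {
    seeds <- fc[sample.int(nf, nCells), , drop = FALSE]
    assignFaces <- function(seeds) {
      d <- matrix(0, nf, nCells)
      for (k in seq_len(nCells))
        d[, k] <- (fc[, 1L] - seeds[k, 1L])^2 + (fc[, 2L] - seeds[k, 2L])^2 +
          (fc[, 3L] - seeds[k, 3L])^2
      max.col(-d, ties.method = "first")
    }
    lab <- assignFaces(seeds)
    for (it in seq_len(relaxIters)) {
      for (k in seq_len(nCells)) {
        sel <- lab == k
        if (!any(sel)) {
          ## reseed an empty cell at the face farthest from all current seeds
          dmin <- rep(Inf, nf)
          for (j in seq_len(nCells))
            dmin <- pmin(dmin, rowSums((fc - rep(seeds[j, ], each = nf))^2))
          seeds[k, ] <- fc[which.max(dmin), ]
        } else {
          w <- fa[sel]
          seeds[k, ] <- colSums(fc[sel, , drop = FALSE] * w) / sum(w)
        }
      }
      lab <- assignFaces(seeds)
    }
    lab
  })
  ## repair empties deterministically (steal the farthest face of the largest cell)
  for (k in seq_len(nCells)) {
    if (!any(assign0 == k)) {
      big <- as.integer(names(which.max(table(assign0))))
      cand <- which(assign0 == big)
      ctr <- colMeans(fc[cand, , drop = FALSE])
      assign0[cand[which.max(rowSums((fc[cand, , drop = FALSE] -
                                        rep(ctr, each = length(cand)))^2))]] <- k
    }
  }
  adj <- faceAdjacency(mesh)
  assign0 <- enforceConnectivity(assign0, adj)
  ## relabel to 1..nCells in order of first occurrence
  assign0 <- match(assign0, unique(assign0))
  cellTessellation(mesh, assign0)
}

#' Deformed copy of a tessellation with optional cell divisions
#'
#' Produces the tessellation one timepoint later: mesh coordinates are
#' mapped by the in-plane affine stretch \code{diag(stretchX, stretchY, 1)}
#' and each cell divides into two offspring with probability
#' \code{divisionProb} (split across the cell's long axis at the median, so
#' both offspring are non-empty). The parent-to-offspring lineage is stored
#' on the returned tessellation (\code{\link{cellLineage}}). The stretch
#' ratios are recovered exactly by \code{\link{cellGrowthMap}} on planar
#' z-normal patches (see \code{\link{makePlanarMesh}}).
#'
#' @param tess a \linkS4class{CellTessellation}
#' @param stretchX,stretchY in-plane stretch factors, > 0
#' @param divisionProb per-cell division probability in [0, 1]
#' @param rngSeed integer RNG seed
#' @return a \linkS4class{CellTessellation} at t+1 carrying the lineage
#' @export
makePairedTessellation <- function(tess, stretchX, stretchY,
                                   divisionProb = 0, rngSeed = 1L) {
  stopifnot(is(tess, "CellTessellation"))
  if (stretchX <= 0 || stretchY <= 0)
    stop("invalid spec: stretch factors must be positive")
  if (divisionProb < 0 || divisionProb > 1)
    stop("invalid spec: division probability must lie in [0, 1]")
  mesh1 <- surfaceMesh(tess@mesh@vertices %*% diag(c(stretchX, stretchY, 1)),
                       tess@mesh@faces, orient = "keep")
  fc <- faceCentroidsRaw(mesh1@vertices, mesh1@faces)
  faceCell0 <- tess@faceCell
  ids <- sort(unique(faceCell0))
  divide <- withSeed(rngSeed, stats::runif(length(ids)) < divisionProb)
  adj <- faceAdjacency(mesh1)
  newLab <- integer(length(faceCell0))
  lineage <- vector("list", length(ids))
  names(lineage) <- as.character(ids)
  nxt <- 0L
  for (k in seq_along(ids)) {
    fset <- which(faceCell0 == ids[k])
    if (divide[k] && length(fset) >= 2L) {
      pts <- fc[fset, , drop = FALSE]
      pts <- sweep(pts, 2L, colMeans(pts))
      dir <- eigen(crossprod(pts), symmetric = TRUE)$vectors[, 1L]
      s <- pts %*% dir
      half <- rank(s, ties.method = "first") <= length(fset) / 2
      newLab[fset[half]] <- nxt + 1L
      newLab[fset[!half]] <- nxt + 2L
      lineage[[k]] <- c(nxt + 1L, nxt + 2L)
      nxt <- nxt + 2L
    } else {
      newLab[fset] <- nxt + 1L
      lineage[[k]] <- nxt + 1L
      nxt <- nxt + 1L
    }
  }
  ## keep offspring face-connected without crossing parent boundaries
  for (k in seq_along(ids)) {
    if (length(lineage[[k]]) == 2L) {
      fset <- which(faceCell0 == ids[k])
      sub <- adj[adj[, 1L] %in% fset & adj[, 2L] %in% fset, , drop = FALSE]
      fixed <- enforceConnectivity(newLab[fset],
                                   cbind(match(sub[, 1L], fset),
                                         match(sub[, 2L], fset)))
      if (length(unique(fixed)) == 2L) newLab[fset] <- fixed
    }
  }
  cellTessellation(mesh1, newLab, lineage = lineage)
}

## ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("nCells", "CellTessellation", function(x) length(x@areas))
#' @rdname accessors
#' @export
setMethod("cellAreas", "CellTessellation", function(x) x@areas)
#' @rdname accessors
#' @export
setMethod("cellCentroids", "CellTessellation", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("faceCell", "CellTessellation", function(x) x@faceCell)
#' @rdname accessors
#' @export
setMethod("cellLineage", "CellTessellation", function(x) x@lineage)
#' @rdname accessors
#' @export
setMethod("vertices", "CellTessellation", function(x) x@mesh@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "CellTessellation", function(x) x@mesh@faces)

setMethod("show", "CellTessellation", function(object) {
  cat(sprintf("CellTessellation: %d cells on %d faces, total area %.4g um^2%s\n",
              nCells(object), length(object@faceCell), sum(object@areas),
              if (length(object@lineage)) ", with lineage" else ""))
})

## per-cell area-weighted unit normal
cellNormals <- function(tess) {
  fa <- faceAreasRaw(tess@mesh@vertices, tess@mesh@faces)
  fn <- tess@mesh@faceNormals
  ids <- seq_len(nCells(tess))
  n <- t(vapply(ids, function(i) {
    sel <- tess@faceCell == i
    colSums(fn[sel, , drop = FALSE] * fa[sel])
  }, numeric(3)))
  normalizeRows(n)
}
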