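#' @include tessellation.R shell-fem.R
NULL

#' Per-cell principal curvature estimation
#'
#' Estimates the curvature tensor of each cell by least-squares fitting a
#' quadric height function \eqn{z = z_0 + Dx + Ey + (Ax^2 + 2Bxy + Cy^2)/2}
#' in the cell's tangent frame to all mesh vertices within
#' \code{neighborhoodRadius} of the cell centroid, with distances measured
#' along the surface (shortest paths on the edge graph; set
#' \code{distance = "euclidean"} for a straight-line radius instead). The
#' shape operator of the fitted quadric is eigen-decomposed into principal
#' curvatures \eqn{\kappa_{max} \ge \kappa_{min}} (positive on a convex
#' surface with outward normals: a sphere has \eqn{\kappa = +1/R}) and
#' tangent axes. Curvature anisotropy is
#' \eqn{(\kappa_{max}-\kappa_{min})/(|\kappa_{max}|+|\kappa_{min}|)}.
#'
#' The neighborhood radius plays the role of the cell-scale smoothing
#' window (30 µm for 2-days-post-anthesis seeds, 60 µm at 5 DPA, matching
#' the distance from a cell center to the far edge of its direct neighbors).
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param tess a \linkS4class{CellTessellation} on \code{mesh}
#' @param neighborhoodRadius fitting radius in µm, > 2 mean edge lengths
#' @param distance "geodesic" (edge-graph shortest path) or "euclidean"
#' @return a \linkS4class{CurvatureField} (1/µm)
#' @export
estimateCurvature <- function(mesh, tess, neighborhoodRadius,
                              distance = c("geodesic", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(is(mesh, "SurfaceMesh"), is(tess, "CellTessellation"))
  v <- mesh@vertices; f <- mesh@faces
  e <- unique(cbind(pmin(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 1L],
                         rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 2L]),
                    pmax(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 1L],
                         rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 2L])))
  elen <- rowNorms(v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE])
  if (neighborhoodRadius <= 2 * mean(elen))
    stop("precondition error: neighborhoodRadius must exceed 2 mean edge lengths")
  ctr <- tess@centroids
  nrm <- cellNormals(tess)
  nc <- nCells(tess)
  ## source vertex per cell: mesh vertex nearest the cell centroid
  src <- vapply(seq_len(nc), function(i)
    which.min(colSums((t(v) - ctr[i, ])^2)), integer(1))
  if (distance == "geodesic") {
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < nrow(v))
      g <- igraph::add_vertices(g, nrow(v) - igraph::vcount(g))
    dmat <- igraph::distances(g, v = src, weights = elen)
  } else {
    dmat <- t(vapply(seq_len(nc), function(i)
      sqrt(colSums((t(v) - ctr[i, ])^2)), numeric(nrow(v))))
  }
  k1 <- numeric(nc); k2 <- numeric(nc)
  ax1 <- matrix(0, nc, 3L); ax2 <- matrix(0, nc, 3L)
  for (i in seq_len(nc)) {
    sel <- which(dmat[i, ] <= neighborhoodRadius)
    if (length(sel) < 6L)
      stop(sprintf("underdetermined fit: cell %d has %d vertices within radius",
                   i, length(sel)))
    fr <- tangentFrame(nrm[i, ])
    rel <- sweep(v[sel, , drop = FALSE], 2L, ctr[i, ])
    x <- rel %*% fr$e1; y <- rel %*% fr$e2; z <- rel %*% fr$n
    X <- cbind(1, x, y, x^2 / 2, x * y, y^2 / 2)
    beta <- qr.coef(qr(X), z)
    g2 <- c(beta[2L], beta[3L])
    H <- matrix(c(beta[4L], beta[5L], beta[5L], beta[6L]), 2L, 2L)
    I1 <- diag(2L) + tcrossprod(g2)
    II <- H / sqrt(1 + sum(g2^2))
    W <- solve(I1, II)
    M <- -(W + t(W)) / 2          # sign: outward-normal convex => kappa > 0
    eg <- eigen(M, symmetric = TRUE)
    k1[i] <- eg$values[1L]; k2[i] <- eg$values[2L]
    a1 <- eg$vectors[, 1L]; a2 <- eg$vectors[, 2L]
    ax1[i, ] <- a1[1L] * fr$e1 + a1[2L] * fr$e2
    ax2[i, ] <- a2[1L] * fr$e1 + a2[2L] * fr$e2
  }
  den <- abs(k1) + abs(k2)
  ani <- ifelse(den > 0, (k1 - k2) / den, NA_real_)
  new("CurvatureField", cellId = seq_len(nc), value1 = k1, value2 = k2,
      axis1 = normalizeRows(ax1), axis2 = normalizeRows(ax2),
      anisotropy = ani, neighborhoodRadius = neighborhoodRadius)
}

#' Analytic principal curvatures of an ellipsoid
#'
#' Exact principal curvatures and directions at a point of the ellipsoid
#' \eqn{(x/a)^2 + (y/b)^2 + (z/c)^2 = 1}, from the shape operator
#' \eqn{S = P\,G\,P / |Gx|} on the tangent plane (\eqn{G =
#' \mathrm{diag}(1/a^2, 1/b^2, 1/c^2)}, \eqn{P} the tangent projector).
#' Positive for the outward normal. The independent oracle for
#' \code{\link{estimateCurvature}}.
#'
#' @param spec an \linkS4class{EllipsoidSpec}
#' @param point 3D position on the ellipsoid (within 1e-6 relative)
#' @return list with \code{kappaMax}, \code{kappaMin}, \code{axisMax},
#'   \code{axisMin}
#' @export
ellipsoidCurvatureOracle <- function(spec, point) {
  stopifnot(is(spec, "EllipsoidSpec"), length(point) == 3L)
  G <- c(1 / spec@a^2, 1 / spec@b^2, 1 / spec@c^2)
  val <- sum(G * point^2)
  if (abs(val - 1) > 1e-6)
    stop("projection error: point is not on the ellipsoid surface")
  gx <- G * point
  n <- gx / sqrt(sum(gx^2))
  fr <- tangentFrame(n)
  Tb <- cbind(fr$e1, fr$e2)
  M <- t(Tb) %*% diag(G) %*% Tb / sqrt(sum(gx^2))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(kappaMax = eg$values[1L], kappaMin = eg$values[2L],
       axisMax = as.numeric(Tb %*% eg$vectors[, 1L]),
       axisMin = as.numeric(Tb %*% eg$vectors[, 2L]))
}
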