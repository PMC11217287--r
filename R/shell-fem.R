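#' @include tessellation.R
NULL

## Closed-form eigen-decomposition of per-row symmetric 2x2 tensors given in
## a local tangent frame; returns principal values (v1 >= v2) and 3D axes.
tangentEigen <- function(m11, m22, m12, e1, e2) {
  mean2 <- (m11 + m22) / 2
  r <- sqrt(((m11 - m22) / 2)^2 + m12^2)
  phi <- 0.5 * atan2(2 * m12, m11 - m22)
  ax1 <- e1 * cos(phi) + e2 * sin(phi)
  ax2 <- -e1 * sin(phi) + e2 * cos(phi)
  list(v1 = mean2 + r, v2 = mean2 - r, axis1 = ax1, axis2 = ax2)
}

## Symmetric 3D tensors (rows: xx yy zz xy xz yz) projected onto the tangent
## plane of each row's unit normal and eigen-decomposed.
projectAndEigen <- function(tensors, normals) {
  n <- nrow(tensors)
  e1 <- matrix(0, n, 3L); e2 <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    fr <- tangentFrame(normals[i, ])
    e1[i, ] <- fr$e1; e2[i, ] <- fr$e2
  }
  applyTensor <- function(u, w) {
    tensors[, 1L] * u[, 1L] * w[, 1L] + tensors[, 2L] * u[, 2L] * w[, 2L] +
      tensors[, 3L] * u[, 3L] * w[, 3L] +
      tensors[, 4L] * (u[, 1L] * w[, 2L] + u[, 2L] * w[, 1L]) +
      tensors[, 5L] * (u[, 1L] * w[, 3L] + u[, 3L] * w[, 1L]) +
      tensors[, 6L] * (u[, 2L] * w[, 3L] + u[, 3L] * w[, 2L])
  }
  tangentEigen(applyTensor(e1, e1), applyTensor(e2, e2), applyTensor(e1, e2),
               e1, e2)
}

## Pick three mutually distant vertices and build the sparse rigid-body
## constraint basis: vertex 1 fully fixed, vertex 2 free only along the line
## to vertex 1, vertex 3 free only within the plane of the three.
rigidConstraintBasis <- function(v, pick = NULL) {
  nv <- nrow(v)
  if (is.null(pick)) {
    v1 <- which.max(v[, 1L])
    d1 <- rowSums(sweep(v, 2L, v[v1, ])^2)
    v2 <- which.max(d1)
    dvec <- v[v2, ] - v[v1, ]
    dhat <- dvec / sqrt(sum(dvec^2))
    rel <- sweep(v, 2L, v[v1, ])
    perp <- rel - (rel %*% dhat) %*% t(dhat)
    v3 <- which.max(rowSums(perp^2))
  } else { v1 <- pick[1L]; v2 <- pick[2L]; v3 <- pick[3L] }
  dvec <- v[v2, ] - v[v1, ]
  dhat <- dvec / sqrt(sum(dvec^2))
  w <- crossProduct(dvec, v[v3, ] - v[v1, ])[1L, ]
  w <- w / sqrt(sum(w^2))                   # plane normal at vertex 3
  fr3 <- tangentFrame(w)                    # m1, m2 span the allowed plane
  iT <- integer(0); jT <- integer(0); xT <- numeric(0); colN <- 0L
  addCol <- function(rows, vals) {
    colN <<- colN + 1L
    iT <<- c(iT, rows); jT <<- c(jT, rep(colN, length(rows))); xT <<- c(xT, vals)
  }
  special <- c(v1, v2, v3)
  for (vi in seq_len(nv)) {
    base <- 3L * (vi - 1L)
    if (!(vi %in% special)) {
      for (d in 1:3) addCol(base + d, 1)
    } else if (vi == v2) {
      addCol(base + 1:3, dhat)
    } else if (vi == v3) {
      addCol(base + 1:3, fr3$e1)
      addCol(base + 1:3, fr3$e2)
    } # v1: fully fixed, no columns
  }
  Matrix::sparseMatrix(i = iT, j = jT, x = xT, dims = c(3L * nv, colN))
}

## Reference-configuration element geometry shared by the linear and the
## finite-strain membrane solvers: local CST shape-function gradients
## (b, c coefficients), areas and global dof indices.
femGeometry <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces; nrm <- mesh@faceNormals
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- normalizeRows(p2 - p1)
  e2 <- crossProduct(nrm, e1)
  x2 <- rowNorms(p2 - p1)
  x3 <- rowSums((p3 - p1) * e1)
  y3 <- rowSums((p3 - p1) * e2)
  A <- 0.5 * x2 * y3
  if (any(A <= 0)) stop("conditioning error: inconsistent face orientation")
  dofIdx <- matrix(0L, nrow(f), 9L)
  for (a in 1:3) for (d in 1:3)
    dofIdx[, 3L * (a - 1L) + d] <- 3L * (f[, a] - 1L) + d
  list(v = v, f = f, nrm = nrm, e1 = e1, e2 = e2, A = A,
       b = cbind(-y3, y3, 0), cc = cbind(x3 - x2, -x3, x2), dofIdx = dofIdx)
}

accumulateDof <- function(vals, idx, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

#' Finite inflation of a closed membrane shell
#'
#' Inflates a closed triangulated membrane under internal pressure by a
#' total-Lagrangian finite-strain solve: constant-strain triangles with a
#' St.Venant–Kirchhoff plane-stress law, follower pressure on the deformed
#' faces, Newton iteration under load ramping, rigid-body modes constrained
#' as in \code{\link{solveMembraneStress}}. Returns the inflated
#' configuration; the membrane stress carried in that configuration is
#' statically determinate and is obtained by running
#' \code{\link{solveMembraneStress}} on the returned mesh (done internally
#' by \code{configuration = "inflated"}).
#'
#' @param mesh a closed \linkS4class{SurfaceMesh} (reference configuration)
#' @param material a \linkS4class{ShellMaterial}; the ratio p/(tE) sets the
#'   inflation magnitude
#' @param steps pressure ramp steps
#' @param maxIter Newton iterations per step
#' @param tol relative residual tolerance
#' @return the inflated \linkS4class{SurfaceMesh}, with the displacement
#'   field in the \code{"displacement"} attribute
#' @export
inflateShell <- function(mesh, material, steps = 4L, maxIter = 30L,
                         tol = 1e-8) {
  stopifnot(is(mesh, "SurfaceMesh"), is(material, "ShellMaterial"))
  if (!isClosed(mesh))
    stop("topology error: inflation requires a closed mesh")
  g <- femGeometry(mesh)
  nv <- nrow(g$v); nf <- nrow(g$f)
  E <- material@youngModulus; nu <- material@poissonRatio
  th <- material@thickness
  D0 <- E / (1 - nu^2)
  D11 <- D0; D12 <- D0 * nu; D33 <- D0 * (1 - nu) / 2
  Cb <- rigidConstraintBasis(g$v)
  inv2A <- 1 / (2 * g$A)
  u <- matrix(0, nv, 3L)

  internalState <- function(x) {
    F1 <- (x[g$f[, 1L], ] * g$b[, 1L] + x[g$f[, 2L], ] * g$b[, 2L] +
             x[g$f[, 3L], ] * g$b[, 3L]) * inv2A
    F2 <- (x[g$f[, 1L], ] * g$cc[, 1L] + x[g$f[, 2L], ] * g$cc[, 2L] +
             x[g$f[, 3L], ] * g$cc[, 3L]) * inv2A
    E11 <- (rowSums(F1 * F1) - 1) / 2
    E22 <- (rowSums(F2 * F2) - 1) / 2
    G12 <- rowSums(F1 * F2)
    list(F1 = F1, F2 = F2,
         S11 = D11 * E11 + D12 * E22, S22 = D12 * E11 + D11 * E22,
         S12 = D33 * G12)
  }

  followerLoad <- function(x, p) {
    an <- 0.5 * crossProduct(x[g$f[, 2L], ] - x[g$f[, 1L], ],
                             x[g$f[, 3L], ] - x[g$f[, 1L], ])  # area * normal
    Fv <- numeric(3L * nv)
    for (a in 1:3) for (d in 1:3)
      Fv <- Fv + accumulateDof(p * an[, d] / 3,
                               g$dofIdx[, 3L * (a - 1L) + d], 3L * nv)
    Fv
  }

  strainRows <- function(st) {
    M1 <- matrix(0, nf, 9L); M2 <- matrix(0, nf, 9L); M3 <- matrix(0, nf, 9L)
    for (a in 1:3) for (d in 1:3) {
      col <- 3L * (a - 1L) + d
      M1[, col] <- g$b[, a] * st$F1[, d] * inv2A
      M2[, col] <- g$cc[, a] * st$F2[, d] * inv2A
      M3[, col] <- (g$cc[, a] * st$F1[, d] + g$b[, a] * st$F2[, d]) * inv2A
    }
    list(M1 = M1, M2 = M2, M3 = M3)
  }

  internalForce <- function(st, M) {
    scale <- g$A * th
    fint <- numeric(3L * nv)
    for (col in 1:9)
      fint <- fint + accumulateDof(
        scale * (M$M1[, col] * st$S11 + M$M2[, col] * st$S22 +
                   M$M3[, col] * st$S12),
        g$dofIdx[, col], 3L * nv)
    fint
  }

  assemble <- function(st) {
    M <- strainRows(st)
    M1 <- M$M1; M2 <- M$M2; M3 <- M$M3
    scale <- g$A * th
    fint <- internalForce(st, M)
    nTrip <- 81L * nf + 27L * nf
    iT <- integer(nTrip); jT <- integer(nTrip); xT <- numeric(nTrip)
    pos <- 0L
    for (i in 1:9) for (j in 1:9) {
      kij <- scale * (D11 * (M1[, i] * M1[, j] + M2[, i] * M2[, j]) +
                      D12 * (M1[, i] * M2[, j] + M2[, i] * M1[, j]) +
                      D33 * M3[, i] * M3[, j])
      iT[pos + seq_len(nf)] <- g$dofIdx[, i]
      jT[pos + seq_len(nf)] <- g$dofIdx[, j]
      xT[pos + seq_len(nf)] <- kij
      pos <- pos + nf
    }
    ## geometric stiffness: (grad_a . S grad_b) I3
    for (a in 1:3) for (bb in 1:3) {
      sab <- scale * inv2A^2 *
        (g$b[, a] * g$b[, bb] * st$S11 + g$cc[, a] * g$cc[, bb] * st$S22 +
           (g$b[, a] * g$cc[, bb] + g$cc[, a] * g$b[, bb]) * st$S12)
      for (d in 1:3) {
        iT[pos + seq_len(nf)] <- g$dofIdx[, 3L * (a - 1L) + d]
        jT[pos + seq_len(nf)] <- g$dofIdx[, 3L * (bb - 1L) + d]
        xT[pos + seq_len(nf)] <- sab
        pos <- pos + nf
      }
    }
    K <- Matrix::sparseMatrix(i = iT, j = jT, x = xT,
                              dims = c(3L * nv, 3L * nv))
    list(fint = fint, K = K)
  }

  for (s in seq_len(steps)) {
    pcur <- material@pressure * s / steps
    for (it in seq_len(maxIter)) {
      x <- g$v + u
      st <- internalState(x)
      asm <- assemble(st)
      Fp <- followerLoad(x, pcur)
      r <- as.numeric(Matrix::t(Cb) %*% (asm$fint - Fp))
      fref <- sqrt(sum(as.numeric(Matrix::t(Cb) %*% Fp)^2))
      if (sqrt(sum(r^2)) < tol * max(fref, 1e-12)) break
      Kr <- Matrix::t(Cb) %*% asm$K %*% Cb
      du <- tryCatch(as.numeric(Cb %*% Matrix::solve(Kr, -r)),
                     error = function(e)
                       stop("conditioning error: inflation tangent singular"))
      ## backtracking on the residual norm
      r0 <- sqrt(sum(r^2)); alpha <- 1
      repeat {
        uTry <- u + alpha * matrix(du, nv, 3L, byrow = TRUE)
        xT2 <- g$v + uTry
        stT <- internalState(xT2)
        rT <- as.numeric(Matrix::t(Cb) %*%
                           (internalForce(stT, strainRows(stT)) -
                              followerLoad(xT2, pcur)))
        if (sqrt(sum(rT^2)) < r0 || alpha < 0.1) break
        alpha <- alpha / 2
      }
      u <- u + alpha * matrix(du, nv, 3L, byrow = TRUE)
      if (it == maxIter)
        warning("inflation Newton did not fully converge at step ", s)
    }
  }
  out <- surfaceMesh(g$v + u, g$f, orient = "keep")
  attr(out, "displacement") <- u
  out
}

#' Membrane stress on a pressurized closed shell
#'
#' Small-strain linear membrane finite-element solution (constant-strain
#' triangles, plane stress) on the given closed surface under a uniform
#' dead pressure load along the outward face normals. Rigid-body modes are
#' removed by fixing six degrees of freedom on three mutually distant
#' vertices; on a convex triangulated shell the remaining system is
#' positive definite (convex triangulated polyhedra are infinitesimally
#' rigid), and the computed stress pattern is insensitive to the constraint
#' choice and to the Young's modulus (a pressurized convex membrane is
#' statically determinate to leading order). Per-face plane-stress tensors
#' are rotated to the tangent frame and eigen-decomposed; with a
#' tessellation, per-cell tensors are the area-weighted means of the face
#' tensors before eigen-decomposition. Stress anisotropy is
#' \eqn{(\sigma_1-\sigma_2)/(\sigma_1+\sigma_2)}.
#'
#' With \code{configuration = "inflated"} the mesh is first inflated to the
#' finite-strain equilibrium (\code{\link{inflateShell}}) and the reported
#' field is the statically determinate membrane stress carried by the
#' inflated shape; the flattened faces of a seed-shaped shell then carry
#' circumferential ("hoop") major stress, as an inflated shell does.
#'
#' @param mesh a closed \linkS4class{SurfaceMesh}
#' @param material a \linkS4class{ShellMaterial}
#' @param tess optional \linkS4class{CellTessellation}; if supplied the field
#'   is per cell, otherwise per face
#' @param constraintVertices optional integer triple overriding the automatic
#'   choice of constrained vertices (used to verify constraint independence)
#' @param configuration "reference" (small-strain solve on the given shape)
#'   or "inflated" (stress on the finite-inflation equilibrium shape)
#' @return a \linkS4class{StressField} (values in MPa); for
#'   \code{"inflated"}, the deformed mesh is in the \code{"inflatedMesh"}
#'   attribute
#' @export
solveMembraneStress <- function(mesh, material, tess = NULL,
                                constraintVertices = NULL,
                                configuration = c("reference", "inflated")) {
  configuration <- match.arg(configuration)
  stopifnot(is(mesh, "SurfaceMesh"), is(material, "ShellMaterial"))
  validObject(material)
  if (!isClosed(mesh))
    stop("topology error: membrane solve requires a closed mesh")
  if (configuration == "inflated") {
    infl <- inflateShell(mesh, material)
    tessI <- if (is.null(tess)) NULL else
      cellTessellation(infl, tess@faceCell, lineage = tess@lineage)
    out <- solveMembraneStress(infl, material, tessI, constraintVertices,
                               configuration = "reference")
    attr(out, "inflatedMesh") <- infl
    return(out)
  }
  v <- mesh@vertices; f <- mesh@faces; nrm <- mesh@faceNormals
  nv <- nrow(v); nf <- nrow(f)
  E <- material@youngModulus; nu <- material@poissonRatio
  th <- material@thickness; p <- material@pressure

  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- normalizeRows(p2 - p1)
  e2 <- crossProduct(nrm, e1)
  x2 <- rowNorms(p2 - p1)
  x3 <- rowSums((p3 - p1) * e1)
  y3 <- rowSums((p3 - p1) * e2)
  A <- 0.5 * x2 * y3
  if (any(A <= 0)) stop("conditioning error: inconsistent face orientation")
  b <- cbind(-y3, y3, 0)
  cc <- cbind(x3 - x2, -x3, x2)

  ## strain-displacement rows (3 strain components x 9 global dofs per face)
  BT1 <- matrix(0, nf, 9L); BT2 <- matrix(0, nf, 9L); BT3 <- matrix(0, nf, 9L)
  inv2A <- 1 / (2 * A)
  for (a in 1:3) for (d in 1:3) {
    col <- 3L * (a - 1L) + d
    BT1[, col] <- b[, a] * e1[, d] * inv2A
    BT2[, col] <- cc[, a] * e2[, d] * inv2A
    BT3[, col] <- (cc[, a] * e1[, d] + b[, a] * e2[, d]) * inv2A
  }
  D0 <- E / (1 - nu^2)
  D11 <- D0; D12 <- D0 * nu; D33 <- D0 * (1 - nu) / 2
  scale <- A * th

  dofIdx <- matrix(0L, nf, 9L)
  for (a in 1:3) for (d in 1:3)
    dofIdx[, 3L * (a - 1L) + d] <- 3L * (f[, a] - 1L) + d

  iT <- integer(81L * nf); jT <- integer(81L * nf); xT <- numeric(81L * nf)
  pos <- 0L
  for (i in 1:9) for (j in 1:9) {
    kij <- scale * (D11 * (BT1[, i] * BT1[, j] + BT2[, i] * BT2[, j]) +
                    D12 * (BT1[, i] * BT2[, j] + BT2[, i] * BT1[, j]) +
                    D33 * BT3[, i] * BT3[, j])
    iT[pos + seq_len(nf)] <- dofIdx[, i]
    jT[pos + seq_len(nf)] <- dofIdx[, j]
    xT[pos + seq_len(nf)] <- kij
    pos <- pos + nf
  }
  K <- Matrix::sparseMatrix(i = iT, j = jT, x = xT, dims = c(3L * nv, 3L * nv))

  ## consistent nodal load: p * A * n / 3 to each corner (indices repeat
  ## across faces, so accumulate with rowsum, not vectorized assignment)
  Fv <- numeric(3L * nv)
  for (a in 1:3) for (d in 1:3) {
    acc <- rowsum(p * A * nrm[, d] / 3, 3L * (f[, a] - 1L) + d)
    Fv[as.integer(rownames(acc))] <- Fv[as.integer(rownames(acc))] + acc[, 1L]
  }

  C <- rigidConstraintBasis(v, pick = constraintVertices)
  Kr <- Matrix::t(C) %*% K %*% C
  fr <- as.numeric(Matrix::t(C) %*% Fv)
  ur <- Matrix::solve(Kr, fr)
  u <- as.numeric(C %*% ur)

  ue <- matrix(u[dofIdx], nf, 9L)
  eps1 <- rowSums(BT1 * ue)
  eps2 <- rowSums(BT2 * ue)
  eps3 <- rowSums(BT3 * ue)
  s11 <- D11 * eps1 + D12 * eps2
  s22 <- D12 * eps1 + D11 * eps2
  s12 <- D33 * eps3

  ## per-face 3D stress tensors (xx yy zz xy xz yz)
  tens <- cbind(
    s11 * e1[, 1L]^2 + s22 * e2[, 1L]^2 + 2 * s12 * e1[, 1L] * e2[, 1L],
    s11 * e1[, 2L]^2 + s22 * e2[, 2L]^2 + 2 * s12 * e1[, 2L] * e2[, 2L],
    s11 * e1[, 3L]^2 + s22 * e2[, 3L]^2 + 2 * s12 * e1[, 3L] * e2[, 3L],
    s11 * e1[, 1L] * e1[, 2L] + s22 * e2[, 1L] * e2[, 2L] +
      s12 * (e1[, 1L] * e2[, 2L] + e1[, 2L] * e2[, 1L]),
    s11 * e1[, 1L] * e1[, 3L] + s22 * e2[, 1L] * e2[, 3L] +
      s12 * (e1[, 1L] * e2[, 3L] + e1[, 3L] * e2[, 1L]),
    s11 * e1[, 2L] * e1[, 3L] + s22 * e2[, 2L] * e2[, 3L] +
      s12 * (e1[, 2L] * e2[, 3L] + e1[, 3L] * e2[, 2L]))

  if (is.null(tess)) {
    ids <- seq_len(nf)
    normals <- nrm
  } else {
    stopifnot(identical(tess@mesh@faces, mesh@faces))
    ids <- seq_len(nCells(tess))
    fa <- A
    tens <- t(vapply(ids, function(ci) {
      sel <- tess@faceCell == ci
      colSums(tens[sel, , drop = FALSE] * fa[sel]) / sum(fa[sel])
    }, numeric(6)))
    normals <- cellNormals(tess)
  }
  eig <- projectAndEigen(tens, normals)
  tot <- eig$v1 + eig$v2
  ani <- ifelse(tot > 0, (eig$v1 - eig$v2) / tot, NA_real_)
  out <- new("StressField", cellId = as.integer(ids), value1 = eig$v1,
             value2 = eig$v2, axis1 = eig$axis1, axis2 = eig$axis2,
             anisotropy = ani)
  attr(out, "displacement") <- matrix(u, ncol = 3L, byrow = TRUE)
  out
}

#' Closed-form membrane stresses on a spheroid
#'
#' Static-equilibrium membrane-theory stresses for a pressurized spheroid of
#' revolution about its \code{a}-axis, at a given latitude (0° at the
#' equator, ±90° at the poles on the a-axis):
#' \deqn{\sigma_m = p R_2 / (2 t), \quad
#'       \sigma_h = (p R_2 / t)\,(1 - R_2 / (2 R_1))}
#' with \eqn{R_1 = a^2 b^2 q^3} and \eqn{R_2 = b^2 q} the meridional and
#' normal-section curvature radii, \eqn{q = \sqrt{\sin^2\lambda/a^2 +
#' \cos^2\lambda/b^2}}. Both formulas are smooth up to the poles, where
#' \eqn{R_1 = R_2 = b^2/a} and \eqn{\sigma_m = \sigma_h = p\,(b^2/a)/(2t)}
#' is returned explicitly. Serves as the independent oracle for
#' \code{\link{solveMembraneStress}}.
#'
#' @param a semi-axis of revolution (µm)
#' @param b equatorial semi-axis (µm)
#' @param material a \linkS4class{ShellMaterial} (only t and p are used)
#' @param latitudeDeg latitude in degrees, in [-90, 90]
#' @return named vector \code{c(sigma_meridional, sigma_hoop)} in MPa
#' @export
spheroidStressOracle <- function(a, b, material, latitudeDeg) {
  stopifnot(a > 0, b > 0, is(material, "ShellMaterial"))
  if (abs(latitudeDeg) > 90) stop("domain error: latitude must lie in [-90, 90]")
  p <- material@pressure; th <- material@thickness
  lam <- latitudeDeg * pi / 180
  q <- sqrt(sin(lam)^2 / a^2 + cos(lam)^2 / b^2)
  R1 <- a^2 * b^2 * q^3
  R2 <- b^2 * q
  if (abs(latitudeDeg) == 90) {
    s <- p * (b^2 / a) / (2 * th)
    return(c(sigma_meridional = s, sigma_hoop = s))
  }
  c(sigma_meridional = p * R2 / (2 * th),
    sigma_hoop = (p * R2 / th) * (1 - R2 / (2 * R1)))
}

## ---- field accessors & show ----

#' @rdname accessors
#' @export
setMethod("cellIds", "TangentTensorField", function(x) x@cellId)
#' @rdname accessors
#' @export
setMethod("principalValues", "TangentTensorField",
          function(x) cbind(v1 = x@value1, v2 = x@value2))
#' @rdname accessors
#' @export
setMethod("principalAxes", "TangentTensorField",
          function(x) list(axis1 = x@axis1, axis2 = x@axis2))
#' @rdname accessors
#' @export
setMethod("anisotropy", "TangentTensorField", function(x) x@anisotropy)

setMethod("show", "TangentTensorField", function(object) {
  cat(sprintf("%s: %d cells, values [%.4g, %.4g], median anisotropy %.3g\n",
              class(object), length(object@cellId),
              min(object@value2, na.rm = TRUE), max(object@value1, na.rm = TRUE),
              stats::median(object@anisotropy, na.rm = TRUE)))
})

#' @rdname asDataFrame
#' @export
setMethod("asDataFrame", "TangentTensorField", function(x, ...) {
  data.frame(cell_id = x@cellId, s1 = x@value1, s2 = x@value2,
             anisotropy = x@anisotropy,
             axis1_x = x@axis1[, 1L], axis1_y = x@axis1[, 2L],
             axis1_z = x@axis1[, 3L],
             axis2_x = x@axis2[, 1L], axis2_y = x@axis2[, 2L],
             axis2_z = x@axis2[, 3L])
})
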