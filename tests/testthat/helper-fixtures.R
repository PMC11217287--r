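## Shared fixtures, computed lazily and cached for the whole run (the FEM
## solves are the expensive pieces; everything is deterministic).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

sphereMesh4 <- function() fixture("sphereMesh4",
  makeEllipsoidMesh(ellipsoidSpec(100, 100, 100), 4))

sphereStress4 <- function() fixture("sphereStress4",
  solveMembraneStress(sphereMesh4(), shellMaterial()))

spheroidMesh4 <- function() fixture("spheroidMesh4",
  makeEllipsoidMesh(ellipsoidSpec(170, 100, 100), 4))

spheroidStress4 <- function() fixture("spheroidStress4",
  solveMembraneStress(spheroidMesh4(), shellMaterial()))

triMesh4 <- function() fixture("triMesh4", makeEllipsoidMesh(spec2DPA(), 4))

triTess <- function() fixture("triTess", tessellateSurface(triMesh4(), 300L, 42L))

## inflated-configuration stress on the 2DPA shell, per cell (the expensive
## model-prediction fixture shared by the correlation and region tests)
triStressInflated <- function() fixture("triStressInflated",
  solveMembraneStress(triMesh4(), shellMaterial(), triTess(),
                      configuration = "inflated"))

triInflatedCurvature <- function() fixture("triInflatedCurvature", {
  infl <- attr(triStressInflated(), "inflatedMesh")
  estimateCurvature(infl, cellTessellation(infl, faceCell(triTess())), 30)
})

triRegions <- function() fixture("triRegions",
  classifyRegions(triMesh4(), triTess(), spec2DPA()))

## uniform-curvature scaffold for axial-statistics tests: 1000 cells in the
## z = 0 tangent plane with the max-curvature axis along x
flatCurvatureField <- function(n = 1000L) {
  new("CurvatureField", cellId = seq_len(n),
      value1 = rep(1, n), value2 = rep(0, n),
      axis1 = matrix(rep(c(1, 0, 0), each = n), ncol = 3L),
      axis2 = matrix(rep(c(0, 1, 0), each = n), ncol = 3L),
      anisotropy = rep(1, n), neighborhoodRadius = 0)
}

## bilinear rotation about the image center (explicit geometry, so rotated
## and original measurements sample the same texture patch)
rotateImageBilinear <- function(img, deg) {
  n <- nrow(img); m <- ncol(img)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  th <- deg * pi / 180
  xs <- rep(seq_len(n), m) - cx
  ys <- rep(seq_len(m), each = n) - cy
  xo <- cos(th) * xs + sin(th) * ys + cx
  yo <- -sin(th) * xs + cos(th) * ys + cy
  x0 <- floor(xo); y0 <- floor(yo)
  ok <- x0 >= 1 & x0 < n & y0 >= 1 & y0 < m
  fx <- xo - x0; fy <- yo - y0
  idx <- function(i, j) (j - 1) * n + i
  v <- numeric(n * m)
  v[ok] <- img[idx(x0[ok], y0[ok])] * (1 - fx[ok]) * (1 - fy[ok]) +
    img[idx(x0[ok] + 1, y0[ok])] * fx[ok] * (1 - fy[ok]) +
    img[idx(x0[ok], y0[ok] + 1)] * (1 - fx[ok]) * fy[ok] +
    img[idx(x0[ok] + 1, y0[ok] + 1)] * fx[ok] * fy[ok]
  matrix(v, n, m)
}

centralDiskMask <- function(n, radius) {
  m <- matrix(FALSE, n, n)
  xs <- row(m) - (n + 1) / 2
  ys <- col(m) - (n + 1) / 2
  m[xs^2 + ys^2 < radius^2] <- TRUE
  m
}

axialDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
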