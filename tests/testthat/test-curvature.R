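test_that("ellipsoid curvature oracle matches closed forms", {
  o <- ellipsoidCurvatureOracle(ellipsoidSpec(100, 100, 100), c(0, 0, 100))
  expect_equal(o$kappaMax, 0.01)
  expect_equal(o$kappaMin, 0.01)
  ## prolate pole is umbilic with curvature a/b^2
  o2 <- ellipsoidCurvatureOracle(ellipsoidSpec(170, 100, 100), c(170, 0, 0))
  expect_equal(o2$kappaMax, 170 / 100^2)
  expect_equal(o2$kappaMin, 170 / 100^2)
  ## triaxial at (0, b, 0): max axis along z in the x-z tangent plane
  o3 <- ellipsoidCurvatureOracle(spec2DPA(), c(0, 100, 0))
  expect_equal(o3$kappaMax, 100 / 85^2)
  expect_equal(o3$kappaMin, 100 / 170^2)
  expect_lt(axialDiff(0, axisAngle(o3$axisMax, c(0, 0, 1))), 1e-6)
  expect_error(ellipsoidCurvatureOracle(spec2DPA(), c(0, 0, 0)), "projection")
})

test_that("quadric curvature estimation recovers sphere and spheroid values", {
  sph <- sphereMesh4()
  ts <- tessellateSurface(sph, 150L, 5L)
  cv <- estimateCurvature(sph, ts, 30)
  pv <- principalValues(cv)
  expect_lt(abs(median(pv[, 1]) - 0.01) / 0.01, 0.03)
  expect_lt(abs(median(pv[, 2]) - 0.01) / 0.01, 0.03)
  expect_lt(median(anisotropy(cv)), 0.05)
  ## spheroid equator pair
  sp <- spheroidMesh4()
  tsp <- tessellateSurface(sp, 200L, 5L)
  cvp <- estimateCurvature(sp, tsp, 30)
  eq <- abs(cellCentroids(tsp)[, 1]) < 17
  expect_lt(abs(median(principalValues(cvp)[eq, 1]) - 0.01) / 0.01, 0.05)
  kmer <- 100 / 170^2
  expect_lt(abs(median(principalValues(cvp)[eq, 2]) - kmer) / kmer, 0.05)
  ## axes are tangent: |v . n| small
  nrm <- seedmech:::cellNormals(tsp)
  dots <- abs(rowSums(principalAxes(cvp)$axis1 * nrm))
  expect_lt(max(dots), 1e-3)
})

test_that("curvature error decreases monotonically with refinement", {
  errs <- vapply(2:4, function(r) {
    sph <- if (r == 4) sphereMesh4() else
      makeEllipsoidMesh(ellipsoidSpec(100, 100, 100), r)
    ts <- tessellateSurface(sph, min(40L, nrow(faces(sph)) %/% 4L), 5L)
    cv <- estimateCurvature(sph, ts, 65)
    median(abs(principalValues(cv)[, 1] - 0.01)) / 0.01
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("curvature preconditions and failure modes are enforced", {
  sph <- makeEllipsoidMesh(ellipsoidSpec(100, 100, 100), 3)
  ts <- tessellateSurface(sph, 40L, 5L)
  expect_error(estimateCurvature(sph, ts, 10), "precondition")
})

test_that("theta distributions are invariant under rigid rotation", {
  sp <- makeEllipsoidMesh(ellipsoidSpec(170, 100, 100), 4)
  ts <- tessellateSurface(sp, 100L, 11L)
  cv <- estimateCurvature(sp, ts, 30)
  cmt <- sampleCMTField(cv, 20, 0, 3L)
  th0 <- thetaValues(correlateOrientationWithCurvature(cmt, cv))
  ## rotate mesh and both fields rigidly
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  rot <- function(m) m %*% t(R)
  cvR <- new("CurvatureField", cellId = cellIds(cv),
             value1 = principalValues(cv)[, 1], value2 = principalValues(cv)[, 2],
             axis1 = rot(principalAxes(cv)$axis1),
             axis2 = rot(principalAxes(cv)$axis2),
             anisotropy = anisotropy(cv), neighborhoodRadius = 30)
  cmtR <- new("OrientationField", cellId = cellIds(cmt),
              vectors = rot(orientationVectors(cmt)),
              score = organizationScore(cmt))
  thR <- thetaValues(correlateOrientationWithCurvature(cmtR, cvR))
  expect_lt(max(abs(th0 - thR)), 1e-6)
})
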