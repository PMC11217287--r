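test_that("spheroid stress oracle reproduces its closed forms", {
  mat <- shellMaterial()          # t = 1 um, p = 0.2 MPa
  ## sphere: both stresses pR/(2t)
  expect_equal(unname(spheroidStressOracle(100, 100, mat, 0)), c(10, 10))
  expect_equal(unname(spheroidStressOracle(100, 100, mat, 37)), c(10, 10))
  ## 2:1 prolate equator: sigma_m = 0.5 p b/t, sigma_h = 0.875 p b/t
  eq <- spheroidStressOracle(200, 100, mat, 0)
  expect_equal(unname(eq["sigma_meridional"]), 0.5 * 0.2 * 100)
  expect_equal(unname(eq["sigma_hoop"]), 0.875 * 0.2 * 100)
  ## pole: umbilic with radius b^2/a
  pole <- spheroidStressOracle(170, 100, mat, 90)
  expect_equal(unname(pole), rep(0.2 * (100^2 / 170) / 2, 2))
  expect_error(spheroidStressOracle(170, 100, mat, 91), "domain")
})

test_that("membrane FEM matches the spheroid oracle across latitudes", {
  st <- spheroidStress4()
  mesh <- spheroidMesh4()
  fc <- (vertices(mesh)[faces(mesh)[, 1], ] + vertices(mesh)[faces(mesh)[, 2], ] +
           vertices(mesh)[faces(mesh)[, 3], ]) / 3
  lat <- asin(pmin(1, pmax(-1, fc[, 1] / 170))) * 180 / pi
  mat <- shellMaterial()
  for (lt in c(0, 20, 40, 60, 75)) {
    sel <- abs(abs(lat) - lt) < 4
    oracle <- spheroidStressOracle(170, 100, mat, lt)
    s1 <- median(principalValues(st)[sel, 1])
    s2 <- median(principalValues(st)[sel, 2])
    expect_lt(abs(s1 - max(oracle)) / max(oracle), 0.05)
    expect_lt(abs(s2 - min(oracle)) / min(oracle), 0.05)
  }
})

test_that("stresses scale exactly with pressure and geometric similarity", {
  sph <- makeEllipsoidMesh(spec2DPA(), 3)
  s0 <- solveMembraneStress(sph, shellMaterial())
  s2 <- solveMembraneStress(sph, shellMaterial(pressure = 0.4))
  expect_equal(principalValues(s2), 2 * principalValues(s0), tolerance = 1e-12)
  ## scaling all lengths and the thickness leaves stresses unchanged
  sphk <- surfaceMesh(vertices(sph) * 3, faces(sph))
  s3 <- solveMembraneStress(sphk, shellMaterial(thickness = 3))
  expect_equal(principalValues(s3), principalValues(s0), tolerance = 1e-9)
  ## Young's modulus scaling leaves the linear solution's stress unchanged
  s4 <- solveMembraneStress(sph, shellMaterial(youngModulus = 1000))
  expect_equal(principalValues(s4), principalValues(s0), tolerance = 1e-9)
})

test_that("the solution is independent of the rigid-body constraint choice", {
  sph <- makeEllipsoidMesh(spec2DPA(), 3)
  s0 <- solveMembraneStress(sph, shellMaterial())
  v <- vertices(sph)
  s1 <- solveMembraneStress(sph, shellMaterial(),
                            constraintVertices = c(which.min(v[, 2]),
                                                   which.max(v[, 2]),
                                                   which.max(v[, 3])))
  rel <- abs(principalValues(s1) - principalValues(s0)) /
    pmax(abs(principalValues(s0)), 1e-9)
  expect_lt(max(rel), 0.01)
  ang <- vapply(seq_len(200), function(i)
    axisAngle(principalAxes(s1)$axis1[i, ], principalAxes(s0)$axis1[i, ]),
    numeric(1))
  expect_lt(stats::quantile(ang, 0.95), 2)
})

test_that("open meshes and invalid materials are rejected", {
  expect_error(solveMembraneStress(makePlanarMesh(10, 10, 2, 2),
                                   shellMaterial()), "topology")
  expect_error(shellMaterial(pressure = -1), "pressure")
  expect_error(shellMaterial(poissonRatio = 0.5), "poisson")
})

test_that("stress axes are tangent and orthogonal with ordered values", {
  st <- sphereStress4()
  ax <- principalAxes(st)
  expect_lt(max(abs(rowSums(ax$axis1 * ax$axis2))), 1e-6)
  pv <- principalValues(st)
  expect_true(all(pv[, 1] >= pv[, 2] - 1e-9))
  a <- anisotropy(st)
  expect_true(all(a >= -1e-12 & a <= 1))
})

test_that("region classification follows the geometric contract", {
  lab <- triRegions()
  tab <- table(regionLabel(lab))
  expect_true(all(tab > 0))
  ctr <- cellCentroids(triTess())
  expect_true(all(abs(ctr[regionLabel(lab) == "tip", 1]) > 0.85 * 170 - 15))
  expect_error(classifyRegions(triMesh4(), triTess(), spec2DPA(),
                               tipFraction = 0.6), "tipFraction")
  ## mesh/spec mismatch: centroids off the stated ellipsoid
  expect_error(classifyRegions(triMesh4(), triTess(),
                               ellipsoidSpec(200, 120, 100)), "inconsistency")
})

test_that("field summaries handle uniform fields, NaNs and coverage", {
  lab <- triRegions()
  n <- nCells(triTess())
  uni <- new("StressField", cellId = seq_len(n), value1 = rep(2, n),
             value2 = rep(1, n),
             axis1 = matrix(rep(c(0, 1, 0), each = n), ncol = 3),
             axis2 = matrix(rep(c(0, 0, 1), each = n), ncol = 3),
             anisotropy = rep(0.3, n))
  fs <- fieldSummary(uni, lab)
  expect_equal(fs$mean_anisotropy, rep(0.3, 3))
  ## one NaN anisotropy: excluded and counted
  uni@anisotropy[5] <- NaN
  fs2 <- fieldSummary(uni, lab)
  expect_equal(sum(fs2$n_excluded), 1L)
  expect_equal(sum(fs2$n), n - 1L)
  ## labels missing a cell
  short <- new("RegionLabels", cellId = seq_len(n - 1L),
               label = factor(rep("flank", n - 1L),
                              levels = c("flat_face", "flank", "tip")))
  expect_error(fieldSummary(uni, short), "coverage")
})
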