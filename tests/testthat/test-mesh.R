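test_that("ellipsoid spec enforces ordered positive semi-axes", {
  s <- spec2DPA()
  expect_equal(unname(semiAxes(s)), c(170, 100, 85))
  expect_error(ellipsoidSpec(0, 1, 1), "positive|a >= b")
  expect_error(ellipsoidSpec(1, 2, 1), "a >= b")
})

test_that("icosphere ellipsoid meshes are closed, on-surface and refine 4x", {
  sph <- makeEllipsoidMesh(ellipsoidSpec(100, 100, 100), 3)
  expect_true(isClosed(sph))
  expect_equal(nrow(faces(sph)), 20L * 4L^3)
  expect_equal(nrow(faces(makeEllipsoidMesh(spec2DPA(), 2))), 20L * 4L^2)
  ## sphere area within 1 % at refinement 4
  expect_lt(abs(meshArea(sphereMesh4()) / (4 * pi * 100^2) - 1), 0.01)
  ## every vertex satisfies the ellipsoid equation to 1e-9 relative
  tri <- makeEllipsoidMesh(spec2DPA(), 2)
  v <- vertices(tri)
  resid <- (v[, 1] / 170)^2 + (v[, 2] / 100)^2 + (v[, 3] / 85)^2 - 1
  expect_lt(max(abs(resid)), 1e-9)
  ## normals point away from the centroid
  fc <- (v[faces(tri)[, 1], ] + v[faces(tri)[, 2], ] + v[faces(tri)[, 3], ]) / 3
  expect_true(all(rowSums(faceNormals(tri) * fc) > 0))
  expect_error(makeEllipsoidMesh(spec2DPA(), 0), "refinement")
})

test_that("2DPA mesh reproduces the seed shape ratios", {
  tri <- makeEllipsoidMesh(spec2DPA(), 3)
  ext <- apply(vertices(tri), 2, function(z) diff(range(z)))
  expect_equal(ext[1] / ext[2], 1.70, tolerance = 1e-6)
  expect_equal(ext[3], 0.85 * ext[2], tolerance = 1e-6)
})

test_that("planar mesh is an open z-normal sheet", {
  pl <- makePlanarMesh(100, 80, 10, 8)
  expect_false(isClosed(pl))
  expect_equal(meshArea(pl), 100 * 80)
  expect_true(all(abs(faceNormals(pl)[, 3] - 1) < 1e-12))
})

test_that("meshes round-trip through OBJ and PLY with a cell-id sidecar", {
  sph <- makeEllipsoidMesh(ellipsoidSpec(50, 40, 30), 2)
  tess <- tessellateSurface(sph, 10L, 1L)
  for (ext in c("obj", "ply")) {
    path <- tempfile(fileext = paste0(".", ext))
    writeSurfaceMesh(sph, path, tess = tess)
    back <- readSurfaceMesh(path)
    expect_lt(max(abs(vertices(back) - vertices(sph))), 1e-6)
    expect_identical(faces(back), faces(sph))
    sidecar <- paste0(tools::file_path_sans_ext(path), "_cells.csv")
    expect_true(file.exists(sidecar))
    expect_equal(utils::read.csv(sidecar)$cell_id, faceCell(tess))
  }
})

test_that("degenerate geometry is rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(surfaceMesh(v, rbind(c(1L, 2L, 3L))), "degenerate")
})
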