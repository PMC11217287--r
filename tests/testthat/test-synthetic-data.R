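test_that("fibril image generator is reproducible and validates inputs", {
  a <- pixelValues(makeFibrilImage(c(64L, 64L), 30, 0.5, 9L))
  b <- pixelValues(makeFibrilImage(c(64L, 64L), 30, 0.5, 9L))
  expect_identical(a, b)
  expect_false(identical(a, pixelValues(makeFibrilImage(c(64L, 64L), 30, 0.5, 10L))))
  expect_error(makeFibrilImage(c(64L, 64L), 30, 1.2, 1L), "anisotropy")
  expect_error(makeFibrilImage(c(64L, 64L), 180, 0.5, 1L), "orientation")
})

test_that("CMT sampler concentrates, randomizes and offsets as specified", {
  cv <- flatCurvatureField(1000L)
  tight <- sampleCMTField(cv, 200, 0, 7L)
  th <- thetaValues(correlateOrientationWithCurvature(tight, cv))
  expect_lt(median(th), 5)
  unif <- sampleCMTField(cv, 0, 0, 7L)
  thu <- thetaValues(correlateOrientationWithCurvature(unif, cv))
  expect_lt(abs(mean(thu) - 45), 3)
  perp <- sampleCMTField(cv, 200, 90, 7L)
  thp <- thetaValues(correlateOrientationWithCurvature(perp, cv))
  expect_gt(median(thp), 85)
  ## vectors are unit-norm and tangent (normal = axis1 x axis2 = +z here)
  v <- orientationVectors(tight)
  expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-6)
  expect_lt(max(abs(v[, 3])), 1e-6)
  ## deterministic per seed
  expect_identical(orientationVectors(sampleCMTField(cv, 20, 0, 3L)),
                   orientationVectors(sampleCMTField(cv, 20, 0, 3L)))
  bad <- cv; bad@axis1[1, ] <- NA_real_
  expect_error(sampleCMTField(bad, 10, 0, 1L), "incomplete")
})

test_that("silhouette generator validates geometry and records ground truth", {
  sp <- silhouetteSpec(170, 100, matrix(c(256, 256), 1), sizePx = c(512L, 512L))
  img <- makeSilhouetteImage(sp, 5L)
  gt <- attr(img, "groundTruth")
  expect_equal(gt$half_length, 170)
  expect_identical(img, makeSilhouetteImage(sp, 5L))
  ## empty spec: zero foreground
  empty <- makeSilhouetteImage(
    silhouetteSpec(40, 25, matrix(numeric(0), 0, 2), sizePx = c(100L, 100L)), 1L)
  expect_lt(max(empty), 0.5)
  ## seed outside the canvas
  expect_error(makeSilhouetteImage(
    silhouetteSpec(60, 40, matrix(c(30, 50), 1), sizePx = c(100L, 100L)), 1L),
    "canvas")
  ## overlapping seeds beyond the tolerated fraction
  expect_error(makeSilhouetteImage(
    silhouetteSpec(40, 25, rbind(c(60, 60), c(80, 60)),
                   sizePx = c(200L, 120L), noiseAmp = 0), 1L),
    "overlap")
})

test_that("silhouette loop-back recovers the drawn aspect ratio", {
  img <- makeSilhouetteImage(
    silhouetteSpec(170, 100, matrix(c(256, 256), 1), sizePx = c(512L, 512L),
                   noiseAmp = 0.01), 5L)
  lab <- segmentSeeds(img)
  expect_equal(max(lab), 1L)
  m <- measureSeed(lab == 1L, mode = "ellipse")
  expect_equal(m$aspect_ratio, 1.70, tolerance = 0.02 / 1.7)
})

test_that("growth observations scatter lognormally about the daily means", {
  g0 <- makeGrowthObservations(c(100, 150, 200), c(1, 1.3, 1.5), 0, 5L, 1L)
  expect_equal(g0$area, rep(c(100, 150, 200), each = 5))
  expect_equal(g0$aspect_ratio, rep(c(1, 1.3, 1.5), each = 5))
  g1 <- makeGrowthObservations(c(100, 150), c(1, 1.3), 0.1, 200L, 1L)
  s <- dailyGrowthSummary(g1)
  expect_lt(max(abs(s$mean_area / c(100, 150) - 1)), 0.02)
  expect_lt(max(abs(s$mean_ar / c(1, 1.3) - 1)), 0.02)
  ## the realized coefficient of variation matches the requested one
  expect_equal(mean(s$sd_area / s$mean_area), 0.1, tolerance = 0.25)
  expect_identical(makeGrowthObservations(c(1, 2), c(1, 1), 0.2, 10L, 3L),
                   makeGrowthObservations(c(1, 2), c(1, 1), 0.2, 10L, 3L))
  expect_error(makeGrowthObservations(c(1, 2), c(1, 1, 1), 0.1, 5L, 1L),
               "length")
  expect_error(makeGrowthObservations(c(1, 2), c(1, 1), 0.1, 0L, 1L), "empty")
})
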