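test_that("axial angle identities hold exactly", {
  expect_equal(axisAngle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(axisAngle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(axisAngle(c(1, 0, 0), c(-1, 0, 0)), 0)
  ## symmetry and sign-flip invariance over random axis pairs
  set.seed(1)
  for (k in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    th <- axisAngle(u, v)
    expect_gte(th, 0); expect_lte(th, 90)
    expect_equal(axisAngle(v, u), th)
    expect_equal(axisAngle(-u, v), th)
    expect_equal(axisAngle(u, -v), th)
    expect_equal(axisAngle(-u, -v), th)
  }
  expect_error(axisAngle(c(0, 0, 0), c(1, 0, 0)), "zero")
  expect_error(axisAngle(c(2, 0, 0), c(1, 0, 0)), "unit")
})

test_that("theta correlation summarizes identical and uniform fields", {
  cv <- flatCurvatureField(1000L)
  ident <- new("OrientationField", cellId = cellIds(cv),
               vectors = principalAxes(cv)$axis1,
               score = rep(1, 1000))
  ad <- correlateOrientationWithCurvature(ident, cv)
  expect_equal(unname(max(thetaValues(ad))), 0)
  expect_equal(ad@summary$median, 0)
  expect_equal(sum(ad@counts), 1000L)
  expect_length(ad@breaks, 19L)       # default 18 bins of 5 degrees
  ## uniform axial field: mean 45 +/- 3, KS distance to uniform < 0.05
  unif <- sampleCMTField(cv, 0, 0, 4L)
  adu <- correlateOrientationWithCurvature(unif, cv)
  expect_lt(abs(adu@summary$mean - 45), 3)
  ks <- suppressWarnings(stats::ks.test(thetaValues(adu), "punif", 0, 90))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("theta sharpens monotonically with CMT concentration", {
  cv <- flatCurvatureField(600L)
  med <- vapply(c(2, 20), function(k)
    stats::median(thetaValues(correlateOrientationWithCurvature(
      sampleCMTField(cv, k, 0, 5L), cv))), numeric(1))
  expect_lt(med[2], med[1])
})

test_that("cells missing from either field are excluded and counted", {
  cv <- flatCurvatureField(100L)
  or <- sampleCMTField(cv, 10, 0, 1L)
  or@cellId <- or@cellId + 50L      # only cells 51..100 shared
  ad <- correlateOrientationWithCurvature(or, cv)
  expect_length(thetaValues(ad), 50L)
  expect_equal(ad@nExcluded, 100L)
  or@cellId <- or@cellId + 1000L
  expect_error(correlateOrientationWithCurvature(or, cv), "empty join")
})

test_that("ablation-relative orientation separates circumferential from radial", {
  ang <- seq(0, 330, by = 30)
  ctr <- cbind(cos(ang * pi / 180), sin(ang * pi / 180)) * 10
  circumferential <- (ang + 90) %% 180
  expect_lt(max(orientationRelativeToPoint(circumferential, ctr, c(0, 0))), 1e-9)
  radial <- ang %% 180
  expect_equal(orientationRelativeToPoint(radial, ctr, c(0, 0)),
               rep(90, 12), tolerance = 1e-9)
  ## ring of circumferential cells with one radial outlier
  mixed <- circumferential
  mixed[5] <- ang[5] %% 180
  dev <- orientationRelativeToPoint(mixed, ctr, c(0, 0))
  expect_equal(median(dev), 0, tolerance = 1e-9)
  expect_equal(max(dev), 90, tolerance = 1e-9)
  expect_error(orientationRelativeToPoint(0, rbind(c(0, 0)), c(0, 0)),
               "undefined direction")
})
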