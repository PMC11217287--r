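test_that("Huang threshold separates a bimodal image", {
  set.seed(2)
  img <- matrix(rnorm(10000, 0.2, 0.02), 100, 100)
  img[30:70, 30:70] <- rnorm(41 * 41, 0.8, 0.02)
  thr <- huangThreshold(img)
  expect_gt(thr, 0.26); expect_lt(thr, 0.74)   # separates the two modes
  expect_equal(sum(img > thr), 41L * 41L)
  expect_error(huangThreshold(matrix(1, 10, 10)), "constant")
})

test_that("segmentation separates disjoint and tangent seeds", {
  s3 <- makeSilhouetteImage(
    silhouetteSpec(40, 25, rbind(c(60, 60), c(180, 60), c(120, 180)),
                   sizePx = c(240L, 240L), noiseAmp = 0.01), 3L)
  lab <- segmentSeeds(s3)
  expect_equal(max(lab), 3L)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(abs(areas - pi * 40 * 25) / (pi * 40 * 25) < 0.02))
  ## area conservation: labelled pixels = foreground of the binary mask
  expect_equal(sum(lab > 0), sum(areas))
  ## tangent pair is split by the distance-transform watershed
  s2 <- makeSilhouetteImage(
    silhouetteSpec(40, 25, rbind(c(60, 80), c(140, 80)),
                   sizePx = c(220L, 160L), noiseAmp = 0), 3L)
  expect_equal(max(segmentSeeds(s2)), 2L)
  ## background-only image yields zero labels with a warning flag
  blank <- makeSilhouetteImage(
    silhouetteSpec(40, 25, matrix(numeric(0), 0, 2), sizePx = c(100L, 100L)), 1L)
  expect_warning(lb <- segmentSeeds(blank), "foreground")
  expect_equal(max(lb), 0L)
  expect_true(attr(lb, "noForeground"))
})

test_that("seed shape measurement matches rasterized ground truth", {
  img <- makeSilhouetteImage(
    silhouetteSpec(170, 100, matrix(c(256, 256), 1), sizePx = c(512L, 512L),
                   noiseAmp = 0), 1L)
  mask <- img > 0.5
  for (mode in c("ellipse", "axes")) {
    m <- measureSeed(mask, mode = mode)
    expect_equal(m$aspect_ratio, 1.70, tolerance = 0.02 / 1.7)
  }
  expect_equal(measureSeed(mask)$area, pi * 170 * 100, tolerance = 0.01)
  ## a circle has aspect ratio 1 in both modes
  circ <- makeSilhouetteImage(
    silhouetteSpec(60, 60, matrix(c(100, 100), 1), sizePx = c(200L, 200L),
                   noiseAmp = 0), 1L)
  expect_equal(measureSeed(circ > 0.5)$aspect_ratio, 1, tolerance = 0.01)
  expect_equal(measureSeed(circ > 0.5, "axes")$aspect_ratio, 1, tolerance = 0.01)
  ## multi-component masks are ambiguous
  two <- mask; two[1:5, 1:5] <- TRUE
  expect_error(measureSeed(two), "ambiguity")
})

test_that("aspect ratio is invariant to rotation and scaling of the mask", {
  rasterEllipse <- function(a, b, phi, n = 420L) {
    xs <- row(matrix(0, n, n)) - (n + 1) / 2
    ys <- col(matrix(0, n, n)) - (n + 1) / 2
    u <- xs * cos(phi) + ys * sin(phi)
    v <- -xs * sin(phi) + ys * cos(phi)
    (u / a)^2 + (v / b)^2 <= 1
  }
  base <- measureSeed(rasterEllipse(150, 90, 0))$aspect_ratio
  for (phi in c(0.4, 1.1)) {
    rot <- measureSeed(rasterEllipse(150, 90, phi))$aspect_ratio
    expect_lt(abs(rot / base - 1), 0.01)
  }
  scaled <- measureSeed(rasterEllipse(75, 45, 0.4))$aspect_ratio
  expect_lt(abs(scaled / base - 1), 0.01)
})

test_that("growth series formulas are reproduced exactly", {
  daily <- data.frame(day = 0:1, mean_area = c(100, 150), sd_area = c(10, 15),
                      mean_ar = c(1.2, 1.5), sd_ar = c(0.06, 0.075))
  g <- growthDerivativeSeries(daily)
  expect_identical(g$growth_rate[1], 0.5)
  expect_equal(g$sd_growth_rate[1], sqrt(0.1^2 + 0.1^2))
  expect_equal(g$growth_anisotropy[1], 0.25)
  expect_equal(g$sd_growth_anisotropy[1], sqrt(0.05^2 + 0.05^2))
  expect_true(is.na(g$growth_rate[2]))
  ## constant series: zero rates, propagated SD = sqrt(2) * cv
  const <- data.frame(day = 0:2, mean_area = rep(200, 3), sd_area = rep(20, 3),
                      mean_ar = rep(1.4, 3), sd_ar = rep(0.14, 3))
  gc <- growthDerivativeSeries(const)
  expect_equal(gc$growth_rate[1:2], c(0, 0))
  expect_equal(gc$sd_growth_rate[1:2], rep(sqrt(2) * 0.1, 2))
  expect_error(growthDerivativeSeries(daily[1, ]), "2 days")
  bad <- daily; bad$mean_area[1] <- -1
  expect_error(growthDerivativeSeries(bad), "positive")
})

test_that("growth series round-trips through the observation generator", {
  truthA <- c(100, 160, 220, 260)
  truthR <- c(0.8, 1.2, 1.5, 1.65)
  obs <- makeGrowthObservations(truthA, truthR, 0.1, 400L, 11L)
  g <- growthDerivativeSeries(dailyGrowthSummary(obs))
  expect_equal(g$growth_rate[1:3], diff(truthA) / truthA[1:3], tolerance = 0.05)
  expect_equal(g$growth_anisotropy[1:3], diff(truthR) / truthR[1:3],
               tolerance = 0.1)
})

test_that("cell growth maps recover affine ground truth", {
  pl <- makePlanarMesh(100, 100, 16, 16)
  t0 <- tessellateSurface(pl, 25L, 7L)
  t1 <- makePairedTessellation(t0, 1.2, 1.0, 0, 8L)
  gm <- cellGrowthMap(t0, t1)
  expect_equal(mean(gm$areal_growth), 0.2, tolerance = 0.01 / 0.2)
  expect_equal(mean(gm$anisotropy), 1.2, tolerance = 0.02 / 1.2)
  expect_lt(max(pmin(gm$main_axis_deg, 180 - gm$main_axis_deg)), 2)
  expect_equal(gm$n_offspring, rep(1L, 25L))
  ## identity stretch
  gid <- cellGrowthMap(t0, makePairedTessellation(t0, 1, 1, 0, 8L))
  expect_lt(max(abs(gid$areal_growth)), 1e-9)
  expect_lt(max(abs(gid$anisotropy - 1)), 1e-9)
  ## pure rotation is an isometry
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t1r <- cellTessellation(surfaceMesh(vertices(pl) %*% t(R), faces(pl),
                                      orient = "keep"),
                          faceCell(t0),
                          lineage = as.list(stats::setNames(1:25, 1:25)))
  gr <- cellGrowthMap(t0, t1r)
  expect_lt(max(abs(gr$areal_growth)), 0.01)
  expect_lt(max(abs(gr$anisotropy - 1)), 0.02)
  ## divisions counted through the lineage
  gd <- cellGrowthMap(t0, makePairedTessellation(t0, 1.1, 1.05, 1, 9L))
  expect_true(all(gd$n_offspring == 2L))
  ## missing lineage entries are an error
  t1b <- makePairedTessellation(t0, 1.1, 1, 0, 8L)
  lin <- cellLineage(t1b); lin[["3"]] <- NULL
  expect_error(cellGrowthMap(t0, t1b, lineage = lin), "lineage")
})

test_that("dimension changes are summarized by per-seed medians", {
  base <- expand.grid(seed_id = 1:2, cell_id = 1:25)
  base$length <- 10; base$width <- 5; base$thickness <- 2
  after <- base
  after$thickness <- base$thickness * 1.10
  out <- dimensionChangeStats(base, after)
  expect_equal(out$perSeed$median_thickness_change_pct, c(10, 10))
  expect_equal(out$perSeed$median_length_change_pct, c(0, 0))
  ## a wild outlier does not move the median
  after2 <- after
  after2$thickness[after2$seed_id == 1][1] <- 50
  out2 <- dimensionChangeStats(base, after2)
  expect_equal(out2$perSeed$median_thickness_change_pct, c(10, 10))
  ## unmatched ids are a join error
  expect_error(dimensionChangeStats(base, after[-3, ]), "join error")
  noshare <- after; noshare$cell_id <- noshare$cell_id + 100
  expect_error(dimensionChangeStats(base, noshare), "join error")
})
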