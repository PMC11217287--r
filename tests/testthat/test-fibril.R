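test_that("fibril tensor recovers the generator's ground-truth orientation", {
  ## the documented reference case
  m <- fibrilTensor(makeFibrilImage(c(256L, 256L), 30, 0.9, 1L))
  expect_lt(axialDiff(m$orientation_deg, 30), 1)
  expect_gt(m$score, 0.6)
  ## across angles and seeds
  for (ang in c(0, 77, 120)) for (s in 1:2) {
    mi <- fibrilTensor(makeFibrilImage(c(256L, 256L), ang, 0.9, s))
    expect_lt(axialDiff(mi$orientation_deg, ang), 1)
  }
})

test_that("isotropic textures score near zero", {
  sc <- vapply(1:20, function(s)
    fibrilTensor(makeFibrilImage(c(256L, 256L), 0, 0, s))$score, numeric(1))
  expect_lt(mean(sc), 0.05)
})

test_that("organization score increases strictly with generator anisotropy", {
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(a)
    mean(vapply(1:10, function(s)
      fibrilTensor(makeFibrilImage(c(128L, 128L), 45, a, s))$score,
      numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("orientation is rotation-equivariant and score rotation-invariant", {
  fi <- makeFibrilImage(c(256L, 256L), 30, 0.9, 3L)
  img <- pixelValues(fi)
  msk <- centralDiskMask(256L, 75)
  m0 <- fibrilTensor(img, roiMask = msk)
  m1 <- fibrilTensor(rotateImageBilinear(img, 40), roiMask = msk)
  expect_lt(abs(axialDiff(m0$orientation_deg, m1$orientation_deg) - 40), 1)
  expect_lt(abs(m0$score - m1$score), 0.02)
})

test_that("measurements are invariant to affine intensity rescaling", {
  img <- pixelValues(makeFibrilImage(c(128L, 128L), 60, 0.8, 2L))
  m0 <- fibrilTensor(img)
  m1 <- fibrilTensor(3.7 * img + 11)
  expect_lt(abs(m0$orientation_deg - m1$orientation_deg), 1e-3)
  expect_lt(abs(m0$score - m1$score), 1e-3)
})

test_that("an image and its 180-degree rotation measure the same axis", {
  img <- pixelValues(makeFibrilImage(c(128L, 128L), 25, 0.9, 6L))
  m0 <- fibrilTensor(img)
  m1 <- fibrilTensor(img[nrow(img):1, ncol(img):1])
  expect_lt(axialDiff(m0$orientation_deg, m1$orientation_deg), 0.5)
})

test_that("degenerate ROIs follow the contract", {
  flat <- matrix(1, 64, 64)
  m <- fibrilTensor(flat)
  expect_equal(m$score, 0)
  expect_true(m$undefined_orientation)
  expect_true(is.na(m$orientation_deg))
  small <- matrix(FALSE, 64, 64); small[1:7, 1:7] <- TRUE
  expect_error(fibrilTensor(flat, roiMask = small), "64 pixels")
})

test_that("batch measurement yields one row per label with organ-axis angles", {
  img <- pixelValues(makeFibrilImage(c(200L, 200L), 30, 0.9, 4L))
  labels <- matrix(0L, 200L, 200L)
  k <- 0L
  for (i in 0:4) for (j in 0:1) {
    k <- k + 1L
    labels[i * 40 + (1:40), j * 100 + (1:100)] <- k
  }
  out <- roiBatchMeasure(img, labels, organAxisDeg = 0)
  expect_equal(nrow(out), 10L)
  expect_lt(stats::sd(out$orientation_deg), 2)    # homogeneous texture
  expect_equal(median(out$relative_orientation_deg), 30, tolerance = 2)
  ## fibrils perpendicular to the organ axis report 90 (hoops around a barrel)
  img90 <- pixelValues(makeFibrilImage(c(200L, 200L), 90, 0.9, 4L))
  out90 <- roiBatchMeasure(img90, labels, organAxisDeg = 0)
  expect_equal(median(out90$relative_orientation_deg), 90, tolerance = 2)
  ## an empty label yields a flagged row
  labels2 <- labels; labels2[labels2 == 9L] <- 10L
  out2 <- roiBatchMeasure(img, labels2)
  expect_equal(out2$n_pixels[9], 0L)
  expect_true(out2$undefined_orientation[9])
})
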