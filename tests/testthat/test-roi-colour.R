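# ROI extraction, stripe masking and masked mean colour.

test_that("thumbnail extraction is an exact crop", {
  set.seed(21)
  img <- array(runif(600 * 600 * 3), dim = c(600, 600, 3))
  th <- extractThumbnail(img, roiSpec(0, 0))
  expect_identical(dim(th), c(53L, 530L, 3L))
  expect_identical(th, img[1:53, 1:530, , drop = FALSE])
  # idempotent full-size crop
  again <- extractThumbnail(th, roiSpec(0, 0, 530, 53))
  expect_identical(again, th)
  const <- array(0.4, dim = c(100, 600, 3))
  expect_true(all(extractThumbnail(const, roiSpec(5, 5)) == 0.4))
  expect_error(extractThumbnail(img, roiSpec(90, 590)), "bounds")
})

test_that("stripe mask matches the renderer's ground-truth mask", {
  scene <- sceneSpec()
  r <- renderFishImage(scene, cameraModel())
  roi <- roiSpec(scene@fishRegion[1] + 5, scene@fishRegion[2] + 10)
  thumb <- extractThumbnail(r$image, roi)
  mk <- stripeMask(thumb)
  gt <- r$mask[(roi$y + 1):(roi$y + 53), (roi$x + 1):(roi$x + 530)]
  expect_gte(mean(mk$mask == gt), 0.99)
  expect_lt(abs(mk$maskFraction - (1 - scene@stripeDuty)), 0.05)
})

test_that("uniform thumbnails keep all pixels with a warning", {
  th <- array(0.6, dim = c(10, 20, 3))
  expect_warning(mk <- stripeMask(th), "constant")
  expect_true(all(mk$mask))
  expect_equal(mk$maskFraction, 1)
})

test_that("stripes of any darkness leave the masked mean colour unchanged", {
  base <- sceneSpec(stripeDuty = 0.4)
  roi <- roiSpec(base@fishRegion[1] + 5, base@fishRegion[2] + 10)
  labRef <- NULL
  for (darkL in c(5, 20, 32)) {
    sc <- sceneSpec(stripeDuty = 0.4, darkLab = c(darkL, -2, 0))
    r <- renderFishImage(sc, cameraModel())
    thumb <- extractThumbnail(r$image, roi)
    mk <- stripeMask(thumb)
    lab <- labMean(measureColour(thumb, mk$mask))
    if (is.null(labRef)) labRef <- lab
    expect_lt(deltaE(lab, labRef), 0.5)
  }
})

test_that("masked mean measurement is exact, order-invariant and flagged when thin", {
  # uniform thumbnail: mean equals the single pixel colour
  px <- srgbEncode(labToLinearRgb(c(47.67, -9.27, 17.17)))
  th <- array(rep(px, each = 200), dim = c(10, 20, 3))
  cm <- measureColour(th)
  expect_lt(deltaE(labMean(cm), c(47.67, -9.27, 17.17)), 1e-8)
  expect_identical(nPixelsUsed(cm), 200L)

  # permutation invariance of the mean (mask selects the same multiset)
  set.seed(22)
  img <- array(runif(300), dim = c(10, 10, 3))
  perm <- sample(100)
  img2 <- array(matrix(img, ncol = 3)[perm, ], dim = c(10, 10, 3))
  expect_identical(labMean(measureColour(img)), labMean(measureColour(img2)))

  # fewer than 50 kept pixels -> unreliable flag
  mk <- matrix(FALSE, 10, 10); mk[1:4, 1:4] <- TRUE
  cm2 <- measureColour(img, mk)
  expect_false(cm2@reliable)
})

test_that("Otsu threshold matches exhaustive between-class variance maximisation", {
  set.seed(23)
  x <- matrix(c(rnorm(300, 0.25, 0.04), rnorm(700, 0.62, 0.05)), 25, 40)
  x <- pmin(pmax(x, 0), 1)
  mine <- otsuThreshold(x)
  # brute-force oracle: scan every observed value as a candidate split
  cand <- sort(unique(as.vector(x)))
  bc <- sapply(cand, function(t) {
    w0 <- mean(x <= t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(x[x <= t]) - mean(x[x > t]))^2
  })
  ref <- cand[which.max(bc)]
  expect_lt(abs(mine - ref), 2 / 256)       # within histogram resolution
  # splits the two-component mixture between its modes
  expect_gt(mine, 0.25 + 2 * 0.04)
  expect_lt(mine, 0.62 - 2 * 0.05)
})
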