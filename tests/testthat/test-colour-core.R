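# Colour-space mathematics: transfer functions, matrix conversions,
# CIELAB, and agreement with an independent reference converter.

test_that("sRGB transfer is the standard piecewise curve and exactly invertible", {
  expect_equal(srgbDecode(0), 0)
  expect_equal(srgbDecode(1), 1)
  expect_equal(srgbDecode(0.04045), 0.04045 / 12.92, tolerance = 1e-12)
  v <- seq(0, 1, length.out = 1000)
  expect_lt(max(abs(srgbEncode(srgbDecode(v)) - v)), 1e-12)
  expect_lt(max(abs(srgbDecode(srgbEncode(v)) - v)), 1e-12)
  # shape is preserved for images
  img <- array(runif(60), dim = c(4, 5, 3))
  expect_identical(dim(srgbDecode(img)), dim(img))
})

test_that("linear RGB <-> XYZ uses the sRGB/D65 primaries and round-trips", {
  w <- linearRgbToXyz(c(1, 1, 1))
  expect_equal(unname(w), c(95.047, 100, 108.883), tolerance = 0.1)
  expect_equal(linearRgbToXyz(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  m <- matrix(runif(300), ncol = 3)
  expect_lt(max(abs(xyzToLinearRgb(linearRgbToXyz(m)) - m)), 1e-10)
})

test_that("CIELAB conversion matches the CIE formulas and inverts", {
  expect_equal(unname(xyzToLab(whitePointD65())), c(100, 0, 0),
               tolerance = 1e-10)
  # hand evaluation: L* = 50 has Y = 100 ((66/116)^3) when Yn = 100
  expect_equal(labToXyz(c(50, 0, 0), white = c(95.047, 100, 108.883))[2],
               100 * (66 / 116)^3, tolerance = 1e-10)
  # grid round trip including below-threshold branch (very dark colours)
  set.seed(5)
  labs <- cbind(runif(200, 0.1, 99), runif(200, -60, 60), runif(200, -60, 60))
  back <- xyzToLab(labToXyz(labs))
  expect_lt(max(abs(back - labs)), 1e-8)
  expect_error(xyzToLab(c(10, 10, 10), white = c(0, 100, 100)), "positive")
})

test_that("conversion agrees with grDevices::convertColor as an independent reference", {
  set.seed(6)
  enc <- matrix(runif(30, 0.05, 0.95), ncol = 3)
  mine <- linearRgbToLab(srgbDecode(enc))
  ref <- grDevices::convertColor(enc, "sRGB", "Lab")
  # reference uses slightly different rounded constants; agree closely
  expect_lt(max(abs(mine - ref)), 0.5)
})

test_that("deltaE is the CIELAB Euclidean distance", {
  expect_equal(deltaE(c(50, 0, 0), c(53, 4, 0)), 5)
  m <- rbind(c(10, 0, 0), c(20, 0, 0))
  expect_equal(deltaE(m, m), c(0, 0))
  expect_equal(deltaE(c(0, 0, 0), m), c(10, 20))
})
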