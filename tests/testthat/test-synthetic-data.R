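# Synthetic-data generators: renderers and cohort simulators.

test_that("identity camera reproduces the ground-truth colour on the true mask", {
  r <- renderFishImage(sceneSpec(), cameraModel())
  roi <- roiSpec(50, 70)
  thumb <- extractThumbnail(r$image, roi)
  gt <- r$mask[71:(70 + 53), 51:(50 + 530)]
  cm <- measureColour(thumb, gt)
  expect_lt(deltaE(labMean(cm), c(47.67, -9.27, 17.17)), 1)
})

test_that("ground-truth mask covers the light fraction of the fish region", {
  for (duty in c(0.3, 0.5, 0.7)) {
    scene <- sceneSpec(stripeDuty = duty)
    r <- renderFishImage(scene, cameraModel())
    region <- r$mask[(scene@fishRegion[2] + 1):(scene@fishRegion[2] + scene@fishRegion[4]),
                     (scene@fishRegion[1] + 1):(scene@fishRegion[1] + scene@fishRegion[3])]
    # within one stripe period of the nominal light fraction
    tolRows <- scene@stripePeriod / scene@fishRegion[4]
    expect_lt(abs(mean(region) - (1 - duty)), tolRows)
    # no mask outside the fish region
    outside <- r$mask
    outside[(scene@fishRegion[2] + 1):(scene@fishRegion[2] + scene@fishRegion[4]),
            (scene@fishRegion[1] + 1):(scene@fishRegion[1] + scene@fishRegion[3])] <- FALSE
    expect_false(any(outside))
  }
})

test_that("scene validity catches degenerate geometry and colour ordering", {
  expect_error(sceneSpec(fishRegion = c(30L, 60L, 0L, 80L)), "degenerate")
  expect_error(sceneSpec(fishRegion = c(30L, 60L, 600L, 80L)), "inside")
  expect_error(sceneSpec(stripeDuty = 1.2), "stripeDuty")
  expect_error(sceneSpec(darkLab = c(60, 0, 0)), "L\\*")
  expect_error(cameraModel(camMatrix = matrix(1, 3, 3)), "invertible")
})

test_that("chart patches pass through a known camera as g*M*reference", {
  ch0 <- renderChartImage(cameraModel(quantization = 0L))
  m0 <- measureChartPatches(ch0$image, ch0$patches)
  ref <- as.matrix(ch0$patches[, c("R", "G", "B")])
  expect_lt(max(abs(m0 - ref)), 1e-9)      # identity, pre-quantization
  expect_equal(nrow(ch0$patches), 24L)
  # non-overlap: pairwise rectangles disjoint
  p <- ch0$patches
  for (i in 1:23) for (j in (i + 1):24) {
    sep <- p$x[i] + p$w[i] <= p$x[j] || p$x[j] + p$w[j] <= p$x[i] ||
      p$y[i] + p$h[i] <= p$y[j] || p$y[j] + p$h[j] <= p$y[i]
    expect_true(sep)
  }
  M <- diag(3) + matrix(c(0, 0.04, -0.02, 0.01, 0, 0.02, -0.03, 0.01, 0), 3, 3)
  g <- 0.9
  ch1 <- renderChartImage(cameraModel(M, g, quantization = 0L))
  m1 <- measureChartPatches(ch1$image, ch1$patches)
  expect_lt(max(abs(m1 - g * ref %*% t(M))), 1e-9)
})

test_that("trajectory generator follows b0 + rate*t with scenario noise", {
  scen <- defaultScenarios()
  tiny <- lapply(scen[c("Control", "High")], function(s) {
    s@sigma <- 1e-12; s
  })
  d0 <- simulateTrajectories(tiny, 20, seed = 3)
  hi <- d0[d0$trial == "High", ]
  expect_lt(max(abs(hi$b - (17.17 - 0.82 * hi$exposure_min))), 1e-9)
  expect_lt(max(d0$exposure_min), 15)

  # OLS slope recovery at the High rate
  d1 <- simulateTrajectories(scen["High"], 40, seed = 4)
  ols <- lm(b ~ exposure_min, d1)
  est <- coef(ols)[2]; se <- sqrt(vcov(ols)[2, 2])
  expect_lt(abs(est - (-0.82)), 3 * se)

  # heteroscedasticity by design: SD ratio ~ 3
  s1 <- trialScenario("Low", 92, 15, rate = -0.25, sigma = 1)
  s3 <- trialScenario("High", 180, 15, rate = -0.25, sigma = 3)
  d2 <- simulateTrajectories(list(s1, s3), 200, seed = 5)
  r1 <- resid(lm(b ~ exposure_min, d2[d2$trial == "Low", ]))
  r3 <- resid(lm(b ~ exposure_min, d2[d2$trial == "High", ]))
  expect_lt(abs(sd(r3) / sd(r1) - 3) / 3, 0.25)

  expect_error(simulateTrajectories(list(), 10), "empty")
})

test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(simulateTrajectories(defaultScenarios(), 10, seed = 9),
                   simulateTrajectories(defaultScenarios(), 10, seed = 9))
  expect_identical(simulateCohort(cohortSpec(seed = 9L)),
                   simulateCohort(cohortSpec(seed = 9L)))
  expect_identical(simulatePostmortem(6, seed = 9),
                   simulatePostmortem(6, seed = 9))
  r1 <- renderFishImage(sceneSpec(), randomCameraModel(7))
  r2 <- renderFishImage(sceneSpec(), randomCameraModel(7))
  expect_identical(r1$image, r2$image)
})

test_that("cohort b* follows the lactate link plus declared variance components", {
  # all variance off: exact link
  sp0 <- cohortSpec(nFish = 5L, trialSD = 0, periodSD = 0, residualSD = 0,
                    seed = 2L)
  d0 <- simulateCohort(sp0)
  expect_lt(max(abs(d0$b - lactateLink(d0$lactate, sp0@lactateLink))), 1e-10)
  # defaults: negative lactate-b* association
  d1 <- simulateCohort(cohortSpec(nFish = 25L, seed = 3L))
  expect_lt(cor(d1$lactate, d1$b), 0)
  # variance decomposition within 30% at n ~ 500
  sp2 <- cohortSpec(nFish = 25L, trialSD = 1, periodSD = 1, residualSD = 2,
                    seed = 4L)
  d2 <- simulateCohort(sp2)
  resid2 <- d2$b - lactateLink(d2$lactate, sp2@lactateLink)
  cellMeans <- tapply(resid2, interaction(d2$trial, d2$monitoring_period),
                      mean)
  withinSD <- sqrt(mean(tapply(resid2, interaction(d2$trial, d2$monitoring_period),
                               var)))
  expect_lt(abs(withinSD - 2) / 2, 0.3)
  expect_lt(abs(sd(cellMeans) - sqrt(2)) / sqrt(2), 0.4)
  expect_error(cohortSpec(lactateLink = c(high = 5, low = 20, mid = 8,
                                          steep = 0.4)),
               "decreasing")
})

test_that("post-mortem series drops by the set amount after death and then stays flat", {
  d <- simulatePostmortem(30, drop = 5, sigma = 1, seed = 6)
  m <- tapply(d$b, d$time_h, mean)
  expect_lt(abs((m["1"] - m["0"]) + 5), 3 * sqrt(2 / 30) * 2)
  # 1 h, 4 h, 24 h means within noise of each other
  later <- m[c("1", "4", "24")]
  expect_lt(max(later) - min(later), 3 * sqrt(2 / 30) * 2)
  expect_error(simulatePostmortem(6, timepoints = c(1, 4)), "invalid")
})

test_that("mortality generator is Binomial(n, p)", {
  expect_identical(simulateMortality(150, 0, seed = 1), 0L)
  expect_identical(simulateMortality(150, 1, seed = 1), 150L)
  counts <- sapply(1:1000, function(s) simulateMortality(150, 0.31, seed = s))
  expect_lt(abs(mean(counts) - 46.5), 1)
})
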