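# Penalized cubic-spline mixed model.

test_that("straight-line data give an effectively linear smooth", {
  # edf is stochastic (chance curvature attracts a little wiggle, as
  # any REML smoother shows), so the linear limit is checked on the
  # average over replicate datasets
  edfs <- sapply(61:65, function(s) {
    set.seed(s)
    n <- 150
    d <- data.frame(x = runif(n, 0, 10))
    d$y <- 2 + 0.5 * d$x + rnorm(n, 0, 0.5)
    f <- fitSplineMixed(d, "y", "x")
    if (s == 61) {
      ps <- predictSmooth(f, seq(0.5, 9.5, length.out = 25))
      expect_true(all(abs(ps$fit - (2 + 0.5 * ps$x)) <= 2 * ps$se + 0.1))
    }
    varParams(f)$edf
  })
  expect_lte(mean(edfs), 1.5)
})

test_that("a quartic signal is tracked far better than any straight line", {
  set.seed(62)
  n <- 300
  d <- data.frame(x = runif(n, 0, 10))
  truth <- 0.02 * (d$x - 5)^4
  d$y <- truth + rnorm(n, 0, 0.5)
  f <- fitSplineMixed(d, "y", "x")
  rmseS <- sqrt(mean((predictSmooth(f, d$x)$fit - truth)^2))
  rmseL <- sqrt(mean((fitted(lm(y ~ x, d)) - truth)^2))
  expect_lt(rmseS, 0.5 * rmseL)
  expect_gt(varParams(f)$edf, 2)
})

test_that("smooth agrees with the mgcv reference on a shared dataset", {
  skip_if_not_installed("mgcv")
  set.seed(63)
  n <- 250
  d <- data.frame(x = runif(n, 0, 10))
  d$y <- sin(d$x) + rnorm(n, 0, 0.3)
  f <- fitSplineMixed(d, "y", "x")
  g <- mgcv::gam(y ~ s(x, bs = "cr"), data = d, method = "REML")
  xs <- seq(0.5, 9.5, length.out = 40)
  mine <- predictSmooth(f, xs)$fit
  ref <- as.vector(predict(g, data.frame(x = xs)))
  expect_lt(sqrt(mean((mine - ref)^2)), 0.1)
})

test_that("the lactate smooth on the cohort generator is monotone decreasing", {
  co <- simulateCohort(cohortSpec(nFish = 10L, seed = 11L))
  f <- fitSplineMixed(co, "b", "lactate",
                      random = c("trial", "monitoring_period"),
                      varPower = TRUE)
  gr <- quantile(co$lactate, c(0.05, 0.95))
  sm <- predictSmooth(f, seq(gr[1], gr[2], length.out = 50))
  expect_true(all(diff(sm$fit) < 0))
  # estimated power is small: generator noise does not scale with the mean
  expect_lt(abs(varParams(f)$estimates["power"]), 0.6)
  expect_identical(varParams(f)$type, "varPower")
})

test_that("basis dimension is chosen by AIC over the candidate list", {
  set.seed(64)
  d <- data.frame(x = runif(200, 0, 10))
  d$y <- sin(d$x) + rnorm(200, 0, 0.3)
  f <- fitSplineMixed(d, "y", "x", basisDims = c(5L, 8L, 12L))
  aics <- varParams(f)$aic
  expect_length(aics, 3)
  expect_identical(varParams(f)$basisDim,
                   as.integer(names(which.min(aics))))
})
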