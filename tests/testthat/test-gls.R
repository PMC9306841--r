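# GLS with group-wise variance weights and Wald-F testing.

test_that("a single variance group collapses to ordinary least squares", {
  set.seed(41)
  d <- data.frame(x = runif(50), g = factor(rep("A", 50)))
  d$y <- 1 + 2 * d$x + rnorm(50)
  f <- fitGls(y ~ x, d, varIdent = "g")
  o <- lm(y ~ x, d)
  expect_lt(max(abs(coef(f) - coef(o))), 1e-8)
  expect_equal(sigma(f), summary(o)$sigma, tolerance = 1e-6)
  expect_identical(varParams(f)$type, "none")
})

test_that("group SD ratios are recovered from heteroscedastic data", {
  set.seed(42)
  n <- 200
  d <- data.frame(g = factor(rep(c("A", "B"), each = n / 2)),
                  x = runif(n))
  d$y <- 2 + d$x + rnorm(n, 0, ifelse(d$g == "A", 1, 3))
  f <- fitGls(y ~ x, d, varIdent = "g")
  dhat <- varParams(f)$estimates["B"]
  expect_lt(abs(dhat - 3) / 3, 0.2)
})

test_that("GLS with variance weights agrees with the nlme reference fit", {
  skip_if_not_installed("nlme")
  d <- simulateTrajectories(defaultScenarios()[c("Control", "High", "Low")],
                            40, seed = 5)
  f <- fitGls(b ~ trial * exposure_min, d, varIdent = "trial")
  g <- nlme::gls(b ~ trial * exposure_min, d,
                 weights = nlme::varIdent(form = ~ 1 | trial),
                 method = "REML")
  expect_lt(max(abs(coef(f) - coef(g))), 1e-6)
  expect_equal(logLik(f)[1], as.numeric(logLik(g)), tolerance = 1e-6)
  expect_lt(max(abs(sqrt(diag(vcov(f))) - sqrt(diag(g$varBeta)))), 1e-4)
  nlmeDelta <- coef(g$modelStruct$varStruct, unconstrained = FALSE,
                    allCoef = TRUE)
  expect_equal(unname(varParams(f)$estimates[names(nlmeDelta)]),
               unname(nlmeDelta), tolerance = 1e-4)
})

test_that("trajectories at the High rate recover the printed slope by GLS", {
  slopes <- recoverScenarioSlopes("High", 15, nReps = 5, seeds = 11:15)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.82)), 3 * max(se, 0.02))
})

test_that("Wald-F is reproducible, powered, and rejects unknown terms", {
  set.seed(44)
  d <- data.frame(g = factor(rep(c("A", "B"), each = 40)), x = runif(80))
  d$y <- 1 + 5 * (d$g == "B") + rnorm(80)      # 5 SD effect
  f <- fitGls(y ~ g + x, d, varIdent = "g")
  t1 <- waldF(f, "g")
  t2 <- waldF(fitGls(y ~ g + x, d, varIdent = "g"), "g")
  expect_equal(testStatistic(t1), testStatistic(t2), tolerance = 1e-10)
  expect_lt(pValue(t1), 1e-10)
  expect_error(waldF(f, "z"), "not in the model")
  expect_identical(t1@testType, "Wald-F")
  expect_equal(t1@dfDenom, 80 - 3)
})

test_that("the vitality screening step drops null terms and keeps real ones", {
  set.seed(45)
  d <- data.frame(v = factor(rep(c("yes", "no"), 40)), x = runif(80))
  d$y <- 1 + d$x + rnorm(80)
  f <- fitGls(y ~ v + x, d)
  out <- dropIfNonsignificant(f, "v")
  expect_true(out$dropped)
  expect_false("v" %in% out$fit@modelInfo$termLabels)

  d$y2 <- 1 + d$x + 4 * (d$v == "yes") + rnorm(80)
  f2 <- fitGls(y2 ~ v + x, d)
  out2 <- dropIfNonsignificant(f2, "v")
  expect_false(out2$dropped)

  out3 <- dropIfNonsignificant(f, "absent_term")
  expect_false(out3$dropped)
  expect_null(out3$test)
})
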