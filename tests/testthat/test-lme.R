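# Random-intercept mixed models, ML refits and likelihood-ratio tests.

test_that("with no group variance the LME log-likelihood meets the GLS one", {
  set.seed(51)
  d <- data.frame(g = factor(rep(1:10, each = 5)), x = runif(50))
  d$y <- 1 + d$x + rnorm(50)                 # tau = 0 truth
  fl <- fitLme(y ~ x, d, random = "g")
  fg <- fitGls(y ~ x, d)
  expect_gte(fl@logLik, fg@logLik - 1e-6)
  expect_lt(fl@logLik - fg@logLik, 0.5)      # boundary estimate, tiny gain
  expect_lt(randomSD(fl)[1], 0.4)
})

test_that("random-intercept SD is recovered (30 groups x 10 obs)", {
  set.seed(52)
  g <- factor(rep(1:30, each = 10))
  d <- data.frame(g = g, x = runif(300))
  d$y <- 2 + d$x + rnorm(30)[as.integer(g)] + rnorm(300)
  f <- fitLme(y ~ x, d, random = "g")
  expect_gte(randomSD(f)[1], 0.7)
  expect_lte(randomSD(f)[1], 1.3)
})

test_that("LME fits agree with the nlme reference, single and nested", {
  skip_if_not_installed("nlme")
  pm <- simulatePostmortem(15, drop = 5, seed = 7)
  f <- fitLme(b ~ time_h + storage, pm, random = "fish_id")
  l <- nlme::lme(b ~ time_h + storage, random = ~ 1 | fish_id, data = pm,
                 method = "REML")
  expect_lt(max(abs(coef(f) - nlme::fixef(l))), 1e-6)
  expect_equal(f@logLik, as.numeric(logLik(l)), tolerance = 1e-6)
  expect_equal(unname(randomSD(f)[1]),
               as.numeric(nlme::VarCorr(l)[1, 2]), tolerance = 1e-3)

  co <- simulateCohort(cohortSpec(nFish = 8L, seed = 3L))
  f2 <- fitLme(b ~ lactate, co, random = c("trial", "monitoring_period"))
  l2 <- nlme::lme(b ~ lactate, random = ~ 1 | trial / monitoring_period,
                  data = co, method = "REML")
  expect_equal(f2@logLik, as.numeric(logLik(l2)), tolerance = 1e-5)
  expect_lt(max(abs(coef(f2) - nlme::fixef(l2))), 1e-4)
})

test_that("optimizer REML maximum matches a brute-force grid on a small instance", {
  set.seed(53)
  g <- factor(rep(1:4, each = 3))           # 12 observations
  X <- cbind(1, runif(12))
  Z <- outer(as.integer(g), 1:4, "==") * 1
  y <- X %*% c(1, 2) + rnorm(4, 0, 1.2)[as.integer(g)] + rnorm(12, 0, 0.8)
  d <- data.frame(y = as.vector(y), x = X[, 2], g = g)
  f <- fitLme(y ~ x, d, random = "g")
  sig <- sigma(f); tau <- randomSD(f)[1]
  grid <- expand.grid(s = seq(0.9 * sig, 1.1 * sig, length.out = 81),
                      t = seq(max(0.7 * tau, 1e-3), 1.3 * tau + 0.05,
                              length.out = 81))
  lls <- mapply(function(s, t) remlLogLikBrute(d$y, X, Z, s, t),
                grid$s, grid$t)
  expect_gte(f@logLik, max(lls) - 1e-6)
  expect_lt(abs(f@logLik - max(lls)), 1e-3)
})

test_that("model generality orders the REML log-likelihoods OLS <= GLS <= LME", {
  set.seed(54)
  d <- data.frame(g = factor(rep(1:8, each = 10)), x = runif(80))
  d$y <- 1 + d$x + rnorm(8, 0, 1)[as.integer(d$g)] +
    rnorm(80, 0, ifelse(as.integer(d$g) %% 2 == 0, 1, 2))
  d$vg <- factor(as.integer(d$g) %% 2)
  ols <- fitGls(y ~ x, d)
  gls <- fitGls(y ~ x, d, varIdent = "vg")
  lme <- fitLme(y ~ x, d, random = "g", varIdent = "vg")
  expect_gte(gls@logLik, ols@logLik - 1e-8)
  expect_gte(lme@logLik, gls@logLik - 1e-8)
})

test_that("LRT behaves at the null, under signal, and on misuse", {
  pm <- simulatePostmortem(12, drop = 5, seed = 8)
  f1 <- fitLme(b ~ time_h, pm, random = "fish_id")
  f0 <- fitLme(b ~ 1, pm, random = "fish_id")
  t <- lrt(f1, f0)
  expect_identical(t@testType, "LRT")
  expect_equal(t@df, 3)
  expect_lt(pValue(t), 0.001)
  # identical models: statistic 0
  t0 <- lrt(f0, fitLme(b ~ 1, pm, random = "fish_id"))
  expect_equal(testStatistic(t0), 0, tolerance = 1e-6)
  # non-nested detection
  f2 <- fitLme(b ~ storage, pm, random = "fish_id")
  expect_error(lrt(f2, f1), "not nested")
  # ML refit happens automatically from REML fits
  expect_identical(f1@method, "REML")
  expect_gt(testStatistic(t), 0)
})

test_that("null LRT statistics follow the chi-square reference distribution", {
  set.seed(55)
  stats <- replicate(300, {
    d <- data.frame(g = factor(rep(1:10, each = 6)), x = rnorm(60))
    d$y <- rnorm(60) + rnorm(10)[as.integer(d$g)]
    f1 <- fitLme(y ~ x, d, random = "g", method = "ML")
    f0 <- fitLme(y ~ 1, d, random = "g", method = "ML")
    testStatistic(lrt(f1, f0))
  })
  ks <- ks.test(stats, function(q) pchisq(q, 1))
  expect_gt(ks$p.value, 0.01)
})
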