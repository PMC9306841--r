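# Shared fixtures: the full calibrated measurement chain on a
# rendered scene, as the pipeline applies it (decode ->
# exposure-normalize -> matrix-correct -> convert).

measureRenderedFish <- function(scene, camMatrix, gainChart, gainFish,
                                headroom = 0.75, threshold = "otsu") {
  chart <- renderChartImage(cameraModel(camMatrix, gainChart,
                                        headroom = headroom))
  fish <- renderFishImage(scene, cameraModel(camMatrix, gainFish,
                                             headroom = headroom))
  measured <- measureChartPatches(chart$image, chart$patches)
  ref <- as.matrix(chart$patches[, c("R", "G", "B")])
  chartGain <- ref[6, "G"] / measured[6, "G"]   # brightest neutral patch
  corr <- fitCorrection(measured * chartGain, ref)
  refWhite <- labToLinearRgb(scene@backgroundLab)[2]
  en <- exposureNormalize(srgbDecode(fish$image), c(10, 5, 200, 30),
                          refWhite)
  roi <- roiSpec(scene@fishRegion[1] + 10, scene@fishRegion[2] + 10)
  thumb <- extractThumbnail(fish$image, roi)
  mk <- stripeMask(thumb, threshold)
  cm <- measureColour(thumb, mk$mask, corr, gain = en$gain)
  list(lab = labMean(cm), measurement = cm, mask = mk, fish = fish,
       correction = corr, exposure = en, roi = roi)
}

# Scenario-slope recovery: Control + one crowded scenario, trial x
# exposure GLS with per-trial variance weights; returns the crowded
# trial's fitted slope per replicate.
recoverScenarioSlopes <- function(name, window, nReps = 10, n = 40,
                                  seeds = seq_len(nReps)) {
  scen <- defaultScenarios()
  sapply(seeds, function(s) {
    d <- simulateTrajectories(scen[c("Control", name)], n,
                              samplingWindow = window, seed = s)
    d$trial <- stats::relevel(factor(d$trial), ref = "Control")
    f <- fitGls(b ~ trial * exposure_min, d, varIdent = "trial")
    cf <- coef(f)
    unname(cf["exposure_min"] + cf[paste0("trial", name, ":exposure_min")])
  })
}

# Independent brute-force REML log-likelihood for a random-intercept
# model, built directly from the marginal covariance (no profiling,
# no shared code with the fitting engine).
remlLogLikBrute <- function(y, X, Z, sigma, tau) {
  n <- length(y); p <- ncol(X)
  V <- sigma^2 * diag(n) + tau^2 * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}
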