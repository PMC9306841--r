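# Central S4 containers. Validity methods enforce the structural
# invariants the rest of the package relies on.

#' CorrectionModel: chart-fitted colour correction
#'
#' A 3x3 linear-RGB correction matrix plus a scalar exposure gain and
#' the RMS patch residual of the least-squares fit. Produced by
#' [fitCorrection()] and consumed by [measureColour()].
#'
#' @slot matrix 3x3 invertible matrix applied to linear-RGB column
#'   vectors (camera colour -> reference colour).
#' @slot gain Positive scalar exposure gain (1 when exposure is
#'   handled separately by [exposureNormalize()]).
#' @slot fitResidual RMS residual of the patch fit, linear-RGB units.
#' @export
setClass("CorrectionModel",
  representation(matrix = "matrix", gain = "numeric", fitResidual = "numeric"),
  prototype(matrix = diag(3), gain = 1, fitResidual = 0))

setValidity("CorrectionModel", function(object) {
  msg <- character()
  if (!all(dim(object@matrix) == c(3L, 3L)))
    msg <- c(msg, "matrix must be 3x3")
  else if (abs(det(object@matrix)) < 1e-12)
    msg <- c(msg, "matrix must be invertible")
  if (length(object@gain) != 1L || object@gain <= 0)
    msg <- c(msg, "gain must be a positive scalar")
  if (object@fitResidual < 0)
    msg <- c(msg, "fitResidual must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ColourMeasurement: masked mean CIELAB of one thumbnail
#'
#' @slot meanLab Named numeric (L, a, b): mean CIELAB over kept pixels.
#' @slot nPixelsUsed Number of pixels entering the mean.
#' @slot maskFraction Fraction of thumbnail pixels kept by the stripe
#'   mask, in (0, 1].
#' @slot thresholdValue Green-plane threshold used by the mask.
#' @slot reliable FALSE when fewer than 50 pixels survived the mask.
#' @export
setClass("ColourMeasurement",
  representation(meanLab = "numeric", nPixelsUsed = "integer",
                 maskFraction = "numeric", thresholdValue = "numeric",
                 reliable = "logical"),
  prototype(meanLab = c(L = NA_real_, a = NA_real_, b = NA_real_),
            nPixelsUsed = 0L, maskFraction = 1, thresholdValue = NA_real_,
            reliable = TRUE))

setValidity("ColourMeasurement", function(object) {
  msg <- character()
  if (length(object@meanLab) != 3L) msg <- c(msg, "meanLab must have length 3")
  if (object@maskFraction <= 0 || object@maskFraction > 1)
    msg <- c(msg, "maskFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ModelFit: one fitted variance-structured linear model
#'
#' Common container for GLS (group-wise variance weights),
#' random-intercept LME and penalized-spline mixed fits. Fixed-effect
#' estimates are reported with their covariance; variance-structure
#' parameters are on the natural scale (SD ratios with the reference
#' level fixed at 1, or the power exponent for power-of-mean
#' variance).
#'
#' @slot coefficients Named fixed-effect estimates.
#' @slot vcov Covariance matrix of the fixed effects.
#' @slot sigma Residual SD (reference-level scale).
#' @slot varStruct List describing the residual variance structure:
#'   `type` ("none", "varIdent" or "varPower") plus its estimates.
#' @slot randomSD Named SDs of the random-intercept terms (empty for
#'   GLS).
#' @slot logLik Maximised log-likelihood at `method`.
#' @slot method "REML" or "ML".
#' @slot nobs,pFixed Observation count and fixed-effect rank.
#' @slot fitted,residuals Population-level fitted values and raw
#'   residuals.
#' @slot converged Optimizer convergence flag.
#' @slot modelInfo List carrying the term structure and refit
#'   specification (used by [waldF()], [lrt()] and [refitML()]).
#' @export
setClass("ModelFit",
  representation(coefficients = "numeric", vcov = "matrix", sigma = "numeric",
                 varStruct = "list", randomSD = "numeric", logLik = "numeric",
                 method = "character", nobs = "integer", pFixed = "integer",
                 fitted = "numeric", residuals = "numeric",
                 converged = "logical", modelInfo = "list"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be a positive finite scalar")
  if (object@converged && !is.finite(object@logLik))
    msg <- c(msg, "logLik must be finite at convergence")
  if (!object@method %in% c("REML", "ML"))
    msg <- c(msg, "method must be 'REML' or 'ML'")
  if (length(msg)) msg else TRUE
})

#' TestResult: one Wald-F or likelihood-ratio test
#'
#' @slot statistic Test statistic (F or LRT chi-square), non-negative.
#' @slot df Numerator df (Wald-F) or df difference (LRT).
#' @slot dfDenom Denominator df (Wald-F only, NA for LRT).
#' @slot pValue p-value in \[0, 1\].
#' @slot testType "Wald-F" or "LRT".
#' @slot term Label of the term tested.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", dfDenom = "numeric",
                 pValue = "numeric", testType = "character", term = "character"),
  prototype(dfDenom = NA_real_, term = NA_character_))

setValidity("TestResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
  if (object@df < 1) msg <- c(msg, "df must be >= 1")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SceneSpec: geometry and ground-truth colour of a synthetic dorsal image
#'
#' The dorsal surface is modelled as a rectangle of alternating dark
#' and light stripes on a white background; the light inter-stripe
#' colour is the quantity the measurement pipeline must recover.
#'
#' @slot imageSize Integer (height, width) in pixels.
#' @slot fishRegion Integer (x, y, width, height), 0-based top-left,
#'   strictly inside the image.
#' @slot stripePeriod Stripe period in pixel rows.
#' @slot stripeDuty Fraction of each period that is dark stripe,
#'   in (0, 1).
#' @slot lightLab,darkLab,backgroundLab Ground-truth CIELAB of the
#'   light inter-stripe skin, the dark stripes and the white
#'   background; background L* > light L* > dark L*.
#' @slot seed Integer seed for any stochastic scene elements.
#' @export
setClass("SceneSpec",
  representation(imageSize = "integer", fishRegion = "integer",
                 stripePeriod = "integer", stripeDuty = "numeric",
                 lightLab = "numeric", darkLab = "numeric",
                 backgroundLab = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@stripeDuty <= 0 || object@stripeDuty >= 1)
    msg <- c(msg, "stripeDuty must lie strictly in (0, 1)")
  r <- object@fishRegion; s <- object@imageSize
  if (r[3] <= 0 || r[4] <= 0) msg <- c(msg, "degenerate fish region")
  if (r[1] <= 0 || r[2] <= 0 || r[1] + r[3] >= s[2] || r[2] + r[4] >= s[1])
    msg <- c(msg, "fishRegion must lie strictly inside the image")
  if (!(object@backgroundLab[1] > object@lightLab[1] &&
        object@lightLab[1] > object@darkLab[1]))
    msg <- c(msg, "need background L* > light L* > dark L*")
  if (length(msg)) msg else TRUE
})

#' CameraModel: linear-RGB camera/flash distortion
#'
#' Applied in linear RGB as `gain * M %*% rgb`, followed by sRGB
#' encoding and 8-bit quantization. Stands in for camera colour
#' rendering plus flash-to-flash exposure inconsistency.
#'
#' @slot camMatrix Invertible 3x3 matrix in linear RGB.
#' @slot exposureGain Positive scalar flash gain.
#' @slot headroom Highlight-protection factor in (0, 1\]: a fixed
#'   scalar applied with the gain, emulating the raw-capture headroom
#'   that keeps a bright white background below clipping even at the
#'   top of the flash-gain range. It cancels through white-reference
#'   exposure normalisation exactly like the gain itself.
#' @slot quantization Bit depth of the rendered image (default 8).
#' @slot seed Integer seed.
#' @export
setClass("CameraModel",
  representation(camMatrix = "matrix", exposureGain = "numeric",
                 headroom = "numeric", quantization = "integer",
                 seed = "integer"),
  prototype(camMatrix = diag(3), exposureGain = 1, headroom = 1,
            quantization = 8L, seed = 1L))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (!all(dim(object@camMatrix) == c(3L, 3L)) ||
      abs(det(object@camMatrix)) < 1e-12)
    msg <- c(msg, "camMatrix must be an invertible 3x3 matrix")
  if (object@exposureGain <= 0) msg <- c(msg, "exposureGain must be > 0")
  if (object@headroom <= 0 || object@headroom > 1)
    msg <- c(msg, "headroom must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' TrialScenario: one crowding treatment condition
#'
#' Named treatment with its crowding density, duration, and the
#' parameters of the linear b* drift the trajectory generator uses:
#' baseline b*, signed rate per minute, and residual SD.
#'
#' @slot name One of "Control", "Low", "Moderate", "High",
#'   "HighProlonged".
#' @slot density Crowding density, kg/m^3.
#' @slot duration Treatment duration, minutes (> 0).
#' @slot b0 Baseline b* at exposure 0.
#' @slot rate Signed b* change per minute (0 for Control).
#' @slot sigma Residual SD in b* units (> 0).
#' @export
setClass("TrialScenario",
  representation(name = "character", density = "numeric",
                 duration = "numeric", b0 = "numeric", rate = "numeric",
                 sigma = "numeric"))

setValidity("TrialScenario", function(object) {
  msg <- character()
  if (!object@name %in% c("Control", "Low", "Moderate", "High", "HighProlonged"))
    msg <- c(msg, "unknown scenario name")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@name == "Control" && object@rate != 0)
    msg <- c(msg, "Control scenario must have rate 0")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: physiology cohort generator settings
#'
#' Simulates fish whose b* is a monotone-decreasing function of plasma
#' lactate plus nested random intercepts (monitoring period within
#' trial) and residual noise; glucose and cortisol are generated
#' independently of b*.
#'
#' @slot nFish Fish per trial x period cell.
#' @slot lactateLink Named numeric: `high` and `low` asymptotes (b*
#'   units), `mid` (lactate at the midpoint) and `steep` (> 0, logistic
#'   steepness). Strictly decreasing from `high` to `low` requires
#'   `high > low`.
#' @slot trialSD,periodSD Random-intercept SDs (b* units), >= 0.
#' @slot residualSD Residual SD (b* units), >= 0.
#' @slot seed Integer seed.
#' @export
setClass("CohortSpec",
  representation(nFish = "integer", lactateLink = "numeric",
                 trialSD = "numeric", periodSD = "numeric",
                 residualSD = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  l <- object@lactateLink
  need <- c("high", "low", "mid", "steep")
  if (!all(need %in% names(l)))
    msg <- c(msg, "lactateLink needs components high, low, mid, steep")
  else if (l["high"] <= l["low"] || l["steep"] <= 0)
    msg <- c(msg, "lactateLink must be strictly decreasing (high > low, steep > 0)")
  if (object@trialSD < 0 || object@periodSD < 0 || object@residualSD < 0)
    msg <- c(msg, "all SDs must be >= 0")
  if (length(msg)) msg else TRUE
})
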