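# Constructors for the synthetic-study building blocks: scenes,
# camera models, trial scenarios and physiology cohort specs.

## Run `expr` under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Construct a SceneSpec
#'
#' Describes one synthetic dorsal photograph: a striped fish rectangle
#' on a white background, with known ground-truth CIELAB colours. The
#' defaults give a fish strip comfortably larger than the standard
#' 530 x 53 measurement ROI.
#'
#' @param imageSize Integer (height, width) in pixels.
#' @param fishRegion Integer (x, y, width, height), 0-based top-left.
#' @param stripePeriod Stripe period in pixel rows.
#' @param stripeDuty Dark-stripe fraction of each period, in (0, 1).
#' @param lightLab Ground-truth CIELAB of the light inter-stripe skin
#'   (default: the control-fish colour).
#' @param darkLab CIELAB of the dark stripes.
#' @param backgroundLab CIELAB of the white background.
#' @param seed Integer seed.
#' @return A [SceneSpec-class].
#' @export
#' @examples
#' sceneSpec()
sceneSpec <- function(imageSize = c(200L, 600L),
                      fishRegion = c(30L, 60L, 540L, 80L),
                      stripePeriod = 16L, stripeDuty = 0.5,
                      lightLab = c(47.67, -9.27, 17.17),
                      darkLab = c(20, -2, 0),
                      backgroundLab = c(95, 0, 2),
                      seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      fishRegion = as.integer(fishRegion),
      stripePeriod = as.integer(stripePeriod), stripeDuty = stripeDuty,
      lightLab = as.numeric(lightLab), darkLab = as.numeric(darkLab),
      backgroundLab = as.numeric(backgroundLab), seed = as.integer(seed))
}

#' Construct a CameraModel
#'
#' @param camMatrix Invertible 3x3 matrix applied in linear RGB.
#' @param exposureGain Positive scalar flash gain.
#' @param headroom Highlight-protection factor in (0, 1\] (1 = none).
#' @param quantization Bit depth (0 disables quantization; default 8).
#' @param seed Integer seed.
#' @return A [CameraModel-class].
#' @export
#' @examples
#' cameraModel()                      # identity camera
cameraModel <- function(camMatrix = diag(3), exposureGain = 1,
                        headroom = 1, quantization = 8L, seed = 1L) {
  new("CameraModel", camMatrix = camMatrix, exposureGain = exposureGain,
      headroom = headroom, quantization = as.integer(quantization),
      seed = as.integer(seed))
}

#' Draw a random distorting camera
#'
#' Near-identity 3x3 colour distortion (identity plus independent
#' Normal(0, `distortionSD`) entries, row-normalised so white stays
#' near white) and a flash gain drawn uniformly in `gainRange`. The
#' fixed highlight headroom keeps the white background below clipping
#' across the whole gain range, as raw capture with protected
#' highlights would; it cancels through exposure normalisation, so
#' the perturbation stays invertible.
#'
#' @param seed Integer seed.
#' @param gainRange Length-2 range for the exposure gain.
#' @param distortionSD SD of the matrix perturbation entries.
#' @param headroom Highlight-protection factor.
#' @param quantization Bit depth of the rendered images.
#' @return A [CameraModel-class].
#' @export
randomCameraModel <- function(seed = 1L, gainRange = c(0.7, 1.3),
                              distortionSD = 0.03, headroom = 0.75,
                              quantization = 8L) {
  .withSeed(seed, {
    M <- diag(3) + matrix(stats::rnorm(9, 0, distortionSD), 3, 3)
    M <- M / rowSums(M)        # keep neutral colours neutral-ish
    g <- stats::runif(1, gainRange[1], gainRange[2])
    cameraModel(camMatrix = M, exposureGain = g, headroom = headroom,
                quantization = quantization, seed = seed)
  })
}

#' Construct a TrialScenario
#'
#' @param name Scenario name: "Control", "Low", "Moderate", "High" or
#'   "HighProlonged".
#' @param density Crowding density, kg/m^3.
#' @param duration Treatment duration, minutes.
#' @param b0 Baseline b*.
#' @param rate Signed b* change per minute.
#' @param sigma Residual SD, b* units.
#' @return A [TrialScenario-class].
#' @export
trialScenario <- function(name, density, duration, b0 = 17.17, rate = 0,
                          sigma = 2.0) {
  new("TrialScenario", name = name, density = density, duration = duration,
      b0 = b0, rate = rate, sigma = sigma)
}

#' Default crowding scenarios
#'
#' The five study conditions: an uncrowded control and four crowding
#' treatments. Densities and durations follow the trial table of the
#' study design; the signed per-minute b* rates are the fitted rates
#' the trajectory analysis reports (reductions of 0.25, 0.82 and 0.20
#' b* units/min for Low, High and HighProlonged; a 0.30 increase for
#' Moderate), and the control drifts at rate 0. Baseline b* is the
#' control mean 17.17 throughout; residual SD defaults to 2.0 b*
#' units.
#'
#' @param b0 Baseline b* shared by all scenarios.
#' @param sigma Residual SD shared by all scenarios.
#' @return Named list of [TrialScenario-class] objects.
#' @export
#' @examples
#' names(defaultScenarios())
defaultScenarios <- function(b0 = 17.17, sigma = 2.0) {
  list(
    Control       = trialScenario("Control",        0.76, 112, b0,  0.00, sigma),
    Low           = trialScenario("Low",           92.00,  15, b0, -0.25, sigma),
    Moderate      = trialScenario("Moderate",     146.21,  13, b0,  0.30, sigma),
    High          = trialScenario("High",         179.87,  15, b0, -0.82, sigma),
    HighProlonged = trialScenario("HighProlonged", 182.75,  68, b0, -0.20, sigma))
}

#' Construct a CohortSpec
#'
#' @param nFish Fish per trial x period cell.
#' @param lactateLink Named numeric (`high`, `low`, `mid`, `steep`):
#'   b* falls from `high` to `low` along a logistic in lactate centred
#'   at `mid` with steepness `steep`.
#' @param trialSD,periodSD,residualSD SDs in b* units.
#' @param seed Integer seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nFish = 10L,
                       lactateLink = c(high = 20, low = 5, mid = 8, steep = 0.4),
                       trialSD = 1.0, periodSD = 1.0, residualSD = 2.0,
                       seed = 1L) {
  new("CohortSpec", nFish = as.integer(nFish), lactateLink = lactateLink,
      trialSD = trialSD, periodSD = periodSD, residualSD = residualSD,
      seed = as.integer(seed))
}

#' Evaluate the lactate -> b* link
#'
#' Monotone-decreasing logistic
#' \eqn{f(x) = low + (high - low) / (1 + e^{steep (x - mid)})}.
#'
#' @param lactate Numeric vector of plasma lactate values (mmol/L).
#' @param link Named link parameters as in [cohortSpec()].
#' @return Expected b* at each lactate value.
#' @export
lactateLink <- function(lactate, link = c(high = 20, low = 5, mid = 8,
                                          steep = 0.4)) {
  unname(link["low"] + (link["high"] - link["low"]) /
           (1 + exp(link["steep"] * (lactate - link["mid"]))))
}
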