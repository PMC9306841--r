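# Accessor generics and show methods for the S4 containers.

#' @rdname CorrectionModel-class
#' @param object,x A `CorrectionModel`.
#' @export
setGeneric("ccMatrix", function(object) standardGeneric("ccMatrix"))
#' @rdname CorrectionModel-class
#' @export
setGeneric("ccGain", function(object) standardGeneric("ccGain"))
#' @rdname CorrectionModel-class
#' @export
setGeneric("fitResidual", function(object) standardGeneric("fitResidual"))

#' @rdname CorrectionModel-class
#' @export
setMethod("ccMatrix", "CorrectionModel", function(object) object@matrix)
#' @rdname CorrectionModel-class
#' @export
setMethod("ccGain", "CorrectionModel", function(object) object@gain)
#' @rdname CorrectionModel-class
#' @export
setMethod("fitResidual", "CorrectionModel", function(object) object@fitResidual)

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel (linear-RGB 3x3 + gain)\n")
  print(round(object@matrix, 5))
  cat(sprintf("gain: %.5f   RMS patch residual: %.3g\n",
              object@gain, object@fitResidual))
})

#' @rdname ColourMeasurement-class
#' @param object A `ColourMeasurement`.
#' @export
setGeneric("labMean", function(object) standardGeneric("labMean"))
#' @rdname ColourMeasurement-class
#' @export
setGeneric("maskFraction", function(object) standardGeneric("maskFraction"))
#' @rdname ColourMeasurement-class
#' @export
setGeneric("nPixelsUsed", function(object) standardGeneric("nPixelsUsed"))
#' @rdname ColourMeasurement-class
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))

#' @rdname ColourMeasurement-class
#' @export
setMethod("labMean", "ColourMeasurement", function(object) object@meanLab)
#' @rdname ColourMeasurement-class
#' @export
setMethod("maskFraction", "ColourMeasurement", function(object) object@maskFraction)
#' @rdname ColourMeasurement-class
#' @export
setMethod("nPixelsUsed", "ColourMeasurement", function(object) object@nPixelsUsed)
#' @rdname ColourMeasurement-class
#' @export
setMethod("thresholdValue", "ColourMeasurement", function(object) object@thresholdValue)

setMethod("show", "ColourMeasurement", function(object) {
  cat(sprintf("ColourMeasurement: L* %.2f  a* %.2f  b* %.2f\n",
              object@meanLab[1], object@meanLab[2], object@meanLab[3]))
  cat(sprintf("  %d pixels (%.1f%% of thumbnail), green threshold %.4f%s\n",
              object@nPixelsUsed, 100 * object@maskFraction,
              object@thresholdValue,
              if (object@reliable) "" else "  [UNRELIABLE: < 50 pixels]"))
})

#' @rdname ModelFit-class
#' @param object A `ModelFit`.
#' @export
setGeneric("varParams", function(object) standardGeneric("varParams"))
#' @rdname ModelFit-class
#' @export
setGeneric("randomSD", function(object) standardGeneric("randomSD"))

#' @rdname ModelFit-class
#' @export
setMethod("varParams", "ModelFit", function(object) object@varStruct)
#' @rdname ModelFit-class
#' @export
setMethod("randomSD", "ModelFit", function(object) object@randomSD)

#' @rdname ModelFit-class
#' @export
setMethod("coef", "ModelFit", function(object, ...) object@coefficients)
#' @rdname ModelFit-class
#' @export
setMethod("vcov", "ModelFit", function(object, ...) object@vcov)
#' @rdname ModelFit-class
#' @param x A `ModelFit` (for `logLik`).
#' @param ... Unused.
#' @export
setMethod("logLik", "ModelFit", function(object, ...) {
  structure(object@logLik, df = object@pFixed + length(object@randomSD) +
              length(object@varStruct$estimates) + 1,
            nobs = object@nobs, class = "logLik")
})
#' @rdname ModelFit-class
#' @export
setMethod("sigma", "ModelFit", function(object, ...) object@sigma)
#' @rdname ModelFit-class
#' @export
setMethod("fitted", "ModelFit", function(object, ...) object@fitted)
#' @rdname ModelFit-class
#' @export
setMethod("residuals", "ModelFit", function(object, ...) object@residuals)

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit (%s, %s): %d obs, logLik %.3f%s\n",
              object@modelInfo$kind %||% "linear", object@method,
              object@nobs, object@logLik,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  est <- object@coefficients
  se <- sqrt(diag(object@vcov))
  print(round(cbind(Estimate = est, SE = se), 4))
  cat(sprintf("residual SD: %.4f\n", object@sigma))
  if (length(object@randomSD))
    cat("random-intercept SDs:",
        paste(sprintf("%s = %.4f", names(object@randomSD), object@randomSD),
              collapse = ", "), "\n")
  vs <- object@varStruct
  if (!is.null(vs$type) && vs$type != "none")
    cat(sprintf("variance structure %s:", vs$type),
        paste(sprintf("%s = %.4f", names(vs$estimates), vs$estimates),
              collapse = ", "), "\n")
})

#' @rdname TestResult-class
#' @param object A `TestResult`.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname TestResult-class
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname TestResult-class
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)
#' @rdname TestResult-class
#' @export
setMethod("testStatistic", "TestResult", function(object) object@statistic)

setMethod("show", "TestResult", function(object) {
  if (object@testType == "Wald-F")
    cat(sprintf("Wald F test, term '%s': F = %.4f, df = (%g, %g), P = %.4g\n",
                object@term, object@statistic, object@df, object@dfDenom,
                object@pValue))
  else
    cat(sprintf("Likelihood ratio test%s: LRT = %.4f, df = %g, P = %.4g\n",
                if (is.na(object@term)) "" else sprintf(" ('%s')", object@term),
                object@statistic, object@df, object@pValue))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
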