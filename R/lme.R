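# Random-intercept linear mixed models (one grouping factor, or two
# nested), likelihood-ratio testing and ML refits.

## Indicator matrix of a factor (n x nlevels).
.indicator <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Fit a random-intercept linear mixed model
#'
#' Fixed effects plus Gaussian random intercepts for one grouping
#' factor or two nested factors (`random = c("trial", "period")`
#' means period nested within trial), optionally with group-wise
#' residual variance weights. Estimation maximises the marginal
#' REML (default) or ML likelihood over the log variance ratios with
#' fixed effects and residual scale profiled out; fixed effects are
#' the generalised least-squares solution at the optimum. Singular
#' fits are reported with the corresponding SD estimated at
#' (numerically) zero, not raised as errors.
#'
#' @param formula Fixed-effects formula.
#' @param data data.frame with all variables.
#' @param random Character vector of 1 or 2 grouping column names;
#'   with 2, the second is nested within the first. Each needs >= 2
#'   levels.
#' @param varIdent Optional factor name for group-wise residual SDs.
#' @param method "REML" (default) or "ML".
#' @return A [ModelFit-class]; `randomSD()` returns the intercept SDs.
#' @export
#' @examples
#' d <- simulatePostmortem(8, drop = 5, seed = 2)
#' fitLme(b ~ time_h, d, random = "fish_id")
fitLme <- function(formula, data, random, varIdent = NULL,
                   method = "REML") {
  stopifnot(length(random) %in% 1:2)
  des <- .buildDesign(formula, data)
  Zlist <- list()
  g1 <- factor(data[[random[1]]])
  if (nlevels(g1) < 2L) stop("grouping factor '", random[1],
                             "' needs >= 2 levels")
  Zlist[[random[1]]] <- .indicator(g1)
  if (length(random) == 2L) {
    g2 <- factor(paste(g1, data[[random[2]]], sep = ":"))
    if (nlevels(g2) < 2L) stop("nested factor '", random[2],
                               "' needs >= 2 levels")
    Zlist[[paste(random, collapse = ":")]] <- .indicator(g2)
  }
  vg <- if (is.null(varIdent)) NULL else factor(data[[varIdent]])
  fit <- .lmmFit(des$y, des$X, Zlist = Zlist, vg = vg, method = method)
  rsd <- sqrt(fit$s2 * fit$psi)
  names(rsd) <- names(Zlist)
  vs <- if (is.null(vg) || nlevels(vg) < 2L)
    list(type = "none", estimates = numeric(0))
  else list(type = "varIdent", estimates = fit$delta)
  beta <- fit$beta; names(beta) <- colnames(des$X)
  vc <- fit$covBeta; dimnames(vc) <- list(names(beta), names(beta))
  new("ModelFit", coefficients = beta, vcov = vc, sigma = sqrt(fit$s2),
      varStruct = vs, randomSD = rsd, logLik = fit$ll, method = method,
      nobs = length(des$y), pFixed = ncol(des$X),
      fitted = fit$fitted, residuals = des$y - fit$fitted,
      converged = fit$converged,
      modelInfo = list(kind = "LME", assign = des$assign,
                       termLabels = des$termLabels,
                       refit = list(fitter = "lme", formula = formula,
                                    data = data, random = random,
                                    varIdent = varIdent)))
}

#' Refit a model by maximum likelihood
#'
#' Re-runs the stored fit specification with `method = "ML"`; used by
#' [lrt()] so that fixed-effect structures are always compared on ML
#' likelihoods (REML likelihoods are not comparable across different
#' fixed effects).
#'
#' @param fit A [ModelFit-class].
#' @return The ML [ModelFit-class] (returned as-is if already ML).
#' @export
refitML <- function(fit) {
  if (fit@method == "ML") return(fit)
  rf <- fit@modelInfo$refit
  switch(rf$fitter,
    gls = fitGls(rf$formula, rf$data, varIdent = rf$varIdent, method = "ML"),
    lme = fitLme(rf$formula, rf$data, random = rf$random,
                 varIdent = rf$varIdent, method = "ML"),
    spline = fitSplineMixed(rf$data, response = rf$response,
                            smooth = rf$smooth, random = rf$random,
                            basisDims = rf$basisDim, varPower = rf$varPower,
                            method = "ML"),
    stop("cannot refit model kind '", rf$fitter, "'"))
}

#' Likelihood ratio test of nested fits
#'
#' \eqn{LRT = 2(\ell_{full} - \ell_{reduced})} against a chi-square
#' with df equal to the parameter-count difference. When the two fits
#' differ in their fixed effects, both are refitted by ML first;
#' nesting is checked by comparing fixed-term sets.
#'
#' @param fitFull,fitReduced Two [ModelFit-class] objects, the second
#'   nested in the first.
#' @return A [TestResult-class].
#' @export
#' @examples
#' d <- simulatePostmortem(8, drop = 5, seed = 3)
#' f1 <- fitLme(b ~ time_h, d, random = "fish_id")
#' f0 <- fitLme(b ~ 1, d, random = "fish_id")
#' lrt(f1, f0)
lrt <- function(fitFull, fitReduced) {
  tf <- fitFull@modelInfo$termLabels
  tr <- fitReduced@modelInfo$termLabels
  if (!all(tr %in% tf))
    stop("models are not nested (reduced fixed terms not a subset)")
  sameFixed <- length(tf) == length(tr) &&
    fitFull@pFixed == fitReduced@pFixed
  if (!sameFixed) {
    fitFull <- refitML(fitFull)
    fitReduced <- refitML(fitReduced)
  } else if (fitFull@method != fitReduced@method) {
    fitFull <- refitML(fitFull)
    fitReduced <- refitML(fitReduced)
  }
  dfF <- attr(logLik(fitFull), "df")
  dfR <- attr(logLik(fitReduced), "df")
  df <- dfF - dfR
  if (df < 1) df <- 1
  stat <- max(0, 2 * (fitFull@logLik - fitReduced@logLik))
  new("TestResult", statistic = stat, df = df, dfDenom = NA_real_,
      pValue = stats::pchisq(stat, df, lower.tail = FALSE),
      testType = "LRT",
      term = setdiff(tf, tr)[1] %||% NA_character_)
}

#' Drop a term when it is not significant
#'
#' Tests `term` in the fitted model (Wald-F for GLS fits, LRT
#' otherwise) and refits without it when p >= `alpha`; the returned
#' object records the decision for audit.
#'
#' @param fit A [ModelFit-class] containing `term` (if absent, the
#'   fit is returned unchanged).
#' @param term Term label to screen (default `"vitality_assessed"`).
#' @param alpha Retention threshold (default 0.05).
#' @return List with `fit` (the chosen model), `dropped` (logical),
#'   `test` (the [TestResult-class], or NULL when absent).
#' @export
dropIfNonsignificant <- function(fit, term = "vitality_assessed",
                                 alpha = 0.05) {
  info <- fit@modelInfo
  if (!term %in% info$termLabels)
    return(list(fit = fit, dropped = FALSE, test = NULL))
  if (info$kind == "GLS") {
    test <- waldF(fit, term)
  } else {
    rf <- info$refit
    reducedFormula <- stats::update.formula(rf$formula,
                                            paste(". ~ . -", term))
    reduced <- fitLme(reducedFormula, rf$data, random = rf$random,
                      varIdent = rf$varIdent, method = fit@method)
    test <- lrt(fit, reduced)
  }
  if (test@pValue >= alpha) {
    rf <- info$refit
    reducedFormula <- stats::update.formula(rf$formula,
                                            paste(". ~ . -", term))
    newFit <- if (info$kind == "GLS")
      fitGls(reducedFormula, rf$data, varIdent = rf$varIdent,
             method = fit@method)
    else
      fitLme(reducedFormula, rf$data, random = rf$random,
             varIdent = rf$varIdent, method = fit@method)
    list(fit = newFit, dropped = TRUE, test = test)
  } else {
    list(fit = fit, dropped = FALSE, test = test)
  }
}
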