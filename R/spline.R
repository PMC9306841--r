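# Penalized cubic-regression-spline mixed model: smooth trend in one
# covariate + optional random intercepts + optional power-of-mean
# residual variance. The spline's second-derivative penalty is
# handled through its mixed-model representation: the penalty null
# space (straight line) is fixed, the wiggles are a random-effect
# block whose variance ratio is the (inverse) smoothing parameter,
# estimated by REML/ML alongside the other variance parameters. The
# basis dimension is chosen by AIC using effective degrees of freedom
# (trace of the smooth's influence), not raw basis size.

## Cubic B-spline basis and second-derivative penalty for dimension K.
.crBasis <- function(x, K, xr = range(x)) {
  stopifnot(K >= 4)
  inner <- if (K > 4)
    stats::quantile(unique(x), probs = seq_len(K - 4) / (K - 3), names = FALSE)
  else numeric(0)
  knots <- c(rep(xr[1], 4), inner, rep(xr[2], 4))
  B <- splines::splineDesign(knots, x, ord = 4)
  xs <- seq(xr[1], xr[2], length.out = 401)
  B2 <- splines::splineDesign(knots, xs, ord = 4, derivs = rep(2L, length(xs)))
  S <- crossprod(B2) * (xs[2] - xs[1])
  eg <- eigen(S, symmetric = TRUE)
  tol <- max(eg$values) * 1e-7
  pos <- eg$values > tol                    # penalty range space (K - 2 dims)
  list(knots = knots, B = B, U = eg$vectors[, pos, drop = FALSE],
       dInvSqrt = 1 / sqrt(eg$values[pos]), xr = xr)
}

.splineZ <- function(basis, x) {
  B <- splines::splineDesign(basis$knots, pmin(pmax(x, basis$xr[1]),
                                               basis$xr[2]), ord = 4)
  B %*% basis$U %*% diag(basis$dInvSqrt, length(basis$dInvSqrt))
}

## One spline-mixed fit at a fixed basis dimension.
.fitSplineK <- function(y, x, K, Zgroups, varPower, method) {
  basis <- .crBasis(x, K)
  Zs <- .splineZ(basis, x)
  X <- cbind("(Intercept)" = 1, x)
  Zlist <- c(list(spline = Zs), Zgroups)
  if (!varPower) {
    fit <- .lmmFit(y, X, Zlist, method = method)
    mu <- NULL
  } else {
    mu <- stats::fitted(stats::lm(y ~ x))
    fit <- NULL
    for (it in 1:8) {
      fit <- .lmmFit(y, X, Zlist, muBase = pmax(abs(mu), 1e-6),
                     method = method)
      uS <- .lmmBlups(fit, Zlist)[[1]]
      muNew <- fit$fitted + as.vector(Zs %*% uS)
      if (max(abs(muNew - mu)) < 1e-6 * (1 + max(abs(mu)))) { mu <- muNew; break }
      mu <- muNew
    }
  }
  edfWiggle <- .lmmEdf(fit, Zs, fit$psi[1])
  list(fit = fit, basis = basis, Zs = Zs, X = X, Zlist = Zlist,
       edf = 1 + edfWiggle, mu = mu)
}

#' Fit a penalized cubic-spline mixed model
#'
#' Smooth Gaussian regression of `response` on `smooth` with a
#' second-derivative penalty, optional nested random intercepts and
#' optional power-of-mean residual variance
#' \eqn{Var(\epsilon_i) = \sigma^2 |\mu_i|^{2\delta}} (estimated by
#' iterating between variance-parameter optimisation and fitted-mean
#' updates). The smoothing parameter is estimated by treating the
#' spline wiggles as a random effect; the basis dimension is selected
#' from `basisDims` by ML-based AIC with effective degrees of freedom
#' counted as the trace of the smooth's influence matrix.
#'
#' @param data data.frame with all variables.
#' @param response,smooth Column names of the response and the smooth
#'   covariate.
#' @param random Optional character vector (length 1 or 2, nested) of
#'   random-intercept grouping columns.
#' @param basisDims Candidate basis dimensions (each >= 4 and at most
#'   the number of distinct covariate values).
#' @param varPower Use power-of-mean residual variance?
#' @param method "REML" (default) or "ML" for the final fit.
#' @return A [ModelFit-class]; the smooth itself is accessed with
#'   [predictSmooth()], its effective degrees of freedom via
#'   `varParams(fit)$edf`.
#' @export
#' @examples
#' d <- simulateCohort(cohortSpec(nFish = 4L))
#' f <- fitSplineMixed(d, "b", "lactate",
#'                     random = c("trial", "monitoring_period"))
#' head(predictSmooth(f, seq(2, 15, by = 1)))
fitSplineMixed <- function(data, response, smooth, random = NULL,
                           basisDims = c(5L, 8L, 10L, 12L),
                           varPower = FALSE, method = "REML") {
  y <- as.numeric(data[[response]])
  x <- as.numeric(data[[smooth]])
  basisDims <- basisDims[basisDims <= length(unique(x))]
  if (!length(basisDims)) stop("no feasible basis dimension")
  Zgroups <- list()
  if (!is.null(random)) {
    g1 <- factor(data[[random[1]]])
    Zgroups[[random[1]]] <- .indicator(g1)
    if (length(random) == 2L) {
      g2 <- factor(paste(g1, data[[random[2]]], sep = ":"))
      Zgroups[[paste(random, collapse = ":")]] <- .indicator(g2)
    }
  }
  # basis-dimension selection on ML likelihoods
  aic <- sapply(basisDims, function(K) {
    fk <- .fitSplineK(y, x, K, Zgroups, varPower, method = "ML")
    nVarPar <- length(fk$fit$theta)
    -2 * fk$fit$ll + 2 * (ncol(fk$X) + (fk$edf - 1) + nVarPar + 1)
  })
  K <- basisDims[which.min(aic)]
  sel <- .fitSplineK(y, x, K, Zgroups, varPower, method = method)
  fit <- sel$fit

  # joint coefficients/covariance of (fixed, spline wiggles) for the
  # smooth curve and its pointwise SEs: Henderson system with the
  # remaining random effects and residual weights in V_r
  n <- length(y)
  v <- fit$v
  Vr <- diag(v, n)
  if (length(Zgroups))
    for (k in seq_along(Zgroups))
      Vr <- Vr + fit$psi[k + 1] * tcrossprod(Zgroups[[k]])
  Rr <- chol(Vr)
  C <- cbind(sel$X, sel$Zs)
  Cw <- forwardsolve(t(Rr), C)
  yw <- forwardsolve(t(Rr), y)
  q <- ncol(sel$Zs)
  D <- diag(c(0, 0, rep(1 / fit$psi[1], q)))
  Hinv <- solve(crossprod(Cw) + D)
  coefJoint <- as.vector(Hinv %*% crossprod(Cw, yw))
  covJoint <- fit$s2 * Hinv

  beta <- fit$beta
  names(beta) <- c("(Intercept)", smooth)
  vc <- fit$covBeta; dimnames(vc) <- list(names(beta), names(beta))
  rsd <- sqrt(fit$s2 * fit$psi)
  names(rsd) <- names(sel$Zlist)
  vs <- if (varPower)
    list(type = "varPower", estimates = c(power = fit$powDelta),
         edf = sel$edf, basisDim = K, aic = stats::setNames(aic, basisDims))
  else
    list(type = "none", estimates = numeric(0), edf = sel$edf,
         basisDim = K, aic = stats::setNames(aic, basisDims))
  new("ModelFit", coefficients = beta, vcov = vc, sigma = sqrt(fit$s2),
      varStruct = vs, randomSD = rsd, logLik = fit$ll, method = method,
      nobs = n, pFixed = 2L,
      fitted = fit$fitted + as.vector(sel$Zs %*% .lmmBlups(fit, sel$Zlist)[[1]]),
      residuals = y - fit$fitted -
        as.vector(sel$Zs %*% .lmmBlups(fit, sel$Zlist)[[1]]),
      converged = fit$converged,
      modelInfo = list(kind = "SplineMixed",
                       assign = c(0L, 1L), termLabels = smooth,
                       basis = sel$basis, coefJoint = coefJoint,
                       covJoint = covJoint, smooth = smooth,
                       refit = list(fitter = "spline", data = data,
                                    response = response, smooth = smooth,
                                    random = random, basisDim = K,
                                    varPower = varPower)))
}

#' Evaluate a fitted smooth with pointwise standard errors
#'
#' @param fit A [ModelFit-class] from [fitSplineMixed()].
#' @param newx Covariate values at which to evaluate the smooth
#'   (clamped to the fitted range).
#' @return data.frame with `x`, `fit` and `se`.
#' @export
predictSmooth <- function(fit, newx) {
  info <- fit@modelInfo
  if (info$kind != "SplineMixed") stop("not a spline mixed fit")
  Zs <- .splineZ(info$basis, newx)
  Cnew <- cbind(1, pmin(pmax(newx, info$basis$xr[1]), info$basis$xr[2]), Zs)
  est <- as.vector(Cnew %*% info$coefJoint)
  se <- sqrt(pmax(rowSums((Cnew %*% info$covJoint) * Cnew), 0))
  data.frame(x = newx, fit = est, se = se)
}
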