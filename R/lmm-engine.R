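# Core estimation engine for every variance-structured model in the
# package: marginal REML/ML likelihood for
#
#   y = X beta + sum_k Z_k u_k + eps,
#   u_k ~ N(0, sigma^2 psi_k I),  eps_i ~ N(0, sigma^2 v_i),
#
# where v_i encodes the residual variance structure: 1 (homoscedastic),
# delta_g^2 per level of a grouping factor with the reference level
# fixed at 1 (group-wise weights), or |mu_i|^(2 delta) (power of the
# fitted mean). beta and sigma^2 are profiled out in closed form;
# the remaining log-variance parameters are maximised numerically with
# a derivative-free simplex started from three fixed points.

## Evaluate the profiled likelihood at theta.
## theta layout: log(psi_k) for each Z block, then log(delta_g) for
## variance groups 2..G, then the power exponent if varPower.
.lmmEval <- function(theta, y, X, Zlist, vg = NULL, muBase = NULL,
                     method = "REML") {
  n <- length(y); p <- ncol(X)
  nZ <- length(Zlist)
  nVG <- if (is.null(vg)) 0L else nlevels(vg)
  usePow <- !is.null(muBase)
  if (any(abs(theta) > 30)) return(list(ll = -1e10))

  psi <- if (nZ) exp(theta[seq_len(nZ)]) else numeric(0)
  v <- rep(1, n)
  delta <- NULL
  if (nVG > 1L) {
    delta <- c(1, exp(theta[nZ + seq_len(nVG - 1L)]))
    names(delta) <- levels(vg)
    v <- delta[as.integer(vg)]^2
  }
  powDelta <- NULL
  if (usePow) {
    powDelta <- theta[length(theta)]
    v <- v * muBase^(2 * powDelta)
  }

  V0 <- diag(v, n)
  for (k in seq_len(nZ)) V0 <- V0 + psi[k] * tcrossprod(Zlist[[k]])
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -1e10))
  logdetV0 <- 2 * sum(log(diag(R)))

  A <- forwardsolve(t(R), X)        # whitened design
  ytil <- forwardsolve(t(R), y)
  AtA <- crossprod(A)
  cAtA <- tryCatch(chol(AtA), error = function(e) NULL)
  if (is.null(cAtA)) return(list(ll = -1e10))
  beta <- backsolve(cAtA, forwardsolve(t(cAtA), crossprod(A, ytil)))
  beta <- as.vector(beta)
  rtil <- ytil - A %*% beta
  q <- sum(rtil^2)

  if (method == "REML") {
    s2 <- q / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetV0 +
                    2 * sum(log(diag(cAtA))) + (n - p))
  } else {
    s2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdetV0 + n)
  }
  list(ll = ll, beta = beta, s2 = s2,
       covBeta = s2 * chol2inv(cAtA),
       fitted = as.vector(X %*% beta), R = R, A = A, rtil = rtil,
       v = v, psi = psi, delta = delta, powDelta = powDelta,
       logdetV0 = logdetV0)
}

## Maximise the profiled likelihood. Returns the evaluation at the
## optimum plus theta and a convergence flag.
.lmmFit <- function(y, X, Zlist = list(), vg = NULL, muBase = NULL,
                    method = "REML") {
  n <- length(y); p <- ncol(X)
  stopifnot(n > p)
  nPar <- length(Zlist) + (if (is.null(vg)) 0L else nlevels(vg) - 1L) +
    (if (is.null(muBase)) 0L else 1L)
  if (nPar == 0L) {
    out <- .lmmEval(numeric(0), y, X, Zlist, vg, muBase, method)
    out$theta <- numeric(0); out$converged <- TRUE
    return(out)
  }
  negll <- function(th) -.lmmEval(th, y, X, Zlist, vg, muBase, method)$ll
  starts <- list(rep(0, nPar), rep(1, nPar), rep(-1, nPar))
  best <- NULL
  for (th0 in starts) {
    opt <- suppressWarnings(
      stats::optim(th0, negll, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 5000)))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  out <- .lmmEval(best$par, y, X, Zlist, vg, muBase, method)
  out$theta <- best$par
  out$converged <- best$convergence == 0 && is.finite(out$ll)
  out
}

## BLUPs of the random-effect blocks at the fitted parameters.
.lmmBlups <- function(fit, Zlist) {
  # V0^{-1} r = R^{-1} rtil
  V0invR <- backsolve(fit$R, fit$rtil)
  lapply(seq_along(Zlist), function(k)
    as.vector(fit$psi[k] * crossprod(Zlist[[k]], V0invR)))
}

## Effective degrees of freedom contributed by one random block when
## its BLUP enters the population-level curve (spline wiggles):
## psi * tr(Z' P Z) with P = V0^{-1} - V0^{-1} X (X'V0^{-1}X)^{-1} X'V0^{-1}.
.lmmEdf <- function(fit, Z, psi) {
  Zw <- forwardsolve(t(fit$R), Z)
  C <- crossprod(Zw, fit$A)                 # Z' V0^{-1} X
  XtViX <- crossprod(fit$A)
  psi * (sum(Zw^2) - sum(diag(C %*% solve(XtViX, t(C)))))
}

## Build a treatment-contrast fixed-effects design from a formula.
.buildDesign <- function(formula, data) {
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  tt <- attr(mf, "terms")
  old <- options(contrasts = c("contr.treatment", "contr.poly"))
  on.exit(options(old))
  X <- stats::model.matrix(tt, mf)
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design is rank deficient")
  list(y = as.numeric(y), X = X, terms = tt,
       assign = attr(X, "assign"),
       termLabels = attr(tt, "term.labels"))
}
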