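# Photographic calibration: chart-based colour-correction fitting and
# white-background exposure normalisation. Both operate in linear RGB.

#' Fit a 3x3 colour-correction matrix from chart patches
#'
#' Least-squares fit of the matrix `M` minimising
#' \eqn{\sum_i \| M m_i - r_i \|^2} over patch pairs, where `m_i` are
#' measured and `r_i` reference linear-RGB patch values. The fit is
#' unconstrained (no offset term); exposure is handled separately by
#' [exposureNormalize()], so the returned gain is 1.
#'
#' @param measured,reference n x 3 matrices of linear-RGB patch values
#'   (n >= 3, same patch order; the fit itself is invariant to a
#'   common permutation of the rows).
#' @return A [CorrectionModel-class] with the fitted matrix and the
#'   RMS patch residual.
#' @export
#' @examples
#' ref <- matrix(runif(72), ncol = 3)
#' A <- diag(3) + 0.05
#' fitCorrection(ref %*% t(A), ref)   # recovers solve(A)
fitCorrection <- function(measured, reference) {
  measured <- as.matrix(measured); reference <- as.matrix(reference)
  stopifnot(ncol(measured) == 3L, ncol(reference) == 3L,
            nrow(measured) == nrow(reference), nrow(measured) >= 3L)
  if (qr(measured)$rank < 3L)
    stop("patch set is rank deficient: need >= 3 non-coplanar patches")
  Mt <- solve(crossprod(measured), crossprod(measured, reference))
  res <- measured %*% Mt - reference
  new("CorrectionModel", matrix = t(Mt), gain = 1,
      fitResidual = sqrt(mean(res^2)))
}

#' Apply a correction model to linear-RGB values
#'
#' @param rgb Linear-RGB values (vector, n x 3 matrix or image array).
#' @param model A [CorrectionModel-class].
#' @return Corrected values, same shape.
#' @export
applyCorrection <- function(rgb, model) {
  z <- .as_nx3(rgb)
  z$restore(model@gain * (z$m %*% t(model@matrix)))
}

#' Normalise exposure against a white reference region
#'
#' Flash output varies image to image; the white background the fish
#' lies on provides a per-image exposure anchor. Intensity is taken as
#' the mean of the linearised green channel over the white region
#' (green approximates luminance); the image is rescaled so that this
#' mean equals `referenceWhite`.
#'
#' @param imageLinear H x W x 3 linear-RGB array.
#' @param whiteRegion Integer (x, y, width, height), 0-based top-left,
#'   inside the image.
#' @param referenceWhite Target linear green value for the region.
#' @return List with `image` (rescaled), `gain`, and `saturated`
#'   (TRUE when the region mean was >= 0.99 before scaling, in which
#'   case the gain is unreliable).
#' @export
exposureNormalize <- function(imageLinear, whiteRegion, referenceWhite = 1) {
  stopifnot(length(dim(imageLinear)) == 3L, dim(imageLinear)[3] == 3L,
            length(whiteRegion) == 4L, referenceWhite > 0)
  x <- whiteRegion[1]; y <- whiteRegion[2]
  w <- whiteRegion[3]; h <- whiteRegion[4]
  d <- dim(imageLinear)
  if (x < 0 || y < 0 || w <= 0 || h <= 0 || x + w > d[2] || y + h > d[1])
    stop("white region out of image bounds")
  g <- mean(imageLinear[(y + 1):(y + h), (x + 1):(x + w), 2])
  saturated <- g >= 0.99
  if (saturated)
    warning("white region appears saturated (mean >= 0.99); gain unreliable")
  gain <- referenceWhite / g
  list(image = imageLinear * gain, gain = gain, saturated = saturated)
}
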