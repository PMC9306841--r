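# Colour-space mathematics: sRGB transfer, linear RGB <-> XYZ (D65),
# XYZ <-> CIELAB. All functions are vectorised and accept either plain
# numeric vectors, n x 3 matrices, or H x W x 3 image arrays.

# Published sRGB/D65 primaries (IEC 61966-2-1), scaled so that
# linear RGB (1,1,1) maps to the D65 white point with Y = 100.
.RGB2XYZ <- 100 * matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.XYZ2RGB <- solve(.RGB2XYZ)

#' D65 reference white point
#'
#' Tristimulus values of the D65 illuminant on the \eqn{Y = 100} scale,
#' i.e. the XYZ image of linear RGB (1, 1, 1) under the sRGB primaries.
#' Used as the default white point for all CIELAB conversions.
#'
#' @return Named numeric vector with components `X`, `Y`, `Z`.
#' @export
#' @examples
#' whitePointD65()
whitePointD65 <- function() {
  w <- as.vector(.RGB2XYZ %*% c(1, 1, 1))
  names(w) <- c("X", "Y", "Z")
  w
}

#' sRGB transfer function (decode and encode)
#'
#' `srgbDecode()` maps gamma-encoded sRGB values in \[0, 1\] to linear
#' light; `srgbEncode()` is its exact inverse. Inputs are clipped to
#' \[0, 1\] before the piecewise transfer is applied, so out-of-range
#' values never propagate.
#'
#' @param x Numeric vector, matrix or array of encoded (resp. linear)
#'   values; any shape is preserved.
#' @return Object of the same shape with the transfer applied.
#' @export
#' @examples
#' srgbDecode(c(0, 0.5, 1))
#' v <- seq(0, 1, length.out = 11)
#' max(abs(srgbEncode(srgbDecode(v)) - v))
srgbDecode <- function(x) {
  v <- pmin(pmax(x, 0), 1)
  out <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  attributes(out) <- attributes(x)
  out
}

#' @rdname srgbDecode
#' @export
srgbEncode <- function(x) {
  v <- pmin(pmax(x, 0), 1)
  out <- ifelse(v <= 0.04045 / 12.92, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
  attributes(out) <- attributes(x)
  out
}

## Coerce vectors / matrices / image arrays to an n x 3 matrix,
## remembering how to restore the original shape.
.as_nx3 <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[3] == 3L)
    d <- dim(x)
    list(m = matrix(x, ncol = 3L), restore = function(m) array(m, dim = d))
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    list(m = x, restore = identity)
  } else {
    stopifnot(length(x) == 3L)
    list(m = matrix(as.numeric(x), nrow = 1L),
         restore = function(m) as.vector(m))
  }
}

#' Linear RGB to XYZ and back (sRGB primaries, D65)
#'
#' Applies the published sRGB/D65 3x3 matrix, on the \eqn{Y = 100}
#' scale so that linear RGB (1, 1, 1) maps exactly to [whitePointD65()].
#'
#' @param rgb,xyz Numeric length-3 vector, n x 3 matrix, or
#'   H x W x 3 array.
#' @return Same shape as the input, converted.
#' @export
#' @examples
#' linearRgbToXyz(c(1, 1, 1))
linearRgbToXyz <- function(rgb) {
  z <- .as_nx3(rgb)
  z$restore(z$m %*% t(.RGB2XYZ))
}

#' @rdname linearRgbToXyz
#' @export
xyzToLinearRgb <- function(xyz) {
  z <- .as_nx3(xyz)
  z$restore(z$m %*% t(.XYZ2RGB))
}

# CIE f(t) and inverse, with the standard linear segment below
# t = (6/29)^3 so the conversion stays smooth near black.
.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}
.lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' XYZ to CIELAB and back
#'
#' Standard CIE 1976 L*a*b* formulas relative to a white point
#' (default D65, \eqn{Y_n = 100}).
#'
#' @param xyz,lab Numeric length-3 vector, n x 3 matrix or H x W x 3
#'   array of tristimulus (resp. L*, a*, b*) values.
#' @param white Reference white point, strictly positive length-3
#'   vector (default [whitePointD65()]).
#' @return Same shape as the input, converted.
#' @export
#' @examples
#' xyzToLab(whitePointD65())           # L* = 100, neutral
#' labToXyz(c(50, 0, 0))[2]            # Y of mid grey
xyzToLab <- function(xyz, white = whitePointD65()) {
  if (any(white <= 0)) stop("white point components must be strictly positive")
  z <- .as_nx3(xyz)
  fx <- .lab_f(z$m[, 1] / white[1])
  fy <- .lab_f(z$m[, 2] / white[2])
  fz <- .lab_f(z$m[, 3] / white[3])
  z$restore(cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz)))
}

#' @rdname xyzToLab
#' @export
labToXyz <- function(lab, white = whitePointD65()) {
  if (any(white <= 0)) stop("white point components must be strictly positive")
  z <- .as_nx3(lab)
  fy <- (z$m[, 1] + 16) / 116
  fx <- fy + z$m[, 2] / 500
  fz <- fy - z$m[, 3] / 200
  z$restore(cbind(white[1] * .lab_finv(fx),
                  white[2] * .lab_finv(fy),
                  white[3] * .lab_finv(fz)))
}

#' Convenience compositions between CIELAB and linear RGB
#'
#' @param lab,rgb Colour values in the respective space (vector,
#'   matrix or image array).
#' @param white Reference white point.
#' @return Converted values, same shape.
#' @export
labToLinearRgb <- function(lab, white = whitePointD65()) {
  xyzToLinearRgb(labToXyz(lab, white))
}

#' @rdname labToLinearRgb
#' @export
linearRgbToLab <- function(rgb, white = whitePointD65()) {
  xyzToLab(linearRgbToXyz(rgb), white)
}

#' CIELAB colour difference
#'
#' Euclidean distance in CIELAB (Delta E*ab, the CIE 1976 colour
#' difference).
#'
#' @param lab1,lab2 Length-3 Lab vectors or n x 3 matrices (recycled
#'   row-wise).
#' @return Numeric vector of colour differences.
#' @export
#' @examples
#' deltaE(c(50, 0, 0), c(53, 4, 0))
deltaE <- function(lab1, lab2) {
  m1 <- .as_nx3(lab1)$m
  m2 <- .as_nx3(lab2)$m
  if (nrow(m1) == 1L && nrow(m2) > 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
  if (nrow(m2) == 1L && nrow(m1) > 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
  sqrt(rowSums((m1 - m2)^2))
}
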