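# Dorsal ROI extraction, green-plane stripe masking and masked mean
# CIELAB measurement.

#' Rectangular ROI specification
#'
#' @param x,y Top-left corner, 0-based pixel coordinates.
#' @param width,height ROI size in pixels; the default 530 x 53 is the
#'   standard dorsal measurement strip (landscape: width >= height).
#' @return List of class `ROISpec`.
#' @export
roiSpec <- function(x, y, width = 530L, height = 53L) {
  stopifnot(width >= height, width > 0, height > 0, x >= 0, y >= 0)
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height)),
            class = "ROISpec")
}

#' Extract the dorsal thumbnail
#'
#' Exact pixel crop (no resampling) of the ROI from an encoded image.
#'
#' @param image H x W x 3 image array.
#' @param roi An `ROISpec` (see [roiSpec()]).
#' @return height x width x 3 thumbnail array.
#' @export
#' @examples
#' img <- renderFishImage(sceneSpec(), cameraModel())$image
#' dim(extractThumbnail(img, roiSpec(40, 70)))
extractThumbnail <- function(image, roi) {
  d <- dim(image)
  if (roi$x < 0 || roi$y < 0 || roi$x + roi$width > d[2] ||
      roi$y + roi$height > d[1])
    stop("ROI out of image bounds")
  image[(roi$y + 1):(roi$y + roi$height),
        (roi$x + 1):(roi$x + roi$width), , drop = FALSE]
}

#' Otsu threshold of a numeric channel
#'
#' Histogram-based threshold maximising between-class variance over
#' 256 bins in \[0, 1\]; the returned value is the upper edge of the
#' chosen bin, so "strictly above threshold" selects the bright class.
#'
#' @param x Numeric values in \[0, 1\].
#' @param levels Number of histogram bins.
#' @return Scalar threshold.
#' @export
otsuThreshold <- function(x, levels = 256L) {
  v <- pmin(pmax(as.vector(x), 0), 1)
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = levels)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[levels]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1L]
}

#' Stripe mask from the green colour plane
#'
#' Applies an automatic (Otsu) threshold to the green channel of the
#' thumbnail and keeps pixels strictly above it: the light
#' inter-stripe "coloured section" of the skin, excluding the dark
#' stripes. A constant thumbnail cannot be thresholded; the whole
#' thumbnail is then kept with a warning.
#'
#' @param thumbnail h x w x 3 encoded thumbnail.
#' @param threshold Either `"otsu"` (default) or a fixed numeric
#'   green-plane threshold.
#' @return List with `mask` (h x w logical), `threshold` and
#'   `maskFraction`.
#' @export
#' @examples
#' r <- renderFishImage(sceneSpec(), cameraModel())
#' th <- extractThumbnail(r$image, roiSpec(40, 70))
#' stripeMask(th)$maskFraction
stripeMask <- function(thumbnail, threshold = "otsu") {
  g <- thumbnail[, , 2]
  if (identical(threshold, "otsu")) {
    if (diff(range(g)) == 0) {
      warning("constant thumbnail: keeping all pixels")
      return(list(mask = matrix(TRUE, nrow(g), ncol(g)),
                  threshold = min(g) - 1, maskFraction = 1))
    }
    thr <- otsuThreshold(g)
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- g > thr
  list(mask = mask, threshold = thr, maskFraction = mean(mask))
}

#' Measure masked mean CIELAB of a thumbnail
#'
#' Each kept pixel is sRGB-decoded, multiplied by the exposure gain,
#' corrected by the 3x3 matrix, converted to XYZ then CIELAB; the
#' arithmetic mean of L*, a*, b* over kept pixels is returned
#' (per-pixel conversion before averaging, so the nonlinear transform
#' is applied in the right order).
#'
#' @param thumbnail h x w x 3 encoded thumbnail.
#' @param mask h x w logical mask (same shape); pixels where TRUE are
#'   used. Fewer than 50 kept pixels flags the result unreliable.
#' @param correction A [CorrectionModel-class] (identity by default).
#' @param gain Extra exposure gain applied before the matrix (e.g.
#'   from [exposureNormalize()] of the parent image).
#' @param threshold Green-plane threshold that produced `mask`
#'   (recorded for audit; see [stripeMask()]).
#' @return A [ColourMeasurement-class].
#' @export
measureColour <- function(thumbnail, mask = NULL,
                          correction = new("CorrectionModel"), gain = 1,
                          threshold = NA_real_) {
  d <- dim(thumbnail)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(all(dim(mask) == d[1:2]))
  keep <- which(as.vector(mask))
  px <- matrix(thumbnail, ncol = 3L)[keep, , drop = FALSE]
  lin <- srgbDecode(px) * gain
  corrected <- applyCorrection(lin, correction)
  lab <- linearRgbToLab(corrected)
  meanLab <- colMeans(lab)
  names(meanLab) <- c("L", "a", "b")
  new("ColourMeasurement", meanLab = meanLab,
      nPixelsUsed = length(keep),
      maskFraction = max(length(keep) / (d[1] * d[2]), .Machine$double.eps),
      thresholdValue = threshold, reliable = length(keep) >= 50L)
}
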