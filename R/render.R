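# Renderers: striped dorsal images and the 24-patch calibration chart,
# both imaged through a CameraModel (gain * M in linear RGB, sRGB
# encoding, 8-bit quantization).

## Camera forward model for an n x 3 matrix of true linear-RGB values.
.cameraApply <- function(rgbLinear, camera) {
  out <- camera@exposureGain * camera@headroom *
    (rgbLinear %*% t(camera@camMatrix))
  out <- pmin(pmax(out, 0), 1)
  enc <- srgbEncode(out)
  if (camera@quantization > 0L) {
    levels <- 2^camera@quantization - 1
    enc <- round(enc * levels) / levels
  }
  enc
}

#' Render a synthetic striped dorsal image
#'
#' Paints a rectangle of alternating dark and light stripes (the
#' dorsal pattern) on a white background, then images the scene
#' through the camera model: linear RGB is scaled by the flash gain,
#' distorted by the 3x3 camera matrix, sRGB-encoded and quantized.
#' The exact binary mask of light inter-stripe pixels is returned for
#' oracle comparison with the measurement pipeline's own mask.
#'
#' Stripes run along the dorsal axis: rows of the fish rectangle
#' cycle with period `stripePeriod`, the first `stripeDuty` fraction
#' of each period being dark stripe.
#'
#' @param scene A [SceneSpec-class].
#' @param camera A [CameraModel-class].
#' @return List with `image` (H x W x 3 encoded array in \[0, 1\]),
#'   `mask` (H x W logical, TRUE for light inter-stripe fish pixels),
#'   `scene` and `camera`.
#' @export
#' @examples
#' r <- renderFishImage(sceneSpec(), cameraModel())
#' dim(r$image); mean(r$mask)
renderFishImage <- function(scene, camera) {
  validObject(scene); validObject(camera)
  H <- scene@imageSize[1]; W <- scene@imageSize[2]
  r <- scene@fishRegion                      # x, y, w, h (0-based)
  cols <- rbind(light = labToLinearRgb(scene@lightLab),
                dark = labToLinearRgb(scene@darkLab),
                background = labToLinearRgb(scene@backgroundLab))
  if (any(cols < -1e-9) || any(cols > 1 + 1e-9))
    stop("scene colour out of the sRGB gamut")
  cols <- pmin(pmax(cols, 0), 1)

  idx <- matrix(3L, H, W)                    # background everywhere
  rows <- (r[2] + 1):(r[2] + r[4])
  colsIdx <- (r[1] + 1):(r[1] + r[3])
  phase <- ((rows - rows[1]) %% scene@stripePeriod) / scene@stripePeriod
  rowType <- ifelse(phase < scene@stripeDuty, 2L, 1L)   # dark first
  idx[rows, colsIdx] <- matrix(rowType, nrow = length(rows),
                               ncol = length(colsIdx))
  mask <- idx == 1L

  enc <- .cameraApply(cols, camera)          # 3 x 3: one row per colour
  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3) img[, , k] <- matrix(enc[as.vector(idx), k], H, W)
  list(image = img, mask = mask, scene = scene, camera = camera)
}

#' Reference patch lattice for the synthetic calibration chart
#'
#' A deterministic 24-patch set (6 x 4 layout) spanning the linear-RGB
#' gamut: a six-step grey ramp, six saturated primaries/secondaries,
#' six darker chromatic patches and six natural mid-tones. Values are
#' linear RGB in \[0, 1\].
#'
#' @return 24 x 3 numeric matrix of reference linear-RGB values.
#' @export
chartReference <- function() {
  greys <- c(0.02, 0.09, 0.20, 0.36, 0.59, 0.90)
  m <- rbind(
    cbind(greys, greys, greys),
    matrix(c(0.70, 0.06, 0.06,  0.06, 0.70, 0.06,  0.06, 0.06, 0.70,
             0.75, 0.60, 0.05,  0.70, 0.10, 0.60,  0.05, 0.60, 0.70),
           ncol = 3, byrow = TRUE),
    matrix(c(0.35, 0.03, 0.03,  0.03, 0.35, 0.03,  0.03, 0.03, 0.35,
             0.40, 0.30, 0.02,  0.35, 0.05, 0.30,  0.02, 0.30, 0.35),
           ncol = 3, byrow = TRUE),
    matrix(c(0.45, 0.30, 0.20,  0.30, 0.45, 0.20,  0.20, 0.30, 0.45,
             0.50, 0.45, 0.30,  0.30, 0.20, 0.45,  0.45, 0.20, 0.30),
           ncol = 3, byrow = TRUE))
  dimnames(m) <- list(NULL, c("R", "G", "B"))
  m
}

#' Render the synthetic 24-patch calibration chart
#'
#' Lays the [chartReference()] patches out on a 6 x 4 grid and images
#' them through the camera model exactly as [renderFishImage()] does.
#' Patch pixel locations are returned so the measurement side can
#' sample each patch without any detection step.
#'
#' @param camera A [CameraModel-class].
#' @param patchSize Patch side length in pixels.
#' @param gap Gap between patches (and margin), pixels.
#' @return List with `image`, and `patches`: a data frame of patch
#'   index, grid position, pixel rectangle (x, y, w, h; 0-based) and
#'   reference linear-RGB values.
#' @export
#' @examples
#' ch <- renderChartImage(cameraModel())
#' nrow(ch$patches)
renderChartImage <- function(camera, patchSize = 32L, gap = 8L) {
  validObject(camera)
  ref <- chartReference()
  ncols <- 6L; nrows <- 4L
  W <- ncols * patchSize + (ncols + 1L) * gap
  H <- nrows * patchSize + (nrows + 1L) * gap
  enc <- .cameraApply(ref, camera)
  bg <- .cameraApply(matrix(c(0.2, 0.2, 0.2), 1), camera)
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  patches <- data.frame(patch = seq_len(24L),
                        row = rep(seq_len(nrows), each = ncols),
                        col = rep(seq_len(ncols), times = nrows))
  patches$x <- gap + (patches$col - 1L) * (patchSize + gap)
  patches$y <- gap + (patches$row - 1L) * (patchSize + gap)
  patches$w <- patchSize; patches$h <- patchSize
  for (i in seq_len(24L)) {
    rows <- (patches$y[i] + 1):(patches$y[i] + patchSize)
    cols <- (patches$x[i] + 1):(patches$x[i] + patchSize)
    for (k in 1:3) img[rows, cols, k] <- enc[i, k]
  }
  patches$R <- ref[, 1]; patches$G <- ref[, 2]; patches$B <- ref[, 3]
  list(image = img, patches = patches, camera = camera)
}

#' Measure mean linear-RGB values of chart patches
#'
#' Decodes the chart image to linear RGB and averages each patch over
#' its known pixel rectangle (inset by 2 px to stay clear of edges).
#'
#' @param image Encoded H x W x 3 chart image.
#' @param patches Patch table as returned by [renderChartImage()].
#' @return 24 x 3 matrix of measured linear-RGB patch values.
#' @export
measureChartPatches <- function(image, patches) {
  lin <- srgbDecode(image)
  out <- matrix(NA_real_, nrow(patches), 3)
  for (i in seq_len(nrow(patches))) {
    rows <- (patches$y[i] + 3):(patches$y[i] + patches$h[i] - 2)
    cols <- (patches$x[i] + 3):(patches$x[i] + patches$w[i] - 2)
    for (k in 1:3) out[i, k] <- mean(lin[rows, cols, k])
  }
  colnames(out) <- c("R", "G", "B")
  out
}
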