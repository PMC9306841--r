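# End-to-end orchestration: write a complete synthetic study to disk,
# measure it back through the calibrated imaging pipeline, and run
# the full statistical analysis to a JSON report. Every artifact
# records the seed; identical inputs give identical outputs.

#' Simulate a complete synthetic study to disk
#'
#' Writes a calibration chart and per-trial striped fish images
#' rendered through one seeded distorting camera (shared matrix,
#' per-image flash gain), together with the metadata table, the
#' ground truth (YAML), and simulated trajectory, physiology cohort,
#' post-mortem and mortality tables.
#'
#' Each imaged fish's ground-truth light colour follows its
#' scenario's b* drift at the sampled exposure time; L* and a* stay
#' at the control values.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param scenarios Named list of [TrialScenario-class] (default
#'   [defaultScenarios()]).
#' @param nImagesPerTrial Fish photographed per trial.
#' @param nPerScenario Fish per scenario in the trajectory table.
#' @return Invisibly, the metadata data.frame.
#' @export
simulateStudy <- function(outDir, seed = 1L,
                          scenarios = defaultScenarios(),
                          nImagesPerTrial = 3L, nPerScenario = 40L) {
  imgDir <- file.path(outDir, "images")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  camMatrix <- randomCameraModel(seed)@camMatrix

  chartCam <- .withSeed(seed + 1000L,
    cameraModel(camMatrix, stats::runif(1, 0.7, 1.3), headroom = 0.75,
                seed = seed))
  chart <- renderChartImage(chartCam)
  png::writePNG(chart$image, file.path(outDir, "chart.png"))
  utils::write.csv(chart$patches, file.path(outDir, "chart_patches.csv"),
                   row.names = FALSE)

  meta <- list(); truth <- list(); k <- 0L
  for (sc in scenarios) {
    times <- .withSeed(seed + 2000L + k,
      stats::runif(nImagesPerTrial, 0, min(sc@duration, 15)))
    for (i in seq_len(nImagesPerTrial)) {
      k <- k + 1L
      bTrue <- sc@b0 + sc@rate * times[i]
      scene <- sceneSpec(lightLab = c(47.67, -9.27, bTrue), seed = seed + k)
      cam <- .withSeed(seed + 3000L + k,
        cameraModel(camMatrix, stats::runif(1, 0.7, 1.3), headroom = 0.75,
                    seed = seed + k))
      r <- renderFishImage(scene, cam)
      id <- sprintf("IMG%03d", k)
      png::writePNG(r$image, file.path(imgDir, paste0(id, ".png")))
      png::writePNG(r$mask * 1, file.path(imgDir, paste0(id, "_mask.png")))
      meta[[k]] <- data.frame(
        fish_id = id, trial = sc@name, monitoring_period = "Treatment",
        exposure_min = times[i], vitality_assessed = TRUE,
        lactate = NA_real_, glucose = NA_real_, cortisol = NA_real_,
        weight_g = 719, length_cm = 38,
        image_path = file.path("images", paste0(id, ".png")),
        roi_x = scene@fishRegion[1] + 5L, roi_y = scene@fishRegion[2] + 10L,
        white_x = 10L, white_y = 5L, white_w = 200L, white_h = 30L)
      truth[[id]] <- list(L = 47.67, a = -9.27, b = bTrue,
                          gain = cam@exposureGain)
    }
  }
  meta <- do.call(rbind, meta)
  utils::write.csv(meta, file.path(outDir, "metadata.csv"), row.names = FALSE)

  utils::write.csv(simulateTrajectories(scenarios, nPerScenario,
                                        samplingWindow = 15,
                                        seed = seed + 10L),
                   file.path(outDir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(simulateCohort(cohortSpec(seed = seed + 20L)),
                   file.path(outDir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(simulatePostmortem(15L, drop = 5, seed = seed + 30L),
                   file.path(outDir, "postmortem.csv"), row.names = FALSE)
  mort <- data.frame(trial = c("Control", "Low", "Moderate", "High"),
                     n_monitored = c(116L, 231L, 131L, 150L),
                     true_p = c(0, 0, 0.03, 0.31))
  mort$deaths <- mapply(simulateMortality, mort$n_monitored, mort$true_p,
                        seed = seed + 40L + seq_len(nrow(mort)))
  utils::write.csv(mort, file.path(outDir, "mortality.csv"), row.names = FALSE)

  yaml::write_yaml(list(
    seed = as.integer(seed),
    processing_order = "decode, exposure-normalize, matrix-correct, convert",
    camera_matrix = lapply(seq_len(3), function(i) as.numeric(camMatrix[i, ])),
    background_lab = c(95, 0, 2),
    scenarios = lapply(scenarios, function(s) list(
      name = s@name, density = s@density, duration = s@duration,
      b0 = s@b0, rate = s@rate, sigma = s@sigma)),
    truth = truth), file.path(outDir, "ground_truth.yaml"))
  invisible(meta)
}

#' Measure a simulated (or real) study directory
#'
#' Calibrates from the chart (exposure-normalised against its
#' brightest neutral patch, then 3x3 matrix fit), then for each image
#' in the metadata table: exposure-normalise against the white
#' background region, crop the 530 x 53 dorsal ROI, mask the dark
#' stripes on the green plane and record the masked mean CIELAB.
#' Per-row failures are recorded and skipped, not fatal.
#'
#' @param dir Study directory written by [simulateStudy()] (or laid
#'   out the same way).
#' @param threshold `"otsu"` or a fixed numeric green-plane threshold.
#' @return The measurements data.frame (also written to
#'   `measurements.csv` in `dir`).
#' @export
measureStudy <- function(dir, threshold = "otsu") {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"))
  patches <- utils::read.csv(file.path(dir, "chart_patches.csv"))
  chartImg <- png::readPNG(file.path(dir, "chart.png"))

  measured <- measureChartPatches(chartImg, patches)
  ref <- as.matrix(patches[, c("R", "G", "B")])
  whiteIdx <- which.max(ref[, "G"] * (abs(ref[, "R"] - ref[, "G"]) < 1e-6))
  chartGain <- ref[whiteIdx, "G"] / measured[whiteIdx, "G"]
  correction <- fitCorrection(measured * chartGain, ref)

  refWhite <- labToLinearRgb(c(95, 0, 2))[2]   # background green, linear
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rows[[i]] <- tryCatch({
      img <- png::readPNG(file.path(dir, meta$image_path[i]))
      lin <- srgbDecode(img)
      en <- exposureNormalize(lin, c(meta$white_x[i], meta$white_y[i],
                                     meta$white_w[i], meta$white_h[i]),
                              referenceWhite = refWhite)
      roi <- roiSpec(meta$roi_x[i], meta$roi_y[i])
      thumb <- extractThumbnail(img, roi)
      m <- stripeMask(thumb, threshold)
      cm <- measureColour(thumb, m$mask, correction, gain = en$gain,
                          threshold = m$threshold)
      lab <- labMean(cm)
      data.frame(fish_id = meta$fish_id[i], L = lab[1], a = lab[2],
                 b = lab[3], n_pixels_used = nPixelsUsed(cm),
                 mask_fraction = m$maskFraction,
                 threshold_value = m$threshold, gain = en$gain,
                 error = NA_character_)
    }, error = function(e)
      data.frame(fish_id = meta$fish_id[i], L = NA_real_, a = NA_real_,
                 b = NA_real_, n_pixels_used = NA_integer_,
                 mask_fraction = NA_real_, threshold_value = NA_real_,
                 gain = NA_real_, error = conditionMessage(e)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(dir, "measurements.csv"), row.names = FALSE)
  out
}

#' Analyse a measured study directory
#'
#' Fits the crowding trajectory GLS (trial x exposure with per-trial
#' variance weights), the lactate spline mixed model, the post-mortem
#' LME (storage term screened at 0.05, time effect tested by LRT) and
#' Wilson mortality intervals; writes `report.json` and diagnostic
#' plots to `dir`.
#'
#' @param dir Study directory containing the tables written by
#'   [simulateStudy()] and [measureStudy()].
#' @return The report as a list (invisibly; also in `report.json`).
#' @export
analyseStudy <- function(dir) {
  report <- list()

  traj <- utils::read.csv(file.path(dir, "trajectories.csv"))
  traj$trial <- stats::relevel(factor(traj$trial), ref = "Control")
  glsFit <- tryCatch(
    fitGls(b ~ trial * exposure_min, traj, varIdent = "trial"),
    error = function(e) NULL)
  if (!is.null(glsFit)) {
    cf <- coef(glsFit)
    slopes <- sapply(setdiff(levels(traj$trial), "Control"), function(tr) {
      inter <- paste0("trial", tr, ":exposure_min")
      unname(cf["exposure_min"] + cf[inter])
    })
    ft <- waldF(glsFit, "trial:exposure_min")
    report$trajectory <- list(
      slopes_b_per_min = as.list(slopes),
      control_slope = unname(cf["exposure_min"]),
      sd_ratios = as.list(varParams(glsFit)$estimates),
      interaction_F = testStatistic(ft), interaction_df = ft@df,
      interaction_p = pValue(ft), converged = glsFit@converged)
  } else report$trajectory <- list(error = "GLS did not fit")

  cohort <- utils::read.csv(file.path(dir, "cohort.csv"))
  spFit <- tryCatch(
    fitSplineMixed(cohort, "b", "lactate",
                   random = c("trial", "monitoring_period"),
                   varPower = TRUE),
    error = function(e) NULL)
  if (!is.null(spFit)) {
    gr <- stats::quantile(cohort$lactate, c(0.05, 0.95))
    sm <- predictSmooth(spFit, seq(gr[1], gr[2], length.out = 50))
    report$physiology <- list(
      lactate_slope_sign = unname(sign(sm$fit[nrow(sm)] - sm$fit[1])),
      smooth_edf = varParams(spFit)$edf,
      basis_dim = varParams(spFit)$basisDim,
      var_power = as.list(varParams(spFit)$estimates),
      monotone_decreasing = all(diff(sm$fit) < 0))
  } else report$physiology <- list(error = "spline model did not fit")

  pm <- utils::read.csv(file.path(dir, "postmortem.csv"))
  pm$time_h <- factor(pm$time_h)
  full <- tryCatch(fitLme(b ~ time_h + storage, pm, random = "fish_id"),
                   error = function(e) NULL)
  if (!is.null(full)) {
    screen <- dropIfNonsignificant(full, "storage")
    chosen <- screen$fit
    null <- fitLme(stats::update.formula(chosen@modelInfo$refit$formula,
                                         . ~ . - time_h),
                   pm, random = "fish_id")
    timeTest <- lrt(chosen, null)
    cf <- coef(chosen)
    report$postmortem <- list(
      storage_dropped = screen$dropped,
      storage_p = if (is.null(screen$test)) NA else pValue(screen$test),
      time_LRT = testStatistic(timeTest), time_df = timeTest@df,
      time_p = pValue(timeTest),
      contrast_1h_vs_0h = unname(cf[grep("time_h1", names(cf))]))
  } else report$postmortem <- list(error = "post-mortem LME did not fit")

  mort <- utils::read.csv(file.path(dir, "mortality.csv"))
  report$mortality <- lapply(seq_len(nrow(mort)), function(i) {
    ci <- wilsonInterval(mort$deaths[i], mort$n_monitored[i])
    list(trial = mort$trial[i], deaths = mort$deaths[i],
         n = mort$n_monitored[i],
         proportion = mort$deaths[i] / mort$n_monitored[i],
         lower = unname(ci[1]), upper = unname(ci[2]))
  })

  if (file.exists(file.path(dir, "measurements.csv"))) {
    mm <- utils::read.csv(file.path(dir, "measurements.csv"))
    meta <- utils::read.csv(file.path(dir, "metadata.csv"))
    mm <- merge(mm, meta[, c("fish_id", "trial")], by = "fish_id")
    ctrl <- mm[mm$trial == "Control" & !is.na(mm$b), ]
    if (nrow(ctrl))
      report$imaging <- list(control_mean_L = mean(ctrl$L),
                             control_mean_a = mean(ctrl$a),
                             control_mean_b = mean(ctrl$b),
                             n_images = sum(!is.na(mm$b)))
  }

  grDevices::png(file.path(dir, "diagnostics.png"), 900, 600)
  old <- graphics::par(mfrow = c(1, 2)); on.exit({graphics::par(old)
    grDevices::dev.off()})
  graphics::plot(traj$exposure_min, traj$b, col = traj$trial,
                 xlab = "exposure (min)", ylab = "b*",
                 main = "b* trajectories by trial")
  if (!is.null(spFit)) {
    graphics::plot(cohort$lactate, cohort$b, pch = 3, col = "grey40",
                   xlab = "plasma lactate", ylab = "b*",
                   main = "lactate smooth")
    sm <- predictSmooth(spFit, seq(min(cohort$lactate), max(cohort$lactate),
                                   length.out = 100))
    graphics::lines(sm$x, sm$fit, lwd = 2, col = "blue")
    graphics::lines(sm$x, sm$fit + 2 * sm$se, lty = 2, col = "blue")
    graphics::lines(sm$x, sm$fit - 2 * sm$se, lty = 2, col = "blue")
  }

  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
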