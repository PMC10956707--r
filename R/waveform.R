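## ETL / rolling-shutter synchronization model.

#' Rolling-shutter exposure schedule
#'
#' Standard rolling-shutter kinematics: row r (0-based from the detector
#' top) starts exposing at \code{r * lineTime} for a top-down shutter, or at
#' \code{(nRows - 1 - r) * lineTime} bottom-up. The frame is feasible only
#' when the full readout plus exposure fits in one frame period.
#'
#' @param camera a \code{\link{CameraSpec}}.
#' @param frameRate frame rate (Hz).
#' @param exposureTime per-row exposure duration (s).
#' @param direction \code{"top-down"} (default) or \code{"bottom-up"}.
#' @return A \code{\link[=ShutterSchedule-class]{ShutterSchedule}}.
#' @examples
#' cam <- CameraSpec(2048, 1024, 6.5, 9.74e-6)
#' sch <- rollingShutterSchedule(cam, frameRate = 50, exposureTime = 2e-3)
#' max(sch@rowStartTimes) + sch@exposureTime   # 11.97 ms, fits in 20 ms
#' @export
rollingShutterSchedule <- function(camera, frameRate, exposureTime,
                                   direction = c("top-down", "bottom-up")) {
  direction <- match.arg(direction)
  if (exposureTime <= 0) stop("'exposureTime' must be > 0")
  period <- 1 / frameRate
  readout <- camera@nRows * camera@lineTime
  if (readout + exposureTime > period) {
    maxRate <- 1 / (readout + exposureTime)
    stop(sprintf(paste0(
      "frame rate infeasible: %d rows x %.3g us line time + %.3g ms exposure ",
      "needs %.4g ms > %.4g ms frame period; maximum feasible frame rate is ",
      "%.4g Hz"),
      camera@nRows, 1e6 * camera@lineTime, 1e3 * exposureTime,
      1e3 * (readout + exposureTime), 1e3 * period, maxRate))
  }
  r <- seq_len(camera@nRows) - 1L
  starts <- if (direction == "top-down") r * camera@lineTime
            else (camera@nRows - 1L - r) * camera@lineTime
  new("ShutterSchedule", rowStartTimes = starts, exposureTime = exposureTime,
      direction = direction, frameRate = frameRate,
      lineTime = camera@lineTime, bidirectional = camera@bidirectionalShutter)
}

#' Plan the ETL drive waveform for a shutter schedule
#'
#' Builds the optical-power trace synchronized with the rolling shutter.
#' Within the active window the power is affine in time, so each row's
#' mid-exposure power maps linearly (via \code{\link{etlPowerToDefocus}}) to
#' that row's in-focus depth. Sawtooth mode appends a dead flyback interval
#' during which the lens resets, costing duty cycle
#' (\code{duty = 1 - flybackTime * frameRate}); triangular mode alternates
#' the ramp sign every frame with no flyback (\code{duty = 1}) but requires
#' a camera able to alternate its shutter direction.
#'
#' @param schedule a \code{\link[=ShutterSchedule-class]{ShutterSchedule}}.
#' @param etl an \code{\link{ETLSpec}}.
#' @param powerSpan full peak-to-peak power excursion (dioptre) across the
#'   active window; must not exceed \code{2 * maxPower}.
#' @param mode \code{"sawtooth"} (default) or \code{"triangular"}.
#' @param flybackTime sawtooth reset interval (s); defaults to the ETL spec.
#' @param defocusGain micrometre of focus shift per dioptre
#'   (\code{mTel^2 * fObj^2}); optional, carried into
#'   \code{\link{rowFocusMap}}.
#' @param nSamples samples in the returned power trace (per frame period).
#' @return A \code{\link[=WaveformPlan-class]{WaveformPlan}}.
#' @examples
#' cam <- CameraSpec(2048, 1024, 6.5, 9.74e-6)
#' sch <- rollingShutterSchedule(cam, 50, 2e-3)
#' plan <- makeWaveform(sch, ETLSpec(16, flybackTime = 8e-3), powerSpan = 2)
#' plan@dutyCycle   # 0.60
#' @export
makeWaveform <- function(schedule, etl, powerSpan,
                         mode = c("sawtooth", "triangular"),
                         flybackTime = NULL, defocusGain = NA_real_,
                         nSamples = 512L) {
  mode <- match.arg(mode)
  if (powerSpan < 0 || powerSpan > 2 * etl@maxPower)
    stop(sprintf("'powerSpan' (%g D) exceeds the ETL range of +/-%g D",
                 powerSpan, etl@maxPower))
  period <- 1 / schedule@frameRate
  rowMid <- schedule@rowStartTimes + schedule@exposureTime / 2
  if (mode == "triangular") {
    if (!schedule@bidirectional)
      stop(paste("triangular drive requires a camera with alternating",
                 "(bidirectional) rolling shutter direction"))
    flybackTime <- 0
    duty <- 1
    active <- period
    # two frame periods: up ramp then mirrored down ramp
    t <- seq(0, 2 * period, length.out = 2L * nSamples)
    tf <- t %% (2 * period)
    up <- tf <= period
    p <- ifelse(up, -powerSpan / 2 + powerSpan * tf / period,
                powerSpan / 2 - powerSpan * (tf - period) / period)
  } else {
    if (is.null(flybackTime)) flybackTime <- etl@flybackTime
    if (flybackTime >= period)
      stop(sprintf("flyback time (%g ms) must be shorter than the frame period (%g ms)",
                   1e3 * flybackTime, 1e3 * period))
    duty <- 1 - flybackTime * schedule@frameRate
    active <- period - flybackTime
    if (max(rowMid) > active)
      stop(sprintf(paste0(
        "last row mid-exposure (%.4g ms) falls inside the flyback interval ",
        "(active window %.4g ms); lower the frame rate, exposure or flyback"),
        1e3 * max(rowMid), 1e3 * active))
    t <- seq(0, period, length.out = nSamples)
    p <- ifelse(t <= active, -powerSpan / 2 + powerSpan * t / active,
                powerSpan / 2 - powerSpan * (t - active) / flybackTime)
  }
  rowPower <- -powerSpan / 2 + powerSpan * rowMid / active
  new("WaveformPlan", frameRate = schedule@frameRate, mode = mode,
      time = t, power = p, flybackTime = flybackTime, dutyCycle = duty,
      rowPower = rowPower, rowMidTimes = rowMid,
      defocusGain = as.numeric(defocusGain))
}

#' Power span that synchronizes the focus ramp with the oblique plane
#'
#' Ideal synchronization requires the focus depth at each row's mid-exposure
#' to equal the depth of the oblique plane at that row (\code{r * pxAxial}).
#' Given the linear power ramp of \code{\link{makeWaveform}} this fixes the
#' full-trace power span to
#' \code{pxAxial * activeWindow / (lineTime * gain)}.
#'
#' @param geometry an \code{\link[=ObliqueGeometry-class]{ObliqueGeometry}}.
#' @param schedule the \code{\link[=ShutterSchedule-class]{ShutterSchedule}}.
#' @param defocusGain micrometre per dioptre (\code{mTel^2 * fObj^2}).
#' @param flybackTime the sawtooth flyback that will be used (s); 0 for
#'   triangular.
#' @return Power span in dioptre.
#' @export
matchedPowerSpan <- function(geometry, schedule, defocusGain, flybackTime = 0) {
  active <- 1 / schedule@frameRate - flybackTime
  geometry@pxAxial * active / (schedule@lineTime * defocusGain)
}

#' Per-row in-focus depth
#'
#' Maps each detector row to the axial depth in focus while that row is
#' exposed. When the plan carries a finite \code{defocusGain} the depth is
#' computed physically from the row's mid-exposure power (centred on the
#' middle of the axial field of view); otherwise the row powers are simply
#' rescaled onto the axial field of view (ideal synchronization). A zero
#' power span yields a constant depth: conventional widefield focus.
#'
#' @param plan a \code{\link[=WaveformPlan-class]{WaveformPlan}}.
#' @param geometry an \code{\link[=ObliqueGeometry-class]{ObliqueGeometry}};
#'   row counts must agree with the plan.
#' @return Numeric vector, micrometre of depth per row (row 1 = detector
#'   top, depth 0 = shallowest plane edge).
#' @export
rowFocusMap <- function(plan, geometry) {
  nr <- length(plan@rowPower)
  if (nr != geometry@nRows)
    stop(sprintf("plan has %d rows but geometry expects %d", nr,
                 geometry@nRows))
  zPlane <- (seq_len(nr) - 1L) * geometry@pxAxial
  pr <- plan@rowPower
  span <- diff(range(pr))
  if (span == 0) return(rep(max(zPlane) / 2, nr))
  if (is.finite(plan@defocusGain)) {
    zMid <- max(zPlane) / 2
    pMid <- mean(range(pr))
    zMid + plan@defocusGain * (pr - pMid)
  } else {
    (pr - min(pr)) / span * max(zPlane)
  }
}
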