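#' @import methods
NULL

.scalarNum <- function(x, name, lower = -Inf, upper = Inf,
                       strictLower = FALSE, strictUpper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    return(sprintf("'%s' must be a single finite number", name))
  if (strictLower && x <= lower)
    return(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  if (!strictLower && x < lower)
    return(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  if (strictUpper && x >= upper)
    return(sprintf("'%s' must be < %g (got %g)", name, upper, x))
  if (!strictUpper && x > upper)
    return(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  NULL
}

#' Objective lens specification
#'
#' Parametric description of an infinity-corrected microscope objective:
#' numerical aperture, focal length, immersion index and back-aperture
#' (pupil) diameter. The pupil diameter of an infinity-corrected objective
#' is \eqn{2\,\mathrm{NA}\,f}; it defaults to that value and can be
#' overridden when a vendor states a different pupil.
#'
#' @slot na numerical aperture (dimensionless), 0 < na < n.
#' @slot fObj focal length (mm).
#' @slot n immersion refractive index.
#' @slot nominalMag nominal magnification printed on the barrel (may be NA).
#' @slot bfpDiameter back focal plane (pupil) diameter (mm).
#' @name ObjectiveSpec-class
#' @rdname ObjectiveSpec
#' @exportClass ObjectiveSpec
setClass("ObjectiveSpec",
  representation(na = "numeric", fObj = "numeric", n = "numeric",
                 nominalMag = "numeric", bfpDiameter = "numeric"),
  validity = function(object) {
    msg <- c(
      .scalarNum(object@na, "na", lower = 0, strictLower = TRUE),
      .scalarNum(object@n, "n", lower = 1),
      .scalarNum(object@fObj, "fObj", lower = 0, strictLower = TRUE),
      .scalarNum(object@bfpDiameter, "bfpDiameter", lower = 0, strictLower = TRUE))
    if (is.null(msg) && object@na >= object@n)
      msg <- sprintf("'na' must be < immersion index 'n' (na = %g, n = %g)",
                     object@na, object@n)
    if (length(msg)) msg else TRUE
  })

#' @param na numerical aperture.
#' @param fObj focal length in mm. When omitted, the Olympus 180 mm tube-lens
#'   standard is assumed and \code{fObj = 180 / nominalMag}.
#' @param n immersion refractive index (default 1.33, water).
#' @param nominalMag nominal magnification (used only to derive \code{fObj}).
#' @param bfpDiameter pupil diameter in mm; defaults to \code{2 * na * fObj}.
#' @return An \code{ObjectiveSpec} object.
#' @examples
#' ObjectiveSpec(na = 1.1, nominalMag = 60, bfpDiameter = 6.6)
#' @rdname ObjectiveSpec
#' @export
ObjectiveSpec <- function(na, fObj = NULL, n = 1.33, nominalMag = NA_real_,
                          bfpDiameter = NULL) {
  if (is.null(fObj)) {
    if (!is.finite(nominalMag) || nominalMag <= 0)
      stop("either 'fObj' or a positive 'nominalMag' must be given")
    fObj <- 180 / nominalMag
  }
  if (is.null(bfpDiameter)) bfpDiameter <- 2 * na * fObj
  new("ObjectiveSpec", na = as.numeric(na), fObj = as.numeric(fObj),
      n = as.numeric(n), nominalMag = as.numeric(nominalMag),
      bfpDiameter = as.numeric(bfpDiameter))
}

#' Light-sheet illumination specification
#'
#' The excitation beam entering at the edge of the objective pupil: its
#' numerical aperture, its radius at the back focal plane, and its diameter
#' ratio to the objective pupil. When a paired objective is supplied the
#' three are kept consistent through \code{2 * rLs = apertureRatio *
#' bfpDiameter} and \code{naLs = apertureRatio * na}.
#'
#' @slot naLs light-sheet numerical aperture.
#' @slot rLs beam radius at the objective back focal plane (mm).
#' @slot apertureRatio light-sheet to objective aperture diameter ratio.
#' @name LightSheetSpec-class
#' @rdname LightSheetSpec
#' @exportClass LightSheetSpec
setClass("LightSheetSpec",
  representation(naLs = "numeric", rLs = "numeric", apertureRatio = "numeric"),
  validity = function(object) {
    msg <- c(
      .scalarNum(object@naLs, "naLs", lower = 0),
      .scalarNum(object@rLs, "rLs", lower = 0),
      .scalarNum(object@apertureRatio, "apertureRatio", lower = 0, upper = 1))
    if (length(msg)) msg else TRUE
  })

#' @param naLs light-sheet numerical aperture; derived from
#'   \code{apertureRatio * objective@na} when omitted.
#' @param rLs beam radius at the BFP (mm); derived from the ratio when omitted.
#' @param apertureRatio diameter ratio (0..1).
#' @param objective an \code{\link{ObjectiveSpec}} used to derive missing fields.
#' @return A \code{LightSheetSpec}.
#' @rdname LightSheetSpec
#' @export
LightSheetSpec <- function(naLs = NULL, rLs = NULL, apertureRatio = NULL,
                           objective = NULL) {
  if (!is.null(objective) && !is.null(apertureRatio)) {
    if (is.null(rLs))  rLs  <- apertureRatio * objective@bfpDiameter / 2
    if (is.null(naLs)) naLs <- apertureRatio * objective@na
  }
  if (is.null(apertureRatio)) {
    apertureRatio <- if (!is.null(objective) && !is.null(rLs))
      2 * rLs / objective@bfpDiameter else NA_real_
  }
  if (is.null(naLs)) naLs <- 0
  if (is.null(rLs))  rLs  <- 0
  if (!is.null(objective) && is.finite(apertureRatio) &&
      abs(2 * rLs - apertureRatio * objective@bfpDiameter) > 1e-9)
    stop("inconsistent light sheet: 2*rLs must equal apertureRatio * bfpDiameter")
  if (is.na(apertureRatio)) apertureRatio <- 0
  new("LightSheetSpec", naLs = as.numeric(naLs), rLs = as.numeric(rLs),
      apertureRatio = as.numeric(apertureRatio))
}

#' Relay telescope specification
#'
#' Ordered focal lengths of the relay train between the objective and the
#' camera. The first two lenses form the pupil-conjugating 4-f telescope
#' whose magnification \code{mTel = f2/f1} scales the objective pupil onto
#' the tunable lens.
#'
#' @slot focalLengths ordered relay focal lengths (mm).
#' @slot mTel pupil magnification of the first telescope (f2/f1).
#' @name RelaySpec-class
#' @rdname RelaySpec
#' @exportClass RelaySpec
setClass("RelaySpec",
  representation(focalLengths = "numeric", mTel = "numeric"),
  validity = function(object) {
    if (length(object@focalLengths) < 2L)
      return("'focalLengths' needs at least the two pupil-relay lenses")
    if (any(!is.finite(object@focalLengths)) || any(object@focalLengths <= 0))
      return("'focalLengths' must all be positive and finite")
    TRUE
  })

#' @param focalLengths numeric vector of relay focal lengths (mm), ordered
#'   from the objective side.
#' @return A \code{RelaySpec}.
#' @examples
#' RelaySpec(c(125, 300, 200, 100, 200))  # the 2.4x pupil telescope first
#' @rdname RelaySpec
#' @export
RelaySpec <- function(focalLengths) {
  focalLengths <- as.numeric(focalLengths)
  new("RelaySpec", focalLengths = focalLengths,
      mTel = focalLengths[2] / focalLengths[1])
}

#' Electrically tunable lens specification
#'
#' @slot apertureDiameter clear aperture (mm).
#' @slot maxPower maximum optical power magnitude, symmetric converging /
#'   diverging (dioptre).
#' @slot flybackTime minimum reset interval for a sawtooth drive (s).
#' @name ETLSpec-class
#' @rdname ETLSpec
#' @exportClass ETLSpec
setClass("ETLSpec",
  representation(apertureDiameter = "numeric", maxPower = "numeric",
                 flybackTime = "numeric"),
  validity = function(object) {
    msg <- c(
      .scalarNum(object@apertureDiameter, "apertureDiameter", lower = 0,
                 strictLower = TRUE),
      .scalarNum(object@maxPower, "maxPower", lower = 0),
      .scalarNum(object@flybackTime, "flybackTime", lower = 0))
    if (length(msg)) msg else TRUE
  })

#' @param apertureDiameter clear aperture (mm).
#' @param maxPower maximum power magnitude (dioptre), default 5.
#' @param flybackTime sawtooth reset interval (s), default 8 ms (reproduces a
#'   60\% duty cycle at 50 Hz).
#' @return An \code{ETLSpec}.
#' @rdname ETLSpec
#' @export
ETLSpec <- function(apertureDiameter, maxPower = 5, flybackTime = 0.008) {
  new("ETLSpec", apertureDiameter = as.numeric(apertureDiameter),
      maxPower = as.numeric(maxPower), flybackTime = as.numeric(flybackTime))
}

#' Rolling-shutter camera specification
#'
#' @slot nCols,nRows active pixel counts; the rolling shutter runs along rows.
#' @slot pixelPitch detector pixel size (micrometre).
#' @slot lineTime rolling-shutter row interval (s).
#' @slot bidirectionalShutter whether the shutter direction can alternate
#'   between frames (required for a triangular ETL drive).
#' @name CameraSpec-class
#' @rdname CameraSpec
#' @exportClass CameraSpec
setClass("CameraSpec",
  representation(nCols = "integer", nRows = "integer", pixelPitch = "numeric",
                 lineTime = "numeric", bidirectionalShutter = "logical"),
  validity = function(object) {
    msg <- c(
      if (object@nCols < 1L) "'nCols' must be >= 1",
      if (object@nRows < 1L) "'nRows' must be >= 1",
      .scalarNum(object@pixelPitch, "pixelPitch", lower = 0, strictLower = TRUE),
      .scalarNum(object@lineTime, "lineTime", lower = 0, strictLower = TRUE))
    if (length(msg)) msg else TRUE
  })

#' @param nCols,nRows active pixel counts.
#' @param pixelPitch pixel size (micrometre).
#' @param lineTime row interval (s).
#' @param bidirectionalShutter logical, default FALSE (most sCMOS detectors
#'   cannot alternate shutter direction).
#' @return A \code{CameraSpec}.
#' @rdname CameraSpec
#' @export
CameraSpec <- function(nCols, nRows, pixelPitch, lineTime,
                       bidirectionalShutter = FALSE) {
  new("CameraSpec", nCols = as.integer(nCols), nRows = as.integer(nRows),
      pixelPitch = as.numeric(pixelPitch), lineTime = as.numeric(lineTime),
      bidirectionalShutter = isTRUE(bidirectionalShutter))
}

#' Full optical system configuration
#'
#' Bundles the objective, light sheet, relay train, tunable lens and camera,
#' plus the total sample-to-camera lateral magnification (derived from the
#' lens chain via \code{\link{chainMagnification}} unless overridden).
#'
#' @slot objective an \code{\link{ObjectiveSpec}}.
#' @slot lightSheet a \code{\link{LightSheetSpec}}.
#' @slot relays a \code{\link{RelaySpec}}.
#' @slot etl an \code{\link{ETLSpec}}.
#' @slot camera a \code{\link{CameraSpec}}.
#' @slot totalMagnification lateral magnification sample to camera.
#' @name SystemConfig-class
#' @rdname SystemConfig
#' @exportClass SystemConfig
setClass("SystemConfig",
  representation(objective = "ObjectiveSpec", lightSheet = "LightSheetSpec",
                 relays = "RelaySpec", etl = "ETLSpec", camera = "CameraSpec",
                 totalMagnification = "numeric"),
  validity = function(object) {
    msg <- .scalarNum(object@totalMagnification, "totalMagnification",
                      lower = 0, strictLower = TRUE)
    if (is.null(msg) &&
        2 * object@lightSheet@rLs > object@objective@bfpDiameter + 1e-9)
      msg <- "light-sheet aperture exceeds the objective back aperture"
    if (length(msg)) msg else TRUE
  })

#' @param objective,lightSheet,relays,etl,camera component specifications.
#' @param totalMagnification optional override of the derived chain
#'   magnification.
#' @return A \code{SystemConfig}.
#' @rdname SystemConfig
#' @export
SystemConfig <- function(objective, lightSheet, relays, etl, camera,
                         totalMagnification = NULL) {
  if (is.null(totalMagnification))
    totalMagnification <- chainMagnification(relays@focalLengths, objective@fObj)
  new("SystemConfig", objective = objective, lightSheet = lightSheet,
      relays = relays, etl = etl, camera = camera,
      totalMagnification = as.numeric(totalMagnification))
}

#' Derived oblique imaging geometry
#'
#' Quantities derived from a \code{\link{SystemConfig}} and a tilt angle:
#' total magnification, per-axis field of view and per-axis object-space
#' pixel sizes. Axes: \emph{perp} is perpendicular to the light-sheet
#' propagation (camera columns), \emph{par} lies along the oblique plane
#' (camera rows), \emph{axial} is along the optical axis.
#'
#' @slot alpha light-sheet tilt from the optical axis (degrees).
#' @slot m total lateral magnification.
#' @slot fovPerp,fovPar,fovAxial fields of view (micrometre).
#' @slot pxPerp,pxPar,pxAxial object-space pixel sizes (micrometre).
#' @slot nRows,nCols detector pixel counts behind the geometry.
#' @name ObliqueGeometry-class
#' @rdname ObliqueGeometry-class
#' @exportClass ObliqueGeometry
setClass("ObliqueGeometry",
  representation(alpha = "numeric", m = "numeric",
                 fovPerp = "numeric", fovPar = "numeric", fovAxial = "numeric",
                 pxPerp = "numeric", pxPar = "numeric", pxAxial = "numeric",
                 nRows = "integer", nCols = "integer"),
  validity = function(object) {
    msg <- c(
      .scalarNum(object@alpha, "alpha", lower = 0, upper = 90,
                 strictLower = TRUE),
      .scalarNum(object@m, "m", lower = 0, strictLower = TRUE))
    a <- object@alpha * pi / 180
    if (is.null(msg)) {
      if (abs(object@fovAxial - object@fovPar * cos(a)) >
          1e-9 * max(1, abs(object@fovAxial)))
        msg <- "fovAxial must equal fovPar * cos(alpha)"
      else if (abs(object@pxPar - object@pxPerp / sin(a)) >
               1e-9 * max(1, abs(object@pxPar)))
        msg <- "pxPar must equal pxPerp / sin(alpha)"
    }
    if (length(msg)) msg else TRUE
  })

#' Rolling-shutter exposure schedule
#'
#' Per-row exposure start times for one frame, plus the timing context
#' needed by the waveform planner.
#'
#' @slot rowStartTimes per-row exposure start (s), row 1 = detector top.
#' @slot exposureTime per-row exposure duration (s).
#' @slot direction one of \code{"top-down"}, \code{"bottom-up"}.
#' @slot frameRate frame rate (Hz).
#' @slot lineTime row interval (s).
#' @slot bidirectional whether the camera can alternate direction per frame.
#' @name ShutterSchedule-class
#' @rdname ShutterSchedule-class
#' @exportClass ShutterSchedule
setClass("ShutterSchedule",
  representation(rowStartTimes = "numeric", exposureTime = "numeric",
                 direction = "character", frameRate = "numeric",
                 lineTime = "numeric", bidirectional = "logical"),
  validity = function(object) {
    st <- object@rowStartTimes
    ord <- if (object@direction == "bottom-up") rev(st) else st
    if (length(ord) > 1 && any(diff(ord) <= 0))
      return("'rowStartTimes' must be strictly monotonic within a frame")
    if (object@exposureTime <= 0) return("'exposureTime' must be > 0")
    TRUE
  })

#' ETL drive waveform plan
#'
#' Sampled optical-power trace synchronized with a rolling-shutter schedule,
#' plus the per-row mid-exposure power and the duty cycle.
#'
#' @slot frameRate frame rate (Hz).
#' @slot mode \code{"sawtooth"} or \code{"triangular"}.
#' @slot time,power sampled power trace (s, dioptre).
#' @slot flybackTime dead reset interval per frame (s, 0 for triangular).
#' @slot dutyCycle usable fraction of the frame period.
#' @slot rowPower per-row ETL power at mid-exposure (dioptre).
#' @slot rowMidTimes per-row mid-exposure times (s).
#' @slot defocusGain micrometre of axial focus shift per dioptre
#'   (\code{mTel^2 * fObj^2}); NA when unknown.
#' @name WaveformPlan-class
#' @rdname WaveformPlan-class
#' @exportClass WaveformPlan
setClass("WaveformPlan",
  representation(frameRate = "numeric", mode = "character", time = "numeric",
                 power = "numeric", flybackTime = "numeric",
                 dutyCycle = "numeric", rowPower = "numeric",
                 rowMidTimes = "numeric", defocusGain = "numeric"),
  validity = function(object) {
    if (object@dutyCycle <= 0 || object@dutyCycle > 1)
      return("'dutyCycle' must lie in (0, 1]")
    TRUE
  })

#' Synthetic fluorescent bead field
#'
#' Ground-truth bead positions and brightnesses in sample coordinates.
#' Axis convention (used throughout the package): \code{z} along the optical
#' axis (positive into the sample), \code{y} the horizontal scan /
#' light-sheet propagation direction, \code{x} perpendicular to both.
#'
#' @slot positions n x 3 matrix of bead centres, columns x, y, z (micrometre).
#' @slot intensities photon-scale amplitudes (> 0).
#' @slot beadDiameter physical bead size (micrometre).
#' @slot bounds 3 x 2 matrix of the declared volume bounds (rows x, y, z).
#' @slot seed random seed used (NA when not seeded).
#' @name BeadField-class
#' @rdname BeadField-class
#' @exportClass BeadField
setClass("BeadField",
  representation(positions = "matrix", intensities = "numeric",
                 beadDiameter = "numeric", bounds = "matrix", seed = "numeric"),
  validity = function(object) {
    if (ncol(object@positions) != 3L) return("'positions' must have 3 columns")
    if (nrow(object@positions) != length(object@intensities))
      return("'intensities' length must match the number of beads")
    if (length(object@intensities) && any(object@intensities <= 0))
      return("'intensities' must be > 0")
    TRUE
  })

#' Imaging (PSF + noise) model for the forward simulator
#'
#' Separable-Gaussian point-spread model with an empirical defocus blur term,
#' a Gaussian-beam light-sheet thickness law, an optional empirical
#' spherical-aberration widening away from the objective's native focal
#' plane, and a Poisson + Gaussian camera noise model.
#'
#' @slot lateralFwhmFocus in-focus lateral PSF FWHM (micrometre).
#' @slot axialFwhmFocus in-focus axial extent (FWHM, micrometre) of a bead in
#'   the reconstructed volume; sets the effective sheet+detection thickness.
#' @slot sheetWaist light-sheet 1/e^2 waist radius (micrometre).
#' @slot rayleighRange sheet focus depth scale (micrometre).
#' @slot saCoefficient empirical axial-width multiplier slope per micrometre
#'   of distance from the native focal plane (1/micrometre).
#' @slot zNative axial position of the objective's native focal plane
#'   (micrometre); NA means the centre of the axial field of view.
#' @slot defocusSlope lateral blur growth per micrometre of focus mismatch
#'   (dimensionless).
#' @slot photonScale,readNoiseSd,offset camera noise model: counts are
#'   \code{Poisson(photonScale * signal) + N(0, readNoiseSd) + offset},
#'   clipped to 16 bit.
#' @name ImagingModel-class
#' @rdname ImagingModel
#' @exportClass ImagingModel
setClass("ImagingModel",
  representation(lateralFwhmFocus = "numeric", axialFwhmFocus = "numeric",
                 sheetWaist = "numeric", rayleighRange = "numeric",
                 saCoefficient = "numeric", zNative = "numeric",
                 defocusSlope = "numeric", photonScale = "numeric",
                 readNoiseSd = "numeric", offset = "numeric"),
  validity = function(object) {
    msg <- c(
      .scalarNum(object@lateralFwhmFocus, "lateralFwhmFocus", 0, strictLower = TRUE),
      .scalarNum(object@axialFwhmFocus, "axialFwhmFocus", 0, strictLower = TRUE),
      .scalarNum(object@sheetWaist, "sheetWaist", 0, strictLower = TRUE),
      .scalarNum(object@rayleighRange, "rayleighRange", 0, strictLower = TRUE),
      .scalarNum(object@saCoefficient, "saCoefficient", 0))
    if (length(msg)) msg else TRUE
  })

#' @param lateralFwhmFocus,axialFwhmFocus in-focus FWHMs (micrometre).
#' @param sheetWaist sheet waist radius (micrometre); defaults to the axial
#'   FWHM / 2 (the sheet dominates the axial extent).
#' @param rayleighRange sheet depth-of-focus scale (micrometre).
#' @param saCoefficient spherical-aberration widening slope (1/micrometre).
#' @param zNative native focal plane depth (micrometre) or NA for mid-FOV.
#' @param defocusSlope lateral blur per micrometre defocus.
#' @param photonScale,readNoiseSd,offset camera noise model parameters.
#' @return An \code{ImagingModel}.
#' @rdname ImagingModel
#' @export
ImagingModel <- function(lateralFwhmFocus = 0.60, axialFwhmFocus = 1.01,
                         sheetWaist = axialFwhmFocus / 2,
                         rayleighRange = 15, saCoefficient = 0,
                         zNative = NA_real_, defocusSlope = 0.5,
                         photonScale = 1, readNoiseSd = 2, offset = 100) {
  new("ImagingModel", lateralFwhmFocus = lateralFwhmFocus,
      axialFwhmFocus = axialFwhmFocus, sheetWaist = sheetWaist,
      rayleighRange = rayleighRange, saCoefficient = saCoefficient,
      zNative = as.numeric(zNative), defocusSlope = defocusSlope,
      photonScale = photonScale, readNoiseSd = readNoiseSd, offset = offset)
}

#' Raw sheared oblique image stack
#'
#' The simulator's output and the deskewer's input: a (frame, row, column)
#' array of 16-bit counts plus the acquisition metadata needed to build the
#' unwarping affine map.
#'
#' @slot frames integer array indexed (frame, row, col).
#' @slot alpha tilt angle (degrees).
#' @slot magnification total lateral magnification.
#' @slot pixelPitch detector pixel size (micrometre).
#' @slot stageStep horizontal sample translation between frames (micrometre).
#' @slot scanDirection +1 (sample moves toward increasing y) or -1.
#' @slot waveformMode ETL drive mode used during acquisition.
#' @name RawStack-class
#' @rdname RawStack-class
#' @exportClass RawStack
setClass("RawStack",
  representation(frames = "array", alpha = "numeric", magnification = "numeric",
                 pixelPitch = "numeric", stageStep = "numeric",
                 scanDirection = "numeric", waveformMode = "character"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L)
      return("'frames' must be a 3-D array (frame, row, col)")
    rng <- suppressWarnings(range(object@frames))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 65535))
      return("'frames' counts must lie within the 16-bit detector range")
    TRUE
  })

#' Affine raw-index to sample-coordinate map
#'
#' Maps 0-based raw indices (k = frame, r = row, c = column) to sample
#' coordinates (x, y, z) in micrometres:
#' \code{x = c q}, \code{y = dir k s + r q}, \code{z = r q / tan(alpha)}
#' with \code{q = pixelPitch / M} and s the stage step.
#'
#' @slot matrix 3 x 3 linear part; rows x, y, z; columns k, r, c.
#' @slot offset length-3 translation (micrometre).
#' @slot voxelSize intended output grid spacing (micrometre, length 3 z, y, x).
#' @name AffineMap-class
#' @rdname AffineMap-class
#' @exportClass AffineMap
setClass("AffineMap",
  representation(matrix = "matrix", offset = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    if (!all(dim(object@matrix) == c(3L, 3L)))
      return("'matrix' must be 3 x 3")
    if (any(!is.finite(object@matrix))) return("'matrix' must be finite")
    if (any(object@voxelSize <= 0)) return("'voxelSize' must be > 0")
    TRUE
  })

#' Cartesian reconstructed volume
#'
#' @slot data 3-D intensity array, axis order (z, y, x).
#' @slot origin sample coordinate of voxel (1,1,1) centre, order (z, y, x),
#'   micrometre.
#' @slot voxelSize grid spacing (micrometre), order (z, y, x).
#' @slot missingFraction fraction of output voxels with no source data
#'   (zero-filled).
#' @name OPMVolume-class
#' @rdname OPMVolume-class
#' @exportClass OPMVolume
setClass("OPMVolume",
  representation(data = "array", origin = "numeric", voxelSize = "numeric",
                 missingFraction = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("'data' must be a 3-D array (z, y, x)")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("'voxelSize' must be 3 positive numbers (z, y, x)")
    if (length(object@origin) != 3L) return("'origin' must have length 3")
    TRUE
  })
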