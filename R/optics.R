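## Closed-form design calculations for the RF-OPM optical train.
## Unit conventions (used package-wide): mm for focal lengths and apertures,
## micrometre for object-space distances, dioptre for ETL power, degrees for
## angles at API boundaries (converted to radians internally).

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

.safeAsin <- function(x, what) {
  if (!is.finite(x) || x < -1 || x > 1)
    stop(sprintf(
      "arcsin argument out of [-1, 1] for %s (got %g); check the parameters",
      what, x), call. = FALSE)
  asin(x)
}

#' Exact light-sheet tilt angle
#'
#' Angle of the light-sheet from the optical axis when the excitation beam
#' is aligned at the edge of the objective pupil:
#' \deqn{\alpha = \arcsin(\mathrm{NA}_{obj}/n) - \tfrac12 \arcsin(\mathrm{NA}_{ls}/n).}
#' The first term is the objective's marginal-ray angle; the second accounts
#' for the finite angular width of the sheet beam.
#'
#' @param objective an \code{\link{ObjectiveSpec}}.
#' @param lightSheet a \code{\link{LightSheetSpec}}, or NULL for an
#'   infinitely thin sheet (second term vanishes).
#' @return Tilt angle in degrees.
#' @examples
#' obj <- ObjectiveSpec(na = 1.1, fObj = 3)
#' tiltAngleExact(obj)                                     # 55.8 deg
#' tiltAngleExact(obj, LightSheetSpec(naLs = 0.198))       # 51.5 deg
#' @seealso \code{\link{tiltAngleParaxial}}, \code{\link{tiltAngleReport}}
#' @export
tiltAngleExact <- function(objective, lightSheet = NULL) {
  naLs <- if (is.null(lightSheet)) 0 else lightSheet@naLs
  n <- objective@n
  if (naLs >= objective@na)
    stop("light-sheet NA must be smaller than the objective NA")
  .deg(.safeAsin(objective@na / n, "objective NA / n") -
       0.5 * .safeAsin(naLs / n, "light-sheet NA / n"))
}

#' Paraxial light-sheet tilt angle
#'
#' Pupil-plane approximation of the tilt angle,
#' \deqn{\alpha = \arcsin\!\big((D_{obj} - R_{ls}) / (2 f n)\big),}
#' with \eqn{D_{obj}} the back-aperture diameter, \eqn{R_{ls}} the beam
#' radius at the back focal plane and f the objective focal length. This is
#' the form used for system design; it needs only pupil-plane distances.
#'
#' @inheritParams tiltAngleExact
#' @return Tilt angle in degrees.
#' @examples
#' obj <- ObjectiveSpec(na = 1.1, fObj = 3, bfpDiameter = 6.6)
#' ls  <- LightSheetSpec(apertureRatio = 0.18, objective = obj)
#' tiltAngleParaxial(obj, ls)   # 48.8 deg
#' @export
tiltAngleParaxial <- function(objective, lightSheet = NULL) {
  rLs <- if (is.null(lightSheet)) 0 else lightSheet@rLs
  arg <- (objective@bfpDiameter - rLs) / (2 * objective@fObj * objective@n)
  if (arg < 0)
    stop("light-sheet radius exceeds the back-aperture diameter")
  .deg(.safeAsin(arg, "(D_obj - R_ls) / (2 f n)"))
}

#' All tilt-angle estimates for a configuration
#'
#' The exact and paraxial formulas disagree slightly (the paraxial one maps
#' pupil radii to angles linearly), and cropping by the tunable-lens
#' aperture changes the effective NA entering the exact formula. Rather than
#' privileging one estimate this reports all three.
#'
#' @param config a \code{\link{SystemConfig}}.
#' @return A data.frame with columns \code{method} and \code{alpha_deg}:
#'   the exact formula at nominal NA, the exact formula at the ETL-cropped
#'   effective NA, and the paraxial pupil-plane formula.
#' @export
tiltAngleReport <- function(config) {
  obj <- config@objective
  naEff <- effectiveNA(obj, config@relays, config@etl)
  objEff <- obj
  objEff@na <- naEff
  objEff@bfpDiameter <- min(obj@bfpDiameter,
                            config@etl@apertureDiameter / config@relays@mTel)
  lsEff <- LightSheetSpec(apertureRatio = config@lightSheet@apertureRatio,
                          objective = objEff)
  data.frame(
    method = c("exact_nominal", "exact_effective", "paraxial"),
    alpha_deg = c(tiltAngleExact(obj, config@lightSheet),
                  tiltAngleExact(objEff, lsEff),
                  tiltAngleParaxial(obj, config@lightSheet)))
}

#' Effective numerical aperture after pupil cropping by the ETL
#'
#' The objective pupil is relayed onto the tunable lens with pupil
#' magnification \code{mTel}; when the relayed pupil exceeds the ETL clear
#' aperture the NA is cropped proportionally:
#' \code{na * min(1, (D_etl / mTel) / D_bfp)}.
#'
#' @param objective an \code{\link{ObjectiveSpec}}.
#' @param relays a \code{\link{RelaySpec}} (provides \code{mTel}).
#' @param etl an \code{\link{ETLSpec}}.
#' @return Effective NA (never exceeds the objective NA).
#' @examples
#' effectiveNA(ObjectiveSpec(na = 0.5, fObj = 9),
#'             RelaySpec(c(125, 300)), ETLSpec(16))   # 0.37
#' @export
effectiveNA <- function(objective, relays, etl) {
  objective@na * min(1, (etl@apertureDiameter / relays@mTel) /
                        objective@bfpDiameter)
}

#' Total lateral magnification of a lens chain
#'
#' The imaging chain alternates collimating and imaging lenses; total
#' magnification is the product of imaging/collimating focal ratios, the
#' first ratio being f_L1 / f_objective.
#'
#' @param focalLengths relay focal lengths (mm) in order from the objective,
#'   excluding the objective itself; must have odd length so that, with the
#'   objective prepended, lenses pair up.
#' @param fObj objective focal length (mm).
#' @return Magnification (dimensionless).
#' @examples
#' chainMagnification(c(125, 300, 200, 100, 200), fObj = 3)   # 55.56
#' @export
chainMagnification <- function(focalLengths, fObj) {
  full <- c(fObj, as.numeric(focalLengths))
  if (any(!is.finite(full)) || any(full <= 0))
    stop("all focal lengths must be positive and finite")
  if (length(full) %% 2L != 0L)
    stop(sprintf(paste0(
      "lens chain must pair collimating and imaging lenses: got %d relay ",
      "lenses after the objective (need an odd count)"),
      length(focalLengths)))
  idx <- seq(2L, length(full), by = 2L)
  prod(full[idx] / full[idx - 1L])
}

#' Oblique field of view and per-axis sampling
#'
#' For detector side lengths \eqn{D} (pixels times pitch) and magnification
#' M, the raw image spans \eqn{D/M} perpendicular to the sheet propagation
#' (columns) and \eqn{D/(M \sin\alpha)} along the oblique plane (rows); the
#' axial extent covered is \eqn{D/(M \tan\alpha)}. Per-axis object-space
#' pixel sizes follow the same ratios.
#'
#' @param config a \code{\link{SystemConfig}}.
#' @param alpha tilt angle in degrees; defaults to the paraxial estimate
#'   from the configuration. Must lie in (0, 90]; 0 would make the
#'   along-sheet field of view infinite.
#' @return An \code{\link[=ObliqueGeometry-class]{ObliqueGeometry}}.
#' @examples
#' cfg <- loadConfig(system.file("extdata", "config_60x.yaml", package = "rfopm"))
#' fieldOfView(cfg)
#' @export
fieldOfView <- function(config, alpha = NULL) {
  if (is.null(alpha))
    alpha <- tiltAngleParaxial(config@objective, config@lightSheet)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 90)
    stop(sprintf(
      "degenerate geometry: alpha must lie in (0, 90] degrees (got %g); a vertical-axis sheet (alpha = 0) has infinite along-sheet FOV",
      alpha))
  a <- .rad(alpha)
  m <- config@totalMagnification
  cam <- config@camera
  pxPerp <- cam@pixelPitch / m
  new("ObliqueGeometry",
      alpha = alpha, m = m,
      fovPerp = cam@nCols * pxPerp,
      fovPar = cam@nRows * pxPerp / sin(a),
      fovAxial = cam@nRows * pxPerp / tan(a),
      pxPerp = pxPerp, pxPar = pxPerp / sin(a), pxAxial = pxPerp / tan(a),
      nRows = cam@nRows, nCols = cam@nCols)
}

#' Required ETL focal length for a target axial field of view
#'
#' To sweep the focus over an axial range FOVaxial, the tunable lens must
#' reach (both converging and diverging) the focal length
#' \deqn{f_{tl} = 2 M_{tel}^2 f_{obj}^2 / \mathrm{FOV}_{axial}.}
#'
#' @param mTel pupil telescope magnification (objective BFP to ETL).
#' @param fObj objective focal length (mm).
#' @param fovAxial axial field of view (micrometre).
#' @return Required focal length magnitude (mm).
#' @examples
#' requiredEtlFocal(2.4, 3, 104)   # ~997 mm
#' @seealso \code{\link{etlPowerToDefocus}} (the inverse relation)
#' @export
requiredEtlFocal <- function(mTel, fObj, fovAxial) {
  if (!is.finite(fovAxial) || fovAxial <= 0)
    stop("'fovAxial' must be > 0 (micrometre)")
  2000 * mTel^2 * fObj^2 / fovAxial
}

#' Axial focus shift produced by an ETL power
#'
#' A pupil-conjugate lens of power P (dioptre) behind a pupil telescope of
#' magnification mTel shifts the imaged plane by
#' \code{dz = mTel^2 * fObj^2 * P} micrometres (sign preserved; fObj in mm).
#' Driving the lens over \eqn{\pm P} spans exactly the axial field of view
#' of \code{\link{requiredEtlFocal}}.
#'
#' @param power ETL optical power (dioptre); vectorized.
#' @param mTel pupil telescope magnification.
#' @param fObj objective focal length (mm).
#' @return Axial focus shift (micrometre).
#' @examples
#' etlPowerToDefocus(1.003, 2.4, 3)   # ~52 um
#' @export
etlPowerToDefocus <- function(power, mTel, fObj) {
  mTel^2 * fObj^2 * power
}
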