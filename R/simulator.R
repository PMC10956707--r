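## Forward model: raw rolling-shutter frames of synthetic bead fields under
## the oblique-plane geometry.
##
## Sample coordinate frame (stated once, used everywhere): z along the
## optical axis (positive into the sample), y the horizontal scan /
## light-sheet propagation direction, x perpendicular to both. Detector row
## 0 maps to the shallowest depth. The light sheet occupies the plane
## y_rel = z * tan(alpha) in stage-relative coordinates
## (y_rel = y - scanDirection * k * stageStep at frame k).

.FWHM2SD <- 1 / (2 * sqrt(2 * log(2)))

#' Generate a random synthetic bead field
#'
#' Uniformly distributed point emitters inside a rectangular volume,
#' emulating sub-diffraction fluorescent microbeads embedded in agarose.
#'
#' @param bounds 3 x 2 numeric matrix, rows x, y, z (micrometre), columns
#'   lower/upper.
#' @param nBeads number of beads (>= 0).
#' @param intensityRange amplitude range (photon-scale counts at the peak),
#'   drawn uniformly.
#' @param beadDiameter physical bead diameter (micrometre); sub-diffraction
#'   beads act as point sources, the value is metadata.
#' @param seed optional integer seed; fixed seed gives identical fields.
#' @return A \code{\link[=BeadField-class]{BeadField}}.
#' @examples
#' bf <- generateBeadField(rbind(x = c(0, 240), y = c(0, 420), z = c(0, 104)),
#'                         nBeads = 500, seed = 1)
#' @export
generateBeadField <- function(bounds, nBeads, intensityRange = c(500, 2000),
                              beadDiameter = 0.17, seed = NULL) {
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(3L, 2L))) stop("'bounds' must be a 3 x 2 matrix")
  if (nBeads < 0) stop("'nBeads' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pos <- cbind(
    x = stats::runif(nBeads, bounds[1, 1], bounds[1, 2]),
    y = stats::runif(nBeads, bounds[2, 1], bounds[2, 2]),
    z = stats::runif(nBeads, bounds[3, 1], bounds[3, 2]))
  ints <- stats::runif(nBeads, intensityRange[1], intensityRange[2])
  new("BeadField", positions = pos, intensities = ints,
      beadDiameter = beadDiameter, bounds = bounds,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Relative light-sheet illumination at a point
#'
#' Gaussian-beam sheet tilted by alpha from the optical axis, with 1/e^2
#' half-thickness \eqn{w(s) = w_0 \sqrt{1 + ((s - s_f)/z_R)^2}} along the
#' propagation coordinate s and peak intensity scaling as \eqn{w_0/w(s)}
#' (energy conservation). The returned value is 1 at the traveling focus on
#' the sheet and \eqn{e^{-2}} one waist away across the sheet.
#'
#' @param point numeric length-3 (x, y, z) or n x 3 matrix, micrometre
#'   (stage-relative coordinates).
#' @param geometry an \code{\link[=ObliqueGeometry-class]{ObliqueGeometry}}.
#' @param focusPosition along-sheet coordinate of the traveling focus
#'   (micrometre).
#' @param model an \code{\link{ImagingModel}} (waist and Rayleigh range).
#' @return Relative illumination in [0, 1] (vectorized over rows).
#' @export
sheetIntensity <- function(point, geometry, focusPosition, model) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  a <- .rad(geometry@alpha)
  d <- (p[, 2] - p[, 3] * tan(a)) * cos(a)      # across-sheet distance
  s <- p[, 2] * sin(a) + p[, 3] * cos(a)        # along-sheet coordinate
  w <- model@sheetWaist * sqrt(1 + ((s - focusPosition) /
                                      model@rayleighRange)^2)
  (model@sheetWaist / w) * exp(-2 * d^2 / w^2)
}

## Linear interpolation of the row->focus map with linear extrapolation at
## the ends (defocus keeps growing beyond the detector edges).
.interpRowFocus <- function(rowFocus, r0) {
  nr <- length(rowFocus)
  if (nr == 1L) return(rep(rowFocus, length(r0)))
  i <- pmin(pmax(floor(r0), 0), nr - 2L)
  f <- r0 - i
  rowFocus[i + 1L] * (1 - f) + rowFocus[i + 2L] * f
}

.applyNoise <- function(signal, model, noise) {
  if (noise) {
    n <- length(signal)
    counts <- stats::rpois(n, model@photonScale * as.vector(signal)) +
      stats::rnorm(n, 0, model@readNoiseSd) + model@offset
  } else {
    counts <- model@photonScale * as.vector(signal) + model@offset
  }
  matrix(as.integer(pmin(pmax(round(counts), 0), 65535)),
         nrow(signal), ncol(signal))
}

## Core renderer for one frame; returns the noiseless signal matrix
## (rows x cols) in photon-scale units, without offset.
.renderSignal <- function(beads, geometry, model, rowFocus,
                          frameIndex, stageStep, scanDirection) {
  nr <- geometry@nRows; nc <- geometry@nCols
  a <- .rad(geometry@alpha)
  pxp <- geometry@pxPerp
  zN <- if (is.finite(model@zNative)) model@zNative else geometry@fovAxial / 2
  sigLat0 <- model@lateralFwhmFocus * .FWHM2SD
  sigPerp0 <- model@axialFwhmFocus * .FWHM2SD * sin(a)
  signal <- matrix(0, nr, nc)
  pos <- beads@positions
  if (!nrow(pos)) return(signal)
  yRel <- pos[, 2] - scanDirection * frameIndex * stageStep
  r0 <- yRel / pxp                 # 0-based fractional row of the projection
  c0 <- pos[, 1] / pxp             # 0-based fractional column
  zFoc <- .interpRowFocus(rowFocus, r0)
  delta <- pos[, 3] - zFoc         # focus mismatch at this bead's row
  saMult <- 1 + model@saCoefficient * abs(pos[, 3] - zN)
  sigPerp <- model@axialFwhmFocus * .FWHM2SD * saMult * sin(a) *
    sqrt(1 + ((delta / cos(a)) / model@rayleighRange)^2)
  dPerp <- (yRel - pos[, 3] * tan(a)) * cos(a)
  wAx <- (sigPerp0 / sigPerp) * exp(-dPerp^2 / (2 * sigPerp^2))
  ## spherical aberration blurs the detection PSF too, not just the sheet
  sigLat <- sqrt((sigLat0 * saMult)^2 + (model@defocusSlope * delta)^2)
  amp <- beads@intensities * wAx * (sigLat0 / sigLat)^2
  sigPx <- sigLat / pxp
  for (b in which(amp > 1e-4 * beads@intensities)) {
    h <- 4 * sigPx[b]
    rr <- max(0, floor(r0[b] - h)):min(nr - 1, ceiling(r0[b] + h))
    cc <- max(0, floor(c0[b] - h)):min(nc - 1, ceiling(c0[b] + h))
    if (rr[1] > rr[length(rr)] || cc[1] > cc[length(cc)] ||
        r0[b] < -h || r0[b] > nr - 1 + h || c0[b] < -h || c0[b] > nc - 1 + h)
      next
    g <- amp[b] * outer(exp(-(rr - r0[b])^2 / (2 * sigPx[b]^2)),
                        exp(-(cc - c0[b])^2 / (2 * sigPx[b]^2)))
    signal[rr + 1L, cc + 1L] <- signal[rr + 1L, cc + 1L] + g
  }
  signal
}

.resolveRowFocus <- function(plan, geometry) {
  if (is.null(plan))
    (seq_len(geometry@nRows) - 1L) * geometry@pxAxial   # ideal sync
  else if (is.numeric(plan)) plan
  else rowFocusMap(plan, geometry)
}

#' Render one raw rolling-shutter frame
#'
#' Each bead contributes a Gaussian spot at its horizontal camera projection
#' (column from x, row from stage-relative y). Brightness is weighted by the
#' Gaussian sheet profile across the oblique plane; lateral width is the
#' in-focus width convolved (in quadrature) with a defocus term proportional
#' to the mismatch between the bead depth and the depth in focus at its row;
#' an optional empirical spherical-aberration term widens the axial response
#' away from the native focal plane. Poisson and Gaussian read noise are
#' applied last.
#'
#' @param beads a \code{\link[=BeadField-class]{BeadField}}.
#' @param geometry an \code{\link[=ObliqueGeometry-class]{ObliqueGeometry}}.
#' @param model an \code{\link{ImagingModel}}.
#' @param plan focus synchronization: NULL for ideal synchronization (the
#'   focus ramp matches the oblique plane), a
#'   \code{\link[=WaveformPlan-class]{WaveformPlan}}, or a numeric per-row
#'   depth vector (e.g. a constant for a static, unsynchronized focus).
#' @param frameIndex 0-based frame number (sets the stage position).
#' @param stageStep horizontal translation between frames (micrometre).
#' @param scanDirection +1 or -1.
#' @param noise apply the camera noise model (default TRUE).
#' @param seed optional seed for the noise draw.
#' @return Integer matrix (rows x cols) of 16-bit counts.
#' @export
renderRawFrame <- function(beads, geometry, model, plan = NULL,
                           frameIndex = 0, stageStep = 0, scanDirection = 1,
                           noise = TRUE, seed = NULL) {
  rowFocus <- .resolveRowFocus(plan, geometry)
  if (length(rowFocus) != geometry@nRows)
    stop(sprintf("row focus map has %d entries but the frame has %d rows",
                 length(rowFocus), geometry@nRows))
  if (!is.null(seed)) set.seed(seed)
  sig <- .renderSignal(beads, geometry, model, rowFocus, frameIndex,
                       stageStep, scanDirection)
  .applyNoise(sig, model, noise)
}

#' Render a stage-scanned raw stack
#'
#' Renders \code{nFrames} rolling-shutter frames, translating the sample
#' horizontally by \code{stageStep} between frames, and bundles them with
#' the acquisition metadata required for deskewing.
#'
#' @inheritParams renderRawFrame
#' @param nFrames number of frames.
#' @param stageStep stage translation per frame (micrometre, > 0).
#' @param waveformMode metadata tag for the drive mode.
#' @return A \code{\link[=RawStack-class]{RawStack}}.
#' @examples
#' geom <- obliqueGeometry(alpha = 30, m = 16.7, pixelPitch = 6.5,
#'                         nRows = 32, nCols = 64)
#' bf <- generateBeadField(rbind(c(5, 20), c(5, 20), c(2, 18)), 3, seed = 1)
#' stk <- renderStack(bf, geom, ImagingModel(), nFrames = 40, stageStep = 0.5,
#'                    seed = 1)
#' @export
renderStack <- function(beads, geometry, model, nFrames, stageStep,
                        plan = NULL, scanDirection = 1,
                        waveformMode = "sawtooth", noise = TRUE, seed = NULL) {
  if (stageStep < 0) stop("'stageStep' must be >= 0")
  rowFocus <- .resolveRowFocus(plan, geometry)
  if (!is.null(seed)) set.seed(seed)
  nr <- geometry@nRows; nc <- geometry@nCols
  arr <- array(0L, c(nFrames, nr, nc))
  for (k in seq_len(nFrames)) {
    sig <- .renderSignal(beads, geometry, model, rowFocus, k - 1L,
                         stageStep, scanDirection)
    arr[k, , ] <- .applyNoise(sig, model, noise)
  }
  new("RawStack", frames = arr, alpha = geometry@alpha,
      magnification = geometry@m,
      pixelPitch = geometry@pxPerp * geometry@m, stageStep = stageStep,
      scanDirection = scanDirection, waveformMode = waveformMode)
}

#' Compact oblique geometry for desk-scale simulations
#'
#' Convenience constructor of an \code{ObliqueGeometry} from first
#' principles (magnification, pixel pitch, counts, angle) without a full
#' \code{\link{SystemConfig}}; used for small synthetic scenes.
#'
#' @param alpha tilt angle (degrees).
#' @param m lateral magnification.
#' @param pixelPitch detector pixel size (micrometre).
#' @param nRows,nCols detector pixel counts.
#' @return An \code{\link[=ObliqueGeometry-class]{ObliqueGeometry}}.
#' @export
obliqueGeometry <- function(alpha, m, pixelPitch, nRows, nCols) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 90)
    stop("alpha must lie in (0, 90] degrees")
  a <- .rad(alpha)
  pxp <- pixelPitch / m
  new("ObliqueGeometry", alpha = alpha, m = m,
      fovPerp = nCols * pxp, fovPar = nRows * pxp / sin(a),
      fovAxial = nRows * pxp / tan(a),
      pxPerp = pxp, pxPar = pxp / sin(a), pxAxial = pxp / tan(a),
      nRows = as.integer(nRows), nCols = as.integer(nCols))
}
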