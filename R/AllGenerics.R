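#' Accessors for rfopm objects
#'
#' Small accessor family: \code{alphaDeg} returns the light-sheet tilt angle
#' in degrees, \code{totalMag} the lateral magnification, \code{frames} the
#' raw (frame, row, col) array, \code{volumeData} the (z, y, x) array,
#' \code{voxelSize} the output grid spacing and \code{beadPositions} the
#' ground-truth bead centre matrix.
#'
#' @param x an rfopm object.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphaDeg", function(x) standardGeneric("alphaDeg"))
#' @rdname accessors
#' @export
setMethod("alphaDeg", "ObliqueGeometry", function(x) x@alpha)
#' @rdname accessors
#' @export
setMethod("alphaDeg", "RawStack", function(x) x@alpha)

#' @rdname accessors
#' @export
setGeneric("totalMag", function(x) standardGeneric("totalMag"))
#' @rdname accessors
#' @export
setMethod("totalMag", "ObliqueGeometry", function(x) x@m)
#' @rdname accessors
#' @export
setMethod("totalMag", "SystemConfig", function(x) x@totalMagnification)
#' @rdname accessors
#' @export
setMethod("totalMag", "RawStack", function(x) x@magnification)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "RawStack", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setMethod("volumeData", "OPMVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "OPMVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "AffineMap", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("beadPositions", function(x) standardGeneric("beadPositions"))
#' @rdname accessors
#' @export
setMethod("beadPositions", "BeadField", function(x) x@positions)

setMethod("show", "SystemConfig", function(object) {
  cat("SystemConfig\n")
  cat(sprintf("  objective : NA %.2f, f %.3g mm, n %.3g, pupil %.3g mm\n",
              object@objective@na, object@objective@fObj, object@objective@n,
              object@objective@bfpDiameter))
  cat(sprintf("  light sheet: NA %.3g, r_BFP %.3g mm (ratio %.3g)\n",
              object@lightSheet@naLs, object@lightSheet@rLs,
              object@lightSheet@apertureRatio))
  cat(sprintf("  relays    : %s mm (pupil mag %.3gx)\n",
              paste(object@relays@focalLengths, collapse = ", "),
              object@relays@mTel))
  cat(sprintf("  ETL       : %.3g mm aperture, +/-%.3g D, flyback %.3g ms\n",
              object@etl@apertureDiameter, object@etl@maxPower,
              1e3 * object@etl@flybackTime))
  cat(sprintf("  camera    : %d x %d px, %.3g um pitch, line time %.3g us\n",
              object@camera@nCols, object@camera@nRows,
              object@camera@pixelPitch, 1e6 * object@camera@lineTime))
  cat(sprintf("  total magnification: %.4gx\n", object@totalMagnification))
})

setMethod("show", "ObliqueGeometry", function(object) {
  cat("ObliqueGeometry\n")
  cat(sprintf("  tilt alpha : %.3f deg\n", object@alpha))
  cat(sprintf("  mag        : %.4gx\n", object@m))
  cat(sprintf("  FOV (perp, par, axial): %.4g, %.4g, %.4g um\n",
              object@fovPerp, object@fovPar, object@fovAxial))
  cat(sprintf("  px  (perp, par, axial): %.4g, %.4g, %.4g um\n",
              object@pxPerp, object@pxPar, object@pxAxial))
})

setMethod("show", "RawStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("RawStack: %d frames x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  alpha %.3f deg, mag %.4gx, pitch %.3g um, stage step %.3g um, scan %+d, %s drive\n",
              object@alpha, object@magnification, object@pixelPitch,
              object@stageStep, as.integer(object@scanDirection),
              object@waveformMode))
})

setMethod("show", "OPMVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("OPMVolume: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel %.4g x %.4g x %.4g um, origin (%.4g, %.4g, %.4g) um, %.2f%% unfilled\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@origin[1], object@origin[2], object@origin[3],
              100 * object@missingFraction))
})

setMethod("show", "WaveformPlan", function(object) {
  cat(sprintf("WaveformPlan: %s drive at %.4g Hz, duty cycle %.3g, flyback %.3g ms\n",
              object@mode, object@frameRate, object@dutyCycle,
              1e3 * object@flybackTime))
  cat(sprintf("  row power span %.4g .. %.4g D over %d rows\n",
              min(object@rowPower), max(object@rowPower),
              length(object@rowPower)))
})

setMethod("show", "BeadField", function(object) {
  cat(sprintf("BeadField: %d beads of %.3g um in [%g, %g] x [%g, %g] x [%g, %g] um (x, y, z)\n",
              nrow(object@positions), object@beadDiameter,
              object@bounds[1, 1], object@bounds[1, 2],
              object@bounds[2, 1], object@bounds[2, 2],
              object@bounds[3, 1], object@bounds[3, 2]))
})
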