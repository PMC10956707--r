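# Shared fixtures: configurations, a desk-scale geometry and imaging model,
# and a simulate-scene helper used across the deskew/PSF tests.

cfg60 <- function() {
  loadConfig(system.file("extdata", "config_60x.yaml", package = "rfopm"))
}

cfg20 <- function() {
  loadConfig(system.file("extdata", "config_20x.yaml", package = "rfopm"))
}

# 45 deg desk geometry: isotropic native voxel (pxAxial == pxPerp == 0.39 um)
deskGeometry <- function(nRows = 64, nCols = 96, alpha = 45, m = 16.67) {
  obliqueGeometry(alpha = alpha, m = m, pixelPitch = 6.5,
                  nRows = nRows, nCols = nCols)
}

# compact PSF so that neighbouring beads interact little at desk densities
deskModel <- function(...) {
  args <- list(lateralFwhmFocus = 1.0, axialFwhmFocus = 2.0, sheetWaist = 1.0,
               rayleighRange = 40, readNoiseSd = 2, offset = 100)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ImagingModel, args)
}

# beads constrained so that every bead crosses the sheet during the sweep
# and sits clear of the detector borders
simScene <- function(geom, model, nBeads, nFrames, stageStep, seed,
                     margin = 4, intensityRange = c(800, 2000)) {
  ta <- tan(geom@alpha * pi / 180)
  zLo <- margin * geom@pxAxial
  zHi <- geom@fovAxial - margin * geom@pxAxial
  yLo <- margin * stageStep + zHi * ta
  yHi <- (nFrames - 1 - margin) * stageStep + zLo * ta
  stopifnot(yHi > yLo)
  bounds <- rbind(x = c(margin * geom@pxPerp, geom@fovPerp - margin * geom@pxPerp),
                  y = c(yLo, yHi), z = c(zLo, zHi))
  beads <- generateBeadField(bounds, nBeads, intensityRange, seed = seed)
  stack <- renderStack(beads, geom, model, nFrames, stageStep, seed = seed + 1)
  list(beads = beads, stack = stack, bounds = bounds)
}

# one shared 200-bead round-trip scene (simulate -> deskew -> measure),
# cached because both the pipeline invariants and the acceptance checks
# grade it
.sceneCache <- new.env(parent = emptyenv())
beadScene200 <- function() {
  if (!is.null(.sceneCache$s200)) return(.sceneCache$s200)
  geom <- deskGeometry(nRows = 64, nCols = 256)
  model <- deskModel()
  sc <- simScene(geom, model, nBeads = 200, nFrames = 400, stageStep = 0.39,
                 seed = 17, intensityRange = c(600, 2000))
  vol <- applyDeskew(sc$stack)
  meas <- measureBeads(vol, threshold = 180, minSeparation = 1.5,
                       window = c(9, 9, 9))
  meas <- meas[meas$fit_ok, , drop = FALSE]
  .sceneCache$s200 <- list(truth = beadPositions(sc$beads), meas = meas,
                           voxel = vol@voxelSize[1])
  .sceneCache$s200
}

# distance from each measured centroid to its nearest ground-truth bead
nearestTruthDist <- function(meas, truth) {
  vapply(seq_len(nrow(meas)), function(i) {
    min(sqrt((truth[, 1] - meas$x[i])^2 + (truth[, 2] - meas$y[i])^2 +
               (truth[, 3] - meas$z[i])^2))
  }, numeric(1))
}

# distance from each ground-truth bead to its nearest measurement
truthToMeasDist <- function(truth, meas) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (!nrow(meas)) return(Inf)
    min(sqrt((meas$x - truth[i, 1])^2 + (meas$y - truth[i, 2])^2 +
               (meas$z - truth[i, 3])^2))
  }, numeric(1))
}
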