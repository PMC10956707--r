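# Affine deskew: map construction, resampling, and parameter-recovery
# properties against the generator's ground truth.

test_that("affine map reproduces the shear/stretch arithmetic", {
  geom <- obliqueGeometry(alpha = 48, m = 55.556, pixelPitch = 6.5,
                          nRows = 128, nCols = 64)
  bf <- generateBeadField(rbind(c(0, 1), c(0, 1), c(0, 1)), 0)
  stk <- renderStack(bf, geom, deskModel(), nFrames = 2, stageStep = 0.4,
                     noise = FALSE)
  map <- buildAffine(stk)
  # origin maps to the origin
  expect_equal(as.numeric(mapRawToSample(map, c(0, 0, 0))), c(0, 0, 0))
  # row 100 at ~0.117 um/px and 48 deg: z = 100 * 0.117 / tan(48 deg) ~ 10.53
  p <- mapRawToSample(map, c(0, 100, 0))
  expect_equal(unname(p[1, "z"]), 10.535, tolerance = 1e-4)
  expect_equal(unname(p[1, "z"]), 100 * (6.5 / 55.556) / tan(48 * pi / 180),
               tolerance = 1e-12)
  # frame index advances y by the stage step; columns advance x only
  expect_equal(as.numeric(mapRawToSample(map, c(5, 0, 0))),
               c(0, 5 * 0.4, 0))
  expect_equal(unname(mapRawToSample(map, c(0, 0, 10))[1, "x"]),
               10 * 6.5 / 55.556, tolerance = 1e-12)
  # vertical sheet: depth degenerates to zero everywhere
  stk90 <- stk; stk90@alpha <- 90
  map90 <- buildAffine(stk90)
  expect_equal(unname(mapRawToSample(map90, c(3, 50, 7))[1, "z"]), 0)
  # missing metadata is reported by name
  bad <- stk; bad@stageStep <- NA_real_
  expect_error(buildAffine(bad), "stageStep")
})

test_that("identity map with nearest interpolation is a bitwise no-op", {
  set.seed(3)
  arr <- array(sample.int(1000, 4 * 6 * 5, replace = TRUE), c(4, 6, 5))
  stk <- new("RawStack", frames = arr, alpha = 45, magnification = 1,
             pixelPitch = 1, stageStep = 1, scanDirection = 1,
             waveformMode = "sawtooth")
  idMap <- new("AffineMap",
               matrix = rbind(x = c(0, 0, 1), y = c(0, 1, 0), z = c(1, 0, 0)),
               offset = c(0, 0, 0), voxelSize = c(1, 1, 1))
  vol <- applyDeskew(stk, idMap, interpolation = "nearest")
  expect_identical(dim(volumeData(vol)), dim(arr))
  expect_true(all(volumeData(vol) == arr))
  expect_identical(vol@missingFraction, 0)
  # a singular map is rejected
  sing <- idMap; sing@matrix[3, ] <- 0
  expect_error(applyDeskew(stk, sing), "invertible")
})

test_that("equal-depth beads land at equal z and the shear is removed", {
  geom <- deskGeometry(nRows = 64, nCols = 64)
  model <- deskModel()
  a <- geom@alpha * pi / 180
  z0 <- 10
  # same depth, different rows (the second crosses the sheet later)
  pos <- rbind(c(8, z0 * tan(a) + 2, z0), c(17, z0 * tan(a) + 14, z0))
  bf <- new("BeadField", positions = pos, intensities = c(3000, 3000),
            beadDiameter = 0.17, bounds = rbind(c(0, 25), c(0, 40), c(0, 25)),
            seed = NA_real_)
  stk <- renderStack(bf, geom, model, nFrames = 60, stageStep = 0.39,
                     noise = FALSE)
  vol <- applyDeskew(stk)
  meas <- measureBeads(vol, threshold = 300, minSeparation = 3,
                       window = c(9, 9, 9))
  expect_identical(nrow(meas), 2L)
  expect_lt(abs(diff(meas$z)), 0.5 * vol@voxelSize[1])
  expect_equal(sort(meas$z), rep(z0, 2), tolerance = 0.05)
})

test_that("simulate -> deskew -> detect recovers bead positions (20 seeded fields)", {
  geom <- deskGeometry(nRows = 48, nCols = 64)
  model <- deskModel()
  voxel <- 6.5 / 16.67   # output voxel, um
  errs <- c()
  for (s in 1:20) {
    sc <- simScene(geom, model, nBeads = 8, nFrames = 80, stageStep = 0.39,
                   seed = 100 + s)
    vol <- applyDeskew(sc$stack)
    meas <- measureBeads(vol, threshold = 200, minSeparation = 2,
                         window = c(9, 9, 9))
    meas <- meas[meas$fit_ok, , drop = FALSE]
    expect_gt(nrow(meas), 0)
    errs <- c(errs, nearestTruthDist(meas, beadPositions(sc$beads)))
  }
  expect_lt(mean(errs), 0.5 * voxel)
})

test_that("pairwise distances between deskewed centroids match ground truth within 1%", {
  geom <- deskGeometry(nRows = 64, nCols = 96)
  model <- deskModel(readNoiseSd = 0)
  a <- geom@alpha * pi / 180
  # hand-placed, well-separated beads (>= 8 um pairwise)
  pos <- rbind(c(8, 12, 6), c(25, 18, 9), c(14, 28, 17),
               c(30, 34, 13), c(20, 22, 21))
  colnames(pos) <- c("x", "y", "z")
  bf <- new("BeadField", positions = pos, intensities = rep(8000, 5),
            beadDiameter = 0.17, bounds = rbind(c(0, 37), c(0, 45), c(0, 25)),
            seed = NA_real_)
  stk <- renderStack(bf, geom, model, nFrames = 110, stageStep = 0.39,
                     noise = FALSE)
  vol <- applyDeskew(stk)
  meas <- measureBeads(vol, threshold = 500, minSeparation = 4,
                       window = c(9, 9, 9))
  expect_identical(nrow(meas), 5L)
  # match measurements to truth rows
  ord <- vapply(seq_len(5), function(i)
    which.min((pos[, 1] - meas$x[i])^2 + (pos[, 2] - meas$y[i])^2 +
                (pos[, 3] - meas$z[i])^2), integer(1))
  expect_setequal(ord, 1:5)
  gt <- pos[ord, ]
  dTrue <- dist(gt); dMeas <- dist(cbind(meas$x, meas$y, meas$z))
  expect_lt(max(abs(dMeas - dTrue) / dTrue), 0.01)
})

test_that("nearest-neighbour resampling conserves intensity for well-sampled spots", {
  # stage step equal to the native voxel and alpha = 45 deg make the raw
  # sampling volume-preserving, so total intensity must carry over
  geom <- deskGeometry(nRows = 64, nCols = 64)
  model <- deskModel(readNoiseSd = 0, offset = 0)
  a <- geom@alpha * pi / 180
  q <- geom@pxPerp
  s <- q * tan(a)   # = q at 45 deg
  pos <- rbind(c(10, 14, 8), c(16, 24, 14))
  colnames(pos) <- c("x", "y", "z")
  bf <- new("BeadField", positions = pos, intensities = c(4000, 6000),
            beadDiameter = 0.17, bounds = rbind(c(0, 25), c(0, 40), c(0, 25)),
            seed = NA_real_)
  stk <- renderStack(bf, geom, model, nFrames = 110, stageStep = s,
                     noise = FALSE)
  vol <- applyDeskew(stk, buildAffine(stk), interpolation = "nearest")
  expect_lt(abs(sum(volumeData(vol)) - sum(frames(stk))) / sum(frames(stk)),
            0.01)
})
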