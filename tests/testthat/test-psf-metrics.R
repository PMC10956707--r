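# Bead characterization pipeline: detection, Gaussian fits, axial binning,
# averaged bead images.

# small synthetic volume with separable Gaussian beads at given voxel
# centres (1-based indices), plus optional seeded noise
gaussVolume <- function(dims, centres, sigma, amplitude = 1000, offset = 100,
                        noiseSd = 0, voxel = 0.5, seed = NULL) {
  v <- array(offset, dims)
  iz <- slice.index(v, 1); iy <- slice.index(v, 2); ix <- slice.index(v, 3)
  for (i in seq_len(nrow(centres))) {
    amp <- if (length(amplitude) > 1) amplitude[i] else amplitude
    v <- v + amp * exp(-((iz - centres[i, 1])^2 + (iy - centres[i, 2])^2 +
                           (ix - centres[i, 3])^2) / (2 * sigma^2))
  }
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + array(rnorm(length(v), 0, noiseSd), dims)
  }
  new("OPMVolume", data = v, origin = c(0, 0, 0),
      voxelSize = rep(voxel, 3), missingFraction = 0)
}

test_that("detection finds isolated maxima and applies suppression rules", {
  centres <- rbind(c(10, 10, 10), c(10, 25, 12), c(22, 14, 20))
  vol <- gaussVolume(c(32, 36, 30), centres, sigma = 1.5)
  det <- detectBeads(vol, threshold = 200, minSeparation = 2)
  expect_identical(nrow(det), 3L)
  expect_setequal(det$iz, centres[, 1])
  # uniform volume: nothing to detect
  flat <- new("OPMVolume", data = array(100, c(10, 10, 10)),
              origin = c(0, 0, 0), voxelSize = rep(0.5, 3),
              missingFraction = 0)
  expect_identical(nrow(detectBeads(flat)), 0L)
  # empty volume: empty result
  none <- new("OPMVolume", data = array(0, c(0, 4, 4)), origin = c(0, 0, 0),
              voxelSize = rep(0.5, 3), missingFraction = 0)
  expect_identical(nrow(detectBeads(none)), 0L)
  # two maxima within the separation radius: the brighter one wins
  close2 <- gaussVolume(c(24, 24, 24), rbind(c(12, 10, 12), c(12, 13, 12)),
                        sigma = 1, amplitude = c(800, 1200))
  det2 <- detectBeads(close2, threshold = 200, minSeparation = 3)
  expect_identical(nrow(det2), 1L)
  expect_identical(det2$iy, 13L)   # the brighter of the pair
  # border margin removes candidates too close to a face
  edge <- gaussVolume(c(24, 24, 24), rbind(c(3, 12, 12)), sigma = 1)
  expect_identical(nrow(detectBeads(edge, threshold = 200, border = 4)), 0L)
  expect_identical(nrow(detectBeads(edge, threshold = 200, border = 2)), 1L)
})

test_that("Gaussian fits recover sigma and the FWHM/sigma ratio is exact", {
  # noiseless separable Gaussian, sigma = 2 voxels -> FWHM = 4.71 voxels
  vol <- gaussVolume(c(31, 31, 31), rbind(c(16, 16, 16)), sigma = 2,
                     voxel = 1)
  m <- fitBead(vol, c(16, 16, 16), window = c(15, 15, 15))
  expect_true(m$fit_ok)
  expect_equal(m$fwhm_z, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-3)
  expect_equal(c(m$x, m$y, m$z), c(15, 15, 15), tolerance = 1e-3)
  # ratio holds for every reported axis by construction of the table
  expect_equal(m$fwhm_x / m$sigma_x, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(m$fwhm_y / m$sigma_y, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  # degenerate flat-top (saturated) profile: flagged not ok, or at bounds
  sat <- vol
  sat@data <- pmin(sat@data, 150)
  msat <- fitBead(sat, c(16, 16, 16), window = c(15, 15, 15))
  expect_false(msat$fit_ok)
  # window leaving the volume is an error
  expect_error(fitBead(vol, c(3, 16, 16), window = c(15, 15, 15)),
               "outside")
})

test_that("detection recall and precision reach 0.95 on a 200-bead seeded field", {
  sc <- beadScene200()
  recall <- mean(truthToMeasDist(sc$truth, sc$meas) < sc$voxel)
  precision <- mean(nearestTruthDist(sc$meas, sc$truth) < sc$voxel)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("axial binning uses half-open anchored bins and aggregates per axis", {
  m <- data.frame(
    x = 1:6, y = 1:6, z = 1:6,
    sigma_x = 1, sigma_y = 1, sigma_z = 1,
    fwhm_x = c(1, 2, 3, 4, 5, 6), fwhm_y = 2, fwhm_z = 3,
    amplitude = 10, offset = 0,
    z_position = c(0, 1, 4.9, 5, 9.9, 10), fit_ok = TRUE, flagged = FALSE)
  prof <- binByAxial(m, binWidth = 5, zMin = 0)
  expect_identical(prof$n_beads, c(3L, 2L, 1L))   # [0,5), [5,10), [10,15)
  expect_equal(prof$bin_center, c(2.5, 7.5, 12.5))
  expect_equal(prof$mean_fwhm_x, c(2, 4.5, 6))
  expect_equal(prof$sd_fwhm_x[1], sd(c(1, 2, 3)))
  # all beads in one bin: the profile is the plain sample mean
  one <- binByAxial(m, binWidth = 50, zMin = 0)
  expect_identical(nrow(one), 1L)
  expect_equal(one$mean_fwhm_x, mean(m$fwhm_x))
  # failed fits and empty input contribute nothing
  m$fit_ok <- FALSE
  expect_identical(nrow(binByAxial(m, 5)), 0L)
  expect_error(binByAxial(m, 0), "binWidth")
})

test_that("bead averaging aligns ROIs and improves SNR roughly as sqrt(n)", {
  set.seed(9)
  n <- 16
  centres <- cbind(sample(8:24, n, TRUE), sample(8:40, n, TRUE),
                   sample(8:40, n, TRUE))
  # keep beads apart so the ROIs do not overlap
  centres <- centres[!duplicated(centres %/% 6), , drop = FALSE]
  vol <- gaussVolume(c(32, 48, 48), centres, sigma = 1.5, amplitude = 500,
                     noiseSd = 20, seed = 10)
  meas <- measureBeads(vol, threshold = 200, minSeparation = 3,
                       window = c(7, 7, 7))
  meas <- meas[meas$fit_ok, , drop = FALSE]
  nb <- nrow(meas)
  expect_gte(nb, 5)
  avg <- averageBeadImage(vol, meas, nMax = nb, roi = c(7, 7, 7))
  one <- averageBeadImage(vol, meas, nMax = 1, roi = c(7, 7, 7))
  expect_identical(dim(avg), c(7L, 7L, 7L))
  # residual noise after averaging n identical beads shrinks ~ sqrt(n):
  # compare corner voxels (no signal) of the averaged vs single ROI
  corner <- function(a) c(a[1:2, 1:2, 1:2], a[6:7, 6:7, 6:7])
  ratio <- sd(corner(one)) / sd(corner(avg))
  expect_gt(ratio, sqrt(nb) * 0.45)
  expect_lt(ratio, sqrt(nb) * 2.2)
  # nMax = 1 returns the brightest bead's ROI untouched
  pb <- round((c(meas$z[which.max(meas$amplitude)],
                 meas$y[which.max(meas$amplitude)],
                 meas$x[which.max(meas$amplitude)]) - 0) / 0.5) + 1
  expect_equal(one, vol@data[(pb[1] - 3):(pb[1] + 3), (pb[2] - 3):(pb[2] + 3),
                             (pb[3] - 3):(pb[3] + 3)])
  # no usable beads is an error
  bad <- meas; bad$fit_ok <- FALSE
  expect_error(averageBeadImage(vol, bad, 5, c(7, 7, 7)), "no usable")
})
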