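## Bead-based PSF characterization: detection, per-axis Gaussian fits,
## FWHM-versus-depth profiles and averaged bead images.

#' Detect bead candidates in a volume
#'
#' Local maxima (26-neighbourhood) above a threshold, with non-maximum
#' suppression within a minimum separation (the brighter candidate wins;
#' ties break by lexicographic voxel order) and removal of candidates too
#' close to the volume border for a subsequent fit window.
#'
#' @param volume an \code{\link[=OPMVolume-class]{OPMVolume}}.
#' @param threshold absolute intensity threshold; default is the volume
#'   median plus five median absolute deviations.
#' @param minSeparation minimum centre-to-centre distance (micrometre)
#'   between accepted detections.
#' @param border per-axis margin in voxels (z, y, x); candidates closer to
#'   any face are dropped (set to half the fit window).
#' @return data.frame with voxel indices (\code{iz, iy, ix}, 1-based),
#'   sample coordinates (\code{x, y, z}, micrometre) and \code{intensity};
#'   zero rows when nothing is found.
#' @export
detectBeads <- function(volume, threshold = NULL, minSeparation = 1,
                        border = c(0, 0, 0)) {
  v <- volume@data
  d <- dim(v)
  empty <- data.frame(iz = integer(), iy = integer(), ix = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      intensity = numeric())
  if (any(d == 0) || all(v == v[1])) return(empty)
  if (is.null(threshold))
    threshold <- stats::median(v) + 5 * stats::mad(v)
  if (length(border) == 1L) border <- rep(border, 3L)
  ## neighbourhood maximum by shifting the array over the 26 offsets
  nmax <- array(-Inf, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
    tz <- sz + dz; ty <- sy + dy; tx <- sx + dx
    okz <- tz >= 1 & tz <= d[1]; oky <- ty >= 1 & ty <= d[2]
    okx <- tx >= 1 & tx <= d[3]
    nmax[sz[okz], sy[oky], sx[okx]] <-
      pmax(nmax[sz[okz], sy[oky], sx[okx]], v[tz[okz], ty[oky], tx[okx]])
  }
  cand <- which(v > threshold & v >= nmax, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  ints <- v[cand]
  ord <- order(-ints, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  ints <- ints[ord]
  ## physical coordinates for the separation test
  pos <- cbind(volume@origin[1] + (cand[, 1] - 1) * volume@voxelSize[1],
               volume@origin[2] + (cand[, 2] - 1) * volume@voxelSize[2],
               volume@origin[3] + (cand[, 3] - 1) * volume@voxelSize[3])
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sel <- which(keep)
    if (!length(sel)) { keep[i] <- TRUE; next }
    dd <- sqrt((pos[sel, 1] - pos[i, 1])^2 + (pos[sel, 2] - pos[i, 2])^2 +
                 (pos[sel, 3] - pos[i, 3])^2)
    keep[i] <- all(dd >= minSeparation)
  }
  cand <- cand[keep, , drop = FALSE]; ints <- ints[keep]
  pos <- pos[keep, , drop = FALSE]
  inb <- cand[, 1] > border[1] & cand[, 1] <= d[1] - border[1] &
    cand[, 2] > border[2] & cand[, 2] <= d[2] - border[2] &
    cand[, 3] > border[3] & cand[, 3] <= d[3] - border[3]
  cand <- cand[inb, , drop = FALSE]; ints <- ints[inb]
  pos <- pos[inb, , drop = FALSE]
  data.frame(iz = cand[, 1], iy = cand[, 2], ix = cand[, 3],
             x = pos[, 3], y = pos[, 2], z = pos[, 1], intensity = ints)
}

## 1-D Gaussian least-squares fit: amplitude, centre, sigma, offset.
## Returns list(ok, A, mu, sigma, b). t is in voxel units.
.fitGauss1d <- function(t, y) {
  b0 <- min(y)
  A0 <- max(y) - b0
  if (A0 <= 0) return(list(ok = FALSE, A = NA, mu = NA, sigma = NA, b = NA))
  ## saturated flat-top guard: a Gaussian peak has a single (or, between
  ## samples, paired) maximum; a clipped plateau repeats it
  if (mean(y >= max(y) - sqrt(.Machine$double.eps)) > 0.25)
    return(list(ok = FALSE, A = NA, mu = NA, sigma = NA, b = NA))
  w <- pmax(y - b0, 0)
  mu0 <- sum(t * w) / sum(w)
  s0 <- sqrt(max(sum((t - mu0)^2 * w) / sum(w), 0.1))
  lower <- c(A = A0 * 0.05, mu = min(t), sigma = 0.25, b = b0 - A0)
  upper <- c(A = A0 * 10, mu = max(t), sigma = diff(range(t)) + 1, b = b0 + A0)
  ## port can flag "false convergence" on noiseless profiles; quality is
  ## judged from the parameter bounds instead, so warnings are muted
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ b + A * exp(-(t - mu)^2 / (2 * sigma^2)),
                 start = list(A = A0, mu = mu0, sigma = s0, b = b0),
                 lower = lower, upper = upper, algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE, A = NA, mu = NA, sigma = NA, b = NA))
  p <- stats::coef(fit)
  atBound <- p["sigma"] <= lower["sigma"] + 1e-6 ||
    p["sigma"] >= upper["sigma"] - 1e-6
  list(ok = !atBound, A = unname(p["A"]), mu = unname(p["mu"]),
       sigma = unname(p["sigma"]), b = unname(p["b"]))
}

## Trilinear sample of a volume at fractional 1-based voxel indices
## (n x 3 matrix, axes z, y, x); points are clamped to the array.
.sampleVolume <- function(v, pts) {
  d <- dim(v)
  pts <- cbind(pmin(pmax(pts[, 1], 1), d[1]),
               pmin(pmax(pts[, 2], 1), d[2]),
               pmin(pmax(pts[, 3], 1), d[3]))
  p0 <- floor(pts)
  p0 <- cbind(pmin(p0[, 1], d[1] - 1), pmin(p0[, 2], d[2] - 1),
              pmin(p0[, 3], d[3] - 1))
  f <- pts - p0
  out <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wgt <- (if (dz) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dx) f[, 3] else 1 - f[, 3])
    out <- out + wgt * v[cbind(p0[, 1] + dz, p0[, 2] + dy, p0[, 3] + dx)]
  }
  out
}

#' Fit one bead with per-axis 1-D Gaussians
#'
#' Extracts single-voxel-wide intensity lines through the bead centre along
#' each axis and fits each with a four-parameter Gaussian (amplitude,
#' centre, sigma, offset) by least squares. Per-axis lines (not
#' projections) are used so that a tilted PSF does not mix axes; because a
#' line that misses the true centre of a tilted PSF returns a shifted
#' apparent centre, the three 1-D fits are iterated (lines resampled by
#' trilinear interpolation through the current centre estimate) until the
#' centre converges. FWHM is \code{2 sqrt(2 ln 2)} times sigma.
#'
#' @param volume an \code{\link[=OPMVolume-class]{OPMVolume}}.
#' @param position length-3 voxel index (iz, iy, ix, 1-based) of the bead,
#'   e.g. one row of \code{\link{detectBeads}}.
#' @param window odd voxel counts (z, y, x) of the fit window; must fit
#'   inside the volume around the bead.
#' @param maxIter centre-refinement iterations (default 4).
#' @return One-row data.frame: centroid (\code{x, y, z}, micrometre),
#'   per-axis \code{sigma_*} and \code{fwhm_*} (micrometre), \code{amplitude},
#'   \code{offset}, \code{z_position}, \code{fit_ok}, and \code{flagged}
#'   (TRUE when a fitted centre disagrees with the initial centroid by more
#'   than 2 voxels).
#' @export
fitBead <- function(volume, position, window = c(9, 9, 9), maxIter = 4L) {
  v <- volume@data
  d <- dim(v)
  if (length(window) == 1L) window <- rep(window, 3L)
  window <- as.integer(window)
  if (any(window %% 2L == 0L)) stop("'window' must be odd on every axis")
  h <- (window - 1L) %/% 2L
  p <- as.integer(position[1:3])
  if (any(p - h < 1L) || any(p + h > d))
    stop("fit window extends outside the volume")
  sub <- v[(p[1] - h[1]):(p[1] + h[1]), (p[2] - h[2]):(p[2] + h[2]),
           (p[3] - h[3]):(p[3] + h[3]), drop = FALSE]
  w <- pmax(sub - min(sub), 0)
  sw <- sum(w)
  ctr <- p - h - 1 + c(sum(slice.index(sub, 1) * w),
                       sum(slice.index(sub, 2) * w),
                       sum(slice.index(sub, 3) * w)) / sw
  ctr0 <- ctr
  fits <- NULL
  for (it in seq_len(maxIter)) {
    fits <- lapply(1:3, function(ax) {
      t <- seq(-h[ax], h[ax])
      pts <- matrix(ctr, length(t), 3, byrow = TRUE)
      pts[, ax] <- pts[, ax] + t
      .fitGauss1d(t, .sampleVolume(v, pts))
    })
    newCtr <- ctr
    for (ax in 1:3)
      if (fits[[ax]]$ok) newCtr[ax] <- ctr[ax] + fits[[ax]]$mu
    ## keep the line centre inside the fit window around the seed voxel
    newCtr <- pmin(pmax(newCtr, p - h), p + h)
    shift <- max(abs(newCtr - ctr))
    ctr <- newCtr
    if (shift < 1e-3) break
  }
  ok <- fits[[1]]$ok && fits[[2]]$ok && fits[[3]]$ok
  kF <- 2 * sqrt(2 * log(2))
  ctrUm <- volume@origin + (ctr - 1) * volume@voxelSize
  sig <- c(fits[[1]]$sigma, fits[[2]]$sigma, fits[[3]]$sigma) *
    volume@voxelSize
  flagged <- ok && any(abs(ctr - ctr0) > 2)
  data.frame(
    x = ctrUm[3], y = ctrUm[2], z = ctrUm[1],
    sigma_x = sig[3], sigma_y = sig[2], sigma_z = sig[1],
    fwhm_x = kF * sig[3], fwhm_y = kF * sig[2], fwhm_z = kF * sig[1],
    amplitude = mean(c(fits[[1]]$A, fits[[2]]$A, fits[[3]]$A)),
    offset = mean(c(fits[[1]]$b, fits[[2]]$b, fits[[3]]$b)),
    z_position = ctrUm[1], fit_ok = ok, flagged = isTRUE(flagged))
}

#' Detect and fit all beads in a volume
#'
#' Convenience wrapper: \code{\link{detectBeads}} with a border matched to
#' the fit window, then \code{\link{fitBead}} on every candidate.
#'
#' @inheritParams detectBeads
#' @param window odd per-axis fit window (voxels), passed to
#'   \code{\link{fitBead}}.
#' @return data.frame of bead measurements (one row per candidate).
#' @export
measureBeads <- function(volume, threshold = NULL, minSeparation = 1,
                         window = c(9, 9, 9)) {
  if (length(window) == 1L) window <- rep(window, 3L)
  cand <- detectBeads(volume, threshold, minSeparation,
                      border = (window - 1) %/% 2)
  out <- lapply(seq_len(nrow(cand)), function(i)
    fitBead(volume, c(cand$iz[i], cand$iy[i], cand$ix[i]), window))
  if (!length(out)) {
    nm <- c("x", "y", "z", "sigma_x", "sigma_y", "sigma_z",
            "fwhm_x", "fwhm_y", "fwhm_z", "amplitude", "offset",
            "z_position")
    empty <- as.data.frame(setNames(rep(list(numeric()), length(nm)), nm))
    empty$fit_ok <- logical(); empty$flagged <- logical()
    return(empty)
  }
  do.call(rbind, out)
}

#' Aggregate bead FWHMs versus axial position
#'
#' Half-open bins \code{[edge, edge + width)} anchored at the volume's (or
#' measurement set's) axial minimum; per-bin mean and standard deviation of
#' each FWHM axis.
#'
#' @param measurements data.frame from \code{\link{fitBead}} /
#'   \code{\link{measureBeads}}; rows with \code{fit_ok == FALSE} are
#'   ignored.
#' @param binWidth axial bin width (micrometre).
#' @param zMin bin anchor (micrometre); defaults to the minimum
#'   \code{z_position} of the measurements.
#' @return data.frame with \code{bin_center}, \code{bin_width},
#'   \code{n_beads} and \code{mean_fwhm_*} / \code{sd_fwhm_*} per axis;
#'   only nonempty bins are reported.
#' @export
binByAxial <- function(measurements, binWidth, zMin = NULL) {
  if (binWidth <= 0) stop("'binWidth' must be > 0")
  m <- measurements[measurements$fit_ok, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(bin_center = numeric(), bin_width = numeric(),
                      n_beads = integer(),
                      mean_fwhm_x = numeric(), sd_fwhm_x = numeric(),
                      mean_fwhm_y = numeric(), sd_fwhm_y = numeric(),
                      mean_fwhm_z = numeric(), sd_fwhm_z = numeric()))
  if (is.null(zMin)) zMin <- min(m$z_position)
  bin <- floor((m$z_position - zMin) / binWidth)
  agg <- function(v, f) as.numeric(tapply(v, bin, f))
  ctr <- zMin + (sort(unique(bin)) + 0.5) * binWidth
  data.frame(
    bin_center = ctr, bin_width = binWidth,
    n_beads = as.integer(tapply(m$z_position, bin, length)),
    mean_fwhm_x = agg(m$fwhm_x, mean), sd_fwhm_x = agg(m$fwhm_x, stats::sd),
    mean_fwhm_y = agg(m$fwhm_y, mean), sd_fwhm_y = agg(m$fwhm_y, stats::sd),
    mean_fwhm_z = agg(m$fwhm_z, mean), sd_fwhm_z = agg(m$fwhm_z, stats::sd))
}

#' Average image of the brightest beads
#'
#' Aligns each bead's region of interest on its (rounded) centroid voxel by
#' integer shifts and averages up to \code{nMax} of the brightest usable
#' beads; with \code{binWidth} given, one average per axial bin is returned
#' (emulating per-depth averaged bead images).
#'
#' @param volume an \code{\link[=OPMVolume-class]{OPMVolume}}.
#' @param measurements data.frame from \code{\link{measureBeads}}.
#' @param nMax maximum number of beads to average (>= 1).
#' @param roi odd per-axis ROI size in voxels (z, y, x).
#' @param binWidth optional axial bin width (micrometre).
#' @return A 3-D array (z, y, x), or a named list of arrays (one per bin)
#'   when \code{binWidth} is given.
#' @export
averageBeadImage <- function(volume, measurements, nMax = 50,
                             roi = c(9, 9, 9), binWidth = NULL) {
  if (nMax < 1) stop("'nMax' must be >= 1")
  if (length(roi) == 1L) roi <- rep(roi, 3L)
  roi <- as.integer(roi)
  if (any(roi %% 2L == 0L)) stop("'roi' must be odd on every axis")
  h <- (roi - 1L) %/% 2L
  d <- dim(volume@data)
  m <- measurements[measurements$fit_ok, , drop = FALSE]
  if (!nrow(m)) stop("no usable beads to average (all fits failed)")
  vox <- function(i) {
    c(round((m$z[i] - volume@origin[1]) / volume@voxelSize[1]) + 1,
      round((m$y[i] - volume@origin[2]) / volume@voxelSize[2]) + 1,
      round((m$x[i] - volume@origin[3]) / volume@voxelSize[3]) + 1)
  }
  inside <- vapply(seq_len(nrow(m)), function(i) {
    p <- vox(i); all(p - h >= 1) && all(p + h <= d)
  }, logical(1))
  m <- m[inside, , drop = FALSE]
  if (!nrow(m)) stop("no usable beads to average (all too close to border)")
  oneAverage <- function(rows) {
    rows <- rows[order(-m$amplitude[rows])]
    rows <- rows[seq_len(min(nMax, length(rows)))]
    acc <- array(0, roi)
    for (i in rows) {
      p <- vox(i)
      acc <- acc + volume@data[(p[1] - h[1]):(p[1] + h[1]),
                               (p[2] - h[2]):(p[2] + h[2]),
                               (p[3] - h[3]):(p[3] + h[3])]
    }
    acc / length(rows)
  }
  if (is.null(binWidth)) return(oneAverage(seq_len(nrow(m))))
  zMin <- min(m$z_position)
  bin <- floor((m$z_position - zMin) / binWidth)
  idx <- split(seq_len(nrow(m)), bin)
  out <- lapply(idx, oneAverage)
  names(out) <- sprintf("z=%.6g", zMin + (as.numeric(names(idx)) + 0.5) * binWidth)
  out
}
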