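## Affine unwarp of raw sheared stacks into Cartesian volumes.

#' Build the raw-index to sample-coordinate affine map
#'
#' Raw oblique stacks are sheared and anisotropically stretched: camera
#' columns sample x at \code{q = pixelPitch / M} per pixel, camera rows mix
#' the horizontal position and the depth of the oblique plane, and the
#' stage adds a per-frame horizontal shift. The unwarping map (0-based
#' indices k = frame, r = row, c = column) is
#' \deqn{x = c\,q,\quad y = \pm k\,s + r\,q,\quad z = r\,q/\tan\alpha.}
#'
#' @param stack a \code{\link[=RawStack-class]{RawStack}} (or anything with
#'   complete metadata slots).
#' @param voxelSize intended output grid spacing (micrometre); scalar or
#'   length 3 (z, y, x). Defaults to the isotropic native sampling
#'   \code{pixelPitch / M}.
#' @return An \code{\link[=AffineMap-class]{AffineMap}}.
#' @examples
#' geom <- obliqueGeometry(48, 55.56, 6.5, nRows = 16, nCols = 16)
#' bf <- generateBeadField(rbind(c(0, 1), c(0, 1), c(0, 1)), 0)
#' stk <- renderStack(bf, geom, ImagingModel(), 2, 0.4, noise = FALSE)
#' buildAffine(stk)
#' @export
buildAffine <- function(stack, voxelSize = NULL) {
  meta <- c(alpha = stack@alpha, magnification = stack@magnification,
            pixelPitch = stack@pixelPitch, stageStep = stack@stageStep,
            scanDirection = stack@scanDirection)
  bad <- names(meta)[!is.finite(meta)]
  if (stack@alpha <= 0 || stack@alpha > 90) bad <- union(bad, "alpha")
  if (length(bad))
    stop("incomplete or invalid stack metadata: ", paste(bad, collapse = ", "))
  q <- stack@pixelPitch / stack@magnification
  a <- .rad(stack@alpha)
  A <- rbind(x = c(k = 0, r = 0, c = q),
             y = c(stack@scanDirection * stack@stageStep, q, 0),
             z = c(0, q / tan(a), 0))
  if (is.null(voxelSize)) voxelSize <- q
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("AffineMap", matrix = A, offset = c(0, 0, 0),
      voxelSize = as.numeric(voxelSize))
}

#' Map raw indices to sample coordinates
#'
#' @param map an \code{\link[=AffineMap-class]{AffineMap}}.
#' @param idx numeric length-3 (k, r, c) 0-based raw index or n x 3 matrix.
#' @return n x 3 matrix of (x, y, z) sample coordinates (micrometre).
#' @export
mapRawToSample <- function(map, idx) {
  idx <- if (is.matrix(idx)) idx else matrix(idx, ncol = 3)
  out <- idx %*% t(map@matrix) +
    matrix(map@offset, nrow(idx), 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Deskew a raw stack into a Cartesian volume
#'
#' Resamples the raw (frame, row, column) stack onto a regular (z, y, x)
#' grid covering the image of the raw bounding box under the affine map.
#' The mapping is inverted and interpolation happens in the raw frame
#' (pull, not push), which leaves no holes; output voxels whose preimage
#' falls outside the raw stack are zero-filled and counted in
#' \code{missingFraction}. Voxel centres (not corners) carry coordinates.
#'
#' @param stack a \code{\link[=RawStack-class]{RawStack}}.
#' @param map an \code{\link[=AffineMap-class]{AffineMap}}; defaults to
#'   \code{buildAffine(stack)}.
#' @param interpolation \code{"linear"} (trilinear, default) or
#'   \code{"nearest"}.
#' @return An \code{\link[=OPMVolume-class]{OPMVolume}}.
#' @export
applyDeskew <- function(stack, map = NULL,
                        interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is.null(map)) map <- buildAffine(stack)
  Ainv <- tryCatch(solve(map@matrix), error = function(e)
    stop("affine map is not invertible: ", conditionMessage(e)))
  d <- dim(stack@frames)
  nk <- d[1]; nr <- d[2]; nc <- d[3]
  corners <- as.matrix(expand.grid(k = c(0, nk - 1), r = c(0, nr - 1),
                                   c = c(0, nc - 1)))
  cc <- mapRawToSample(map, corners)
  lo <- unname(apply(cc, 2, min))                    # x, y, z order
  hi <- unname(apply(cc, 2, max))
  vox <- unname(map@voxelSize)                       # z, y, x order
  nz <- as.integer(floor((hi[3] - lo[3]) / vox[1])) + 1L
  ny <- as.integer(floor((hi[2] - lo[2]) / vox[2])) + 1L
  nx <- as.integer(floor((hi[1] - lo[1]) / vox[3])) + 1L
  out <- array(0, c(nz, ny, nx))
  xg <- lo[1] + (seq_len(nx) - 1L) * vox[3]
  yg <- lo[2] + (seq_len(ny) - 1L) * vox[2]
  raw <- stack@frames
  nMissing <- 0
  ## z depends only on the row index and x only on the column index, but the
  ## inverse is applied in full generality; one z-slice at a time keeps the
  ## index arrays small.
  grid <- cbind(x = rep(xg, each = ny) - map@offset[1],
                y = rep(yg, times = nx) - map@offset[2])
  for (iz in seq_len(nz)) {
    zc <- lo[3] + (iz - 1L) * vox[1] - map@offset[3]
    kf <- Ainv[1, 1] * grid[, 1] + Ainv[1, 2] * grid[, 2] + Ainv[1, 3] * zc
    rf <- Ainv[2, 1] * grid[, 1] + Ainv[2, 2] * grid[, 2] + Ainv[2, 3] * zc
    cf <- Ainv[3, 1] * grid[, 1] + Ainv[3, 2] * grid[, 2] + Ainv[3, 3] * zc
    if (interpolation == "nearest") {
      ki <- round(kf); ri <- round(rf); ci <- round(cf)
      ok <- ki >= 0 & ki <= nk - 1 & ri >= 0 & ri <= nr - 1 &
        ci >= 0 & ci <= nc - 1
      vals <- numeric(length(kf))
      if (any(ok))
        vals[ok] <- raw[cbind(ki[ok] + 1L, ri[ok] + 1L, ci[ok] + 1L)]
    } else {
      ok <- kf >= 0 & kf <= nk - 1 & rf >= 0 & rf <= nr - 1 &
        cf >= 0 & cf <= nc - 1
      vals <- numeric(length(kf))
      if (any(ok)) {
        k0 <- floor(kf[ok]); r0 <- floor(rf[ok]); c0 <- floor(cf[ok])
        k1 <- pmin(k0 + 1, nk - 1); r1 <- pmin(r0 + 1, nr - 1)
        c1 <- pmin(c0 + 1, nc - 1)
        wk <- kf[ok] - k0; wr <- rf[ok] - r0; wc <- cf[ok] - c0
        vals[ok] <-
          raw[cbind(k0 + 1L, r0 + 1L, c0 + 1L)] * (1 - wk) * (1 - wr) * (1 - wc) +
          raw[cbind(k1 + 1L, r0 + 1L, c0 + 1L)] * wk * (1 - wr) * (1 - wc) +
          raw[cbind(k0 + 1L, r1 + 1L, c0 + 1L)] * (1 - wk) * wr * (1 - wc) +
          raw[cbind(k0 + 1L, r0 + 1L, c1 + 1L)] * (1 - wk) * (1 - wr) * wc +
          raw[cbind(k1 + 1L, r1 + 1L, c0 + 1L)] * wk * wr * (1 - wc) +
          raw[cbind(k1 + 1L, r0 + 1L, c1 + 1L)] * wk * (1 - wr) * wc +
          raw[cbind(k0 + 1L, r1 + 1L, c1 + 1L)] * (1 - wk) * wr * wc +
          raw[cbind(k1 + 1L, r1 + 1L, c1 + 1L)] * wk * wr * wc
      }
    }
    nMissing <- nMissing + sum(!ok)
    out[iz, , ] <- matrix(vals, ny, nx)
  }
  new("OPMVolume", data = out,
      origin = c(lo[3], lo[2], lo[1]), voxelSize = vox,
      missingFraction = nMissing / (as.numeric(nz) * ny * nx))
}
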