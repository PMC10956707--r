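# Closed-form design calculator: tilt angles, aperture matching,
# magnification, field of view, ETL focal range.

test_that("exact tilt angle matches direct evaluation and handles domain errors", {
  obj <- ObjectiveSpec(na = 1.1, fObj = 3, n = 1.33)
  # thin sheet: second term vanishes, arcsin(1.1/1.33)
  expect_equal(tiltAngleExact(obj), 55.79868, tolerance = 1e-6)
  expect_equal(tiltAngleExact(obj), asin(1.1 / 1.33) * 180 / pi,
               tolerance = 1e-12)
  # finite sheet aperture tilts the beam back by half its own half-angle
  ls <- LightSheetSpec(naLs = 0.198)
  expect_equal(tiltAngleExact(obj, ls), 51.51790, tolerance = 1e-6)
  # NA > n is unphysical: the arcsin argument leaves [-1, 1]
  bad <- obj
  bad@na <- 1.4   # bypasses construction-time validity on purpose
  expect_error(tiltAngleExact(bad), "arcsin")
})

test_that("exact tilt angle is monotone in both apertures", {
  nas <- seq(0.4, 1.2, by = 0.1)
  a <- vapply(nas, function(na)
    tiltAngleExact(ObjectiveSpec(na = na, fObj = 3)), numeric(1))
  expect_true(all(diff(a) > 0))
  naLss <- seq(0, 0.3, by = 0.05)
  obj <- ObjectiveSpec(na = 1.1, fObj = 3)
  b <- vapply(naLss, function(nl)
    tiltAngleExact(obj, LightSheetSpec(naLs = nl)), numeric(1))
  expect_true(all(diff(b) < 0))
})

test_that("paraxial tilt angle reproduces pupil-plane arithmetic", {
  obj <- ObjectiveSpec(na = 1.1, fObj = 3, bfpDiameter = 6.6)
  ls <- LightSheetSpec(apertureRatio = 0.18, objective = obj)
  expect_equal(ls@rLs, 0.594, tolerance = 1e-12)
  expect_equal(tiltAngleParaxial(obj, ls), 48.81885, tolerance = 1e-6)
  # degenerate endpoints of the arcsin argument
  objFull <- ObjectiveSpec(na = 1, fObj = 3, n = 1.33,
                           bfpDiameter = 2 * 3 * 1.33)
  expect_equal(tiltAngleParaxial(objFull), 90)
  objZero <- ObjectiveSpec(na = 1.1, fObj = 3, bfpDiameter = 6.6)
  lsAll <- LightSheetSpec(rLs = 6.6)
  expect_equal(tiltAngleParaxial(objZero, lsAll), 0)
  # the 0.18 aperture ratio reproduces the quoted 20 deg for the 20x pupil
  obj20 <- ObjectiveSpec(na = 0.5, fObj = 9)
  ls20 <- LightSheetSpec(apertureRatio = 0.18, objective = obj20)
  expect_equal(tiltAngleParaxial(obj20, ls20), 20.005, tolerance = 1e-4)
})

test_that("effective NA reflects pupil cropping by the ETL aperture", {
  rel <- RelaySpec(c(125, 300))
  etl <- ETLSpec(16)
  expect_equal(rel@mTel, 2.4)
  # 20x: 9 mm pupil vs 16/2.4 = 6.67 mm relayed ETL aperture
  expect_equal(effectiveNA(ObjectiveSpec(na = 0.5, fObj = 9), rel, etl),
               0.37037, tolerance = 1e-4)
  # 60x: 6.6 mm pupil fits inside the relayed aperture: no cropping
  obj60 <- ObjectiveSpec(na = 1.1, fObj = 3, bfpDiameter = 6.6)
  expect_identical(effectiveNA(obj60, rel, etl), 1.1)
  # infinite aperture never crops; cropping is idempotent and bounded
  expect_identical(effectiveNA(obj60, rel, ETLSpec(1e9)), 1.1)
  for (na in c(0.3, 0.8, 1.2)) {
    obj <- ObjectiveSpec(na = na, fObj = 5, n = 1.33)
    e1 <- effectiveNA(obj, rel, etl)
    obj2 <- obj; obj2@na <- e1
    obj2@bfpDiameter <- min(obj@bfpDiameter, etl@apertureDiameter / rel@mTel)
    expect_lte(e1, na)
    expect_equal(effectiveNA(obj2, rel, etl), e1, tolerance = 1e-12)
  }
})

test_that("chain magnification multiplies imaging/collimating focal ratios", {
  chain <- c(125, 300, 200, 100, 200)
  expect_equal(chainMagnification(chain, fObj = 3), 55.5556, tolerance = 1e-4)
  # identity 1:1 relay
  expect_equal(chainMagnification(7, fObj = 7), 1)
  # same chain behind the 9 mm objective (the value consistent with the
  # 720 um horizontal field of view; a nominal 16.66x is also in circulation)
  expect_equal(chainMagnification(chain, fObj = 9), 18.5185, tolerance = 1e-4)
  expect_error(chainMagnification(c(125, 300), fObj = 3), "pair")
  expect_error(chainMagnification(c(125, -300, 10), fObj = 3), "positive")
})

test_that("field of view follows the projection geometry", {
  cfg <- cfg60()
  g <- fieldOfView(cfg, alpha = 48.87)
  expect_equal(g@fovPerp, 2048 * 6.5 / cfg@totalMagnification,
               tolerance = 1e-12)
  expect_equal(g@fovPerp, 239.62, tolerance = 1e-4)
  expect_equal(g@fovAxial, 104.626, tolerance = 1e-4)
  # algebraic identities of the oblique projection
  a <- g@alpha * pi / 180
  expect_equal(g@fovAxial, g@fovPar * cos(a), tolerance = 1e-12)
  expect_equal(g@fovPar, g@fovPerp * (1024 / 2048) / sin(a),
               tolerance = 1e-12)
  expect_equal(g@pxPar, g@pxPerp / sin(a), tolerance = 1e-12)
  # vertical sheet: no axial extent
  g90 <- fieldOfView(cfg, alpha = 90)
  expect_equal(g90@fovAxial, 0, tolerance = 1e-9)
  expect_equal(g90@fovPar, g90@fovPerp * 1024 / 2048, tolerance = 1e-9)
  expect_error(fieldOfView(cfg, alpha = 0), "degenerate")
})

test_that("identities hold across random valid configurations", {
  set.seed(42)
  cfg <- cfg60()
  for (i in 1:25) {
    alpha <- runif(1, 5, 89)
    g <- fieldOfView(cfg, alpha)
    a <- alpha * pi / 180
    expect_equal(g@fovAxial, g@fovPar * cos(a), tolerance = 1e-12)
    expect_equal(g@fovPar,
                 g@fovPerp * (g@nRows / g@nCols) / sin(a),
                 tolerance = 1e-12)
  }
})

test_that("ETL focal requirement and power-to-defocus are mutual inverses", {
  expect_equal(requiredEtlFocal(2.4, 3, 104), 996.92, tolerance = 1e-4)
  # inverse proportionality in the axial range
  expect_equal(requiredEtlFocal(2.4, 3, 52), 2 * requiredEtlFocal(2.4, 3, 104),
               tolerance = 1e-12)
  expect_error(requiredEtlFocal(2.4, 3, 0), "fovAxial")
  # defocus law
  expect_identical(etlPowerToDefocus(0, 2.4, 3), 0)
  expect_equal(etlPowerToDefocus(1.003, 2.4, 3), 51.9955, tolerance = 1e-4)
  expect_equal(etlPowerToDefocus(2, 2.4, 3), 2 * etlPowerToDefocus(1, 2.4, 3),
               tolerance = 1e-12)
  # feeding the required power back recovers half the range per sign
  for (fov in c(10, 104, 958)) {
    ftl <- requiredEtlFocal(2.4, 3, fov)
    expect_equal(etlPowerToDefocus(1000 / ftl, 2.4, 3), fov / 2,
                 tolerance = 1e-12)
  }
})

test_that("tilt-angle report lists nominal, cropped and paraxial estimates", {
  rep20 <- tiltAngleReport(cfg20())
  expect_setequal(rep20$method,
                  c("exact_nominal", "exact_effective", "paraxial"))
  # cropping lowers the exact estimate; the paraxial pupil formula with the
  # 0.18 ratio lands at 20 deg
  ex <- rep20$alpha_deg[rep20$method == "exact_nominal"]
  exEff <- rep20$alpha_deg[rep20$method == "exact_effective"]
  expect_lt(exEff, ex)
  expect_equal(rep20$alpha_deg[rep20$method == "paraxial"], 20.0,
               tolerance = 0.01)
})
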