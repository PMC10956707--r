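---
title: "Remote-focusing oblique plane microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote-focusing oblique plane microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfopm)
```

## The imaging problem

Oblique plane microscopy (OPM) is a single-objective light-sheet technique:
excitation is confined to one edge of the objective pupil so that the sheet
propagates at an angle $\alpha$ from the optical axis, and fluorescence is
collected through the same lens. Because the illuminated plane is tilted,
only a narrow strip of it is in focus on a camera at any instant.
Conventional OPM re-images the tilted plane with a secondary/tertiary
objective pair, at the cost of a pupil mismatch that discards aperture. The
remote-focusing variant modelled here (RF-OPM) instead places an
electrically tunable lens (ETL) in a pupil-conjugate plane and ramps its
optical power linearly while the camera's rolling shutter sweeps the
detector: the in-focus strip travels with the exposed rows, so a full
in-focus image of the oblique plane is acquired without reprojection optics
and with the full objective aperture.

This package implements the computational side of the method at desk scale:
the design calculator, the synchronization model, a forward simulator of
raw acquisitions, the affine deskew, and the bead-based PSF
characterization pipeline. Everything a real instrument would contribute —
photons through glass — is replaced by an explicit forward model, so every
downstream claim can be checked against known ground truth.

## Design equations

For an objective of numerical aperture $\mathrm{NA}_{obj}$, immersion index
$n$ and a sheet of aperture $\mathrm{NA}_{ls}$, the tilt from the optical
axis is

$$\alpha = \arcsin\frac{\mathrm{NA}_{obj}}{n}
  - \frac{1}{2}\arcsin\frac{\mathrm{NA}_{ls}}{n},$$

with a paraxial pupil-plane form
$\alpha = \arcsin\!\big((D_{obj}-R_{ls})/(2fn)\big)$ in terms of the back
aperture diameter $D_{obj}$, the beam radius $R_{ls}$ and the focal length
$f$. The two disagree by a few degrees at high NA; `tiltAngleReport()`
reports both (plus the exact form at the ETL-cropped effective NA) rather
than privileging one.

With magnification $M$, detector side $D$ and tilt $\alpha$, the field of
view is $D/M$ across the sheet, $D/(M\sin\alpha)$ along the oblique plane
and $D/(M\tan\alpha)$ axially; per-axis pixel sizes follow the same
ratios, which is exactly the anisotropy the deskew must undo. The ETL must
reach $f_{tl} = 2M_{tel}^2 f_{obj}^2/\mathrm{FOV}_{axial}$ both converging
and diverging ($M_{tel}$ the pupil-relay magnification); the inverse
relation, $\Delta z = M_{tel}^2 f_{obj}^2 P$ micrometres per dioptre, is
the defocus law used by the synchronization model and the simulator.

```{r design}
cfg <- loadConfig(system.file("extdata", "config_60x.yaml", package = "rfopm"))
fieldOfView(cfg)
tiltAngleReport(cfg)
```

## Synchronization model

`rollingShutterSchedule()` gives each row's exposure start
($r \cdot$ line time, direction-adjusted); `makeWaveform()` lays an affine
power ramp over the active window so that each row's *mid-exposure* power
(mid-exposure, not start, so residual blur over a finite exposure is
symmetric) maps through the defocus law to that row's in-focus depth.
Sawtooth drive appends a dead flyback interval — duty cycle
$1 - t_{fly} f$ exactly — while triangular drive alternates slope with
duty 1 but requires a camera able to alternate its shutter direction.
The flyback default of 8 ms reproduces a 60% duty cycle at 50 Hz; the
quoted 90% at 10 Hz corresponds to 10 ms, and the two are simply different
operating points, both representable. Frame rates are limited by readout
plus exposure against the frame period; ETL secondary resonances (roughly
400 Hz in commercial lenses) are out of scope and appear only as the
advice not to drive faster.

## The forward model

Coordinates (used everywhere): $z$ along the optical axis into the sample,
$y$ the horizontal scan/propagation direction, $x$ perpendicular; detector
row 0 maps to the shallowest depth, and the sheet occupies
$y_{rel} = z\tan\alpha$ in stage-relative coordinates.

Each sub-diffraction bead renders as a separable Gaussian spot at its
horizontal camera projection. Three physically motivated factors shape it:

* **Sheet profile.** A Gaussian beam of waist $w_0$ and Rayleigh range
  $z_R$: across-sheet weight $\exp(-2d^2/w(s)^2)$ with
  $w(s) = w_0\sqrt{1+((s-s_f)/z_R)^2}$ and a $w_0/w$ amplitude factor.
  The axial FWHM parameter of `ImagingModel` sets the effective
  sheet+detection thickness.
* **Defocus.** The lateral width grows in quadrature with a slope per
  micrometre of mismatch between the bead depth and the row's in-focus
  depth, with amplitude scaled to conserve flux. Under ideal
  synchronization this mismatch is zero at the bead's own row — which is
  why the in-focus flux of a bead is invariant to its row position — but
  during a stage scan the off-sheet frames see a defocused, dimmer image.
  The realized axial response in the reconstructed volume is therefore the
  sheet profile multiplied by this detection envelope, and is somewhat
  narrower than the sheet alone.
* **Spherical aberration.** ETL remote focusing with high-NA objectives
  degrades away from the objective's native focal plane. No functional
  form is published, so it is modelled as an empirical width multiplier
  $1 + c_{sa}\,|z - z_{native}|$ applied to *both* the axial and the
  in-focus lateral widths. Applying it to the sheet term alone would let
  the unaffected detection envelope clip the response and suppress the
  very widening the term exists to emulate; treating it as a
  detection-path blur (which it physically is) makes the fitted axial
  FWHM grow monotonically away from the native plane, as observed with
  high-NA objectives, while $c_{sa}=0$ yields the flat profile seen at
  low NA.

Noise is Poisson on the photon-scale signal plus Gaussian read noise and a
constant offset, clipped to 16 bit and seeded for reproducibility. Spots
are rendered within a $\pm4\sigma$ support (truncation error below
$10^{-4}$ of peak). What the generator does **not** emulate: scattering,
sample-induced aberrations, ETL hysteresis, astigmatism from thick
dichroics, or index-mismatch effects — so a green round-trip test
establishes the correctness of the geometry, synchronization and analysis
code, not instrument performance.

## Deskew

Raw stacks index (frame $k$, row $r$, column $c$), and map to sample
coordinates as $x = cq$, $y = \pm ks + rq$, $z = rq/\tan\alpha$ with
$q = \text{pixel pitch}/M$ and $s$ the stage step. `applyDeskew()` inverts
this map and pulls (interpolates in the raw frame — no holes), with
trilinear interpolation by default and nearest-neighbour as the
conservative option; unfilled corner wedges are zero-filled and counted in
the volume metadata. Voxel centres carry coordinates, indices are 0-based
in the map, and the output voxel defaults to the isotropic native sampling
$q$ (the finest axis); anisotropic voxels are supported for coarse axial
PSFs where full sampling wastes memory.

## Bead characterization

Detection is 26-neighbourhood local maxima above a threshold (default:
volume median + 5 MAD — no detection criterion is published, so a robust
background statistic is used), with brighter-wins suppression inside a
minimum separation and a border margin for the fit window. Each bead is
fitted with three independent 1-D Gaussians (amplitude, centre, sigma,
offset) along single-voxel-wide lines through its centre — lines, not
projections, so a tilted PSF does not mix axes. Because a line that misses
the true centre of a tilted PSF returns a shifted apparent centre, the
three fits are iterated with trilinearly interpolated lines through the
current centre estimate; the iteration's fixed point is the true centre
for any Gaussian with $|\rho|<1$ and converges in 2–3 passes. FWHM is
$2\sqrt{2\ln 2}\,\sigma$ throughout. Saturated flat-top profiles (a
plateau of repeated maxima) are marked `fit_ok = FALSE`, as are fits at
their sigma bounds; centres that drift more than 2 voxels from the initial
centroid are flagged but kept. `binByAxial()` aggregates FWHM versus depth
in half-open bins anchored at the axial minimum, and
`averageBeadImage()` aligns and averages the brightest beads per bin.

## Numerical choices and limitations

* Angles cross API boundaries in degrees; focal lengths and apertures in
  mm, object-space distances in micrometre, ETL power in dioptre.
* The per-axis Gaussian fits use the `port` algorithm with moment-based
  starts and bounded sigma; convergence warnings on noiseless profiles are
  muted, and quality is judged from the bounds and the saturation guard.
* A pupil diameter default of $2\,\mathrm{NA}\,f$ and the 180 mm tube-lens
  standard ($f = 180/\text{nominal magnification}$) reproduce the printed
  55.55x chain; both can be overridden.
* The 20x configuration records a long-standing bookkeeping discrepancy:
  a nominal 16.66x effective magnification circulates for this lens chain,
  but the chain arithmetic gives 18.52x, which is also the value
  consistent with the 720 um horizontal field of view. The fixture uses
  18.52x and documents the other value.
* Bead fields are uniform in their bounding box; the sheet waist and
  Rayleigh range for the fixtures are chosen consistent with a sheet
  aperture of 0.18 of the objective's, as no measured values are
  published.
* The deskew is exact for the rigid acquisition geometry it models; it
  does not correct sample-induced warping, and no deconvolution or
  multi-view fusion is attempted.

## A desk-scale round trip

```{r roundtrip}
geom <- obliqueGeometry(alpha = 45, m = 16.67, pixelPitch = 6.5,
                        nRows = 64, nCols = 96)
model <- ImagingModel(lateralFwhmFocus = 1.0, axialFwhmFocus = 2.0,
                      sheetWaist = 1.0, rayleighRange = 40)
beads <- generateBeadField(rbind(x = c(5, 32), y = c(26, 55), z = c(3, 22)),
                           nBeads = 10, seed = 1)
stack <- renderStack(beads, geom, model, nFrames = 150, stageStep = 0.39,
                     seed = 2)
volume <- applyDeskew(stack)
meas <- measureBeads(volume, threshold = 200, minSeparation = 2)
truth <- beadPositions(beads)
err <- vapply(seq_len(nrow(meas)), function(i)
  min(sqrt((truth[, 1] - meas$x[i])^2 + (truth[, 2] - meas$y[i])^2 +
             (truth[, 3] - meas$z[i])^2)), numeric(1))
summary(err)   # localization error, micrometre (voxel = 0.39 um)
```

Sub-voxel localization of the generated beads after the full
simulate–deskew–measure chain is the package's core self-check; the same
loop at larger scale backs the acceptance tests.
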