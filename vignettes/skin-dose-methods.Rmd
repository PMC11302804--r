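---
title: "Methods: comparing in-vivo film skin dose with TPS calculations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing in-vivo film skin dose with TPS calculations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Photon dose calculation algorithms are least reliable at the air--tissue
interface, exactly where the radiosensitive basal layer of the epidermis
sits. In breast radiotherapy with tangential fields the lateral breast is a
beam entrance/exit surface and the inferior breast receives most of its
dose from lateral scatter, so the two regions stress a dose engine in
different ways. Convolution/superposition algorithms (AAA-type) scale dose
by electron density and tend to misestimate interface dose; deterministic
Boltzmann-transport solvers (AXB-type) handle the interface more directly.

`dermadose` implements the full measurement-to-report chain used to
quantify these effects when radiochromic film is placed between the skin
and a breast-support cradle during treatment:

1. skin structures on the CT grid (surface-voxel contour, interior rinds),
2. extraction and unfolding of the 3D surface dose into the film plane,
3. film processing (calibration, trimming, filtering, registration,
   fraction averaging),
4. statistics: DVH/D50%, pixel-wise dose differences with Gaussian fits
   and t-tests, and gamma-index pass rates.

Because the underlying patient data are private, the package ships a
synthetic mode with a known ground truth; every stage is validated against
that truth or against independent brute-force oracles.

## The synthetic phantom

The phantom is a water-equivalent half-cylinder (flat face down) resting
on a thin cradle shell whose plane is tilted 12 degrees about the
left--right axis, mirroring the clinical support-device geometry. In the
plane frame, `h` is height above the cradle and `w` runs along the plane
from the inferior edge of the contact region. Defaults:

| parameter | default | meaning |
|---|---|---|
| `breast_radius` | 3.4 cm | contact width = 2r = 6.8 cm |
| `breast_length` | 25 cm | unfolded contact length (11 lateral + 14 inferior) |
| `cradle_tilt` | 12 deg | plane tilt |
| `ct_spacing` | 0.12 x 0.12 x 0.25 cm | clinical CT resolution |
| `dose_grid_spacing` | 0.1 cm | TPS calculation lattice |
| `prescription` | 42.5 Gy / 16 fx | dose normalisation |

The defaults give a contact area of 6.8 x 25 = 170 cm^2, the film stencil
size. HU values are -1000 (air), 0 (tissue; no body HU is prescribed
anywhere, water-equivalence is the natural choice) and -700 (cradle, inside
the -800..-600 segmentation band). The phantom is generic and
parameterised, not claimed anatomical: there is no published breast size
distribution or cradle curvature to emulate, so the half-cylinder is the
simplest solid with a developable contact surface and a realistic tilt.

## The parametric dose model

The TPS engines themselves are out of scope; what the analysis needs is a
family of dose fields with controllable surface behaviour. Depth `d` below
the body surface is the anisotropic Euclidean distance transform of the
body mask (Felzenszwalb's separable algorithm in compiled code, since no
installed R package offers an anisotropic 3D EDT), and

```
D(d) = Rx * [S + (1 - S)(1 - exp(-d / lambda))]
          * [1 - sc * delta * exp(-d / lambda)]  (+ bias in the first layer)
```

with surface dose fraction `S`, buildup length `lambda`, and a scatter
deficit `delta` applied where `w` lies in the inferior segment (`sc = 1`).
Outside the body the depth is clamped to zero so the field carries the
surface value into the air margin; this avoids edge dilution when the dose
grid is sampled trilinearly at surface-voxel centres.

Default profiles (one shared buildup length of 0.4 cm, truth `S = 0.80`):

* `truth` -- what the film measures; no deficit.
* `aaa_like` -- `S` lowered by 0.04, deficit 4% on the inferior surface:
  underestimates the surface layer, worst on the scatter surface.
* `axb_like` -- `S` raised by 0.03, deficit 2.3%: a small overestimate,
  closest to measurement on the inferior surface.

These offsets were fixed once, from the magnitudes a film-versus-TPS
comparison of this design reports (surface-layer disagreement of a few
percent, rind-induced shifts of 2--8%); the package's tests assert only
the resulting *sign pattern* and orderings, never the magnitudes, which
remain configuration.

With `S = 0.80` and `lambda = 0.4` the D50% of the surface voxel layer
lands near 80% of prescription and rises by roughly 2% (0.2 cm rind) and
7--8% (0.5 cm rind) for the AAA-like profile -- the same order as clinical
experience, driven entirely by the buildup integral, not by tuning.

The 18-case cohort jitters the radius (5% relative SD), the truth surface
fraction (SD 0.05) and the buildup length (5% relative SD) per case, so
cohort SD columns exercise real between-case variance. One RNG stream per
case, seeded as `config_seed + 7919 * case_id`.

## Film simulation and processing

Simulated fractions are the truth surface dose plus a systematic offset
(default 0), a sinusoidal ridge artefact (default 2% amplitude, 0.5 cm
period, inferior region only -- emulating the reconstruction artefacts
that appear where the tilted cradle plane crosses CT slices), i.i.d.
Gaussian noise (default SD 7.5% of prescription), and a small random rigid
misalignment per fraction (SD 1.5 px translation, 0.75 degrees rotation).
Fractions are rendered through the calibration curve into 16-bit
green-channel scans and processed exactly as real scans would be.

Processing decisions the protocol leaves open, and what this package does:

* **Calibration form.** The one-scan protocol is named without a
  functional form; the rational response `X(D) = (a + bD)/(c + D)` is the
  standard choice for radiochromic film. It is fitted by an exact
  linearisation (`XD = a + bD - cX`) refined by Levenberg--Marquardt.
  Out-of-range responses are masked, never clipped: no dose is fabricated
  beyond the calibrated range.
* **Filter order.** A 5x5 adaptive local-mean/variance (Wiener-type)
  filter and a 5x5 median filter are both applied; the order is not
  specified by the protocol, so it is a configuration option
  (`denoise_order`), defaulting to Wiener-then-median. Both filters
  respect the validity mask: invalid pixels neither contribute to nor
  receive values, so constant regions are exact fixed points.
* **Trim.** The outer two pixels are removed by eroding the validity mask
  with a Chebyshev (square) margin, so stencil corners are treated like
  edges and the image border counts as boundary.
* **Registration.** "Rigid registration" is realised as rotation +
  translation (no scale) maximising normalised cross-correlation over the
  common valid region, with a coarse-to-fine pyramid (exhaustive integer
  search at the coarsest level, Nelder--Mead refinement per level). NCC is
  insensitive to the dose offsets under study, which is what makes
  registering a biased TPS map to film legitimate. The first processed
  fraction is the fixed reference for fractions; the mean film map is then
  registered once into the TPS frame (the unfolded maps of both algorithm
  profiles share one lattice), where the region labels are defined.

## Surface unfolding

The contact contour is chained per CT slice by greedy nearest-neighbour
traversal starting from the lateral (minimum-x) end -- the natural anchor
for this phantom, where each slice contour runs across the left-right
axis; the anchor choice and traversal direction are configurable. 2D
coordinates preserve consecutive 3D vector magnitudes exactly:

* `u` (along contour) = cumulative 3D arc length from the slice anchor,
* `v` (across slices) = cumulative 3D anchor-to-anchor distance, starting
  at the most superior slice.

For developable surfaces (plane, cylinder sector, the tilted cradle) this
is an isometry to machine precision, which the tests assert at 1e-9 cm.
For non-developable input the mapping still runs but reports a distortion
summary (2D vs 3D distances of across-slice neighbours) instead of
silently dropping the discrepancy. Gaps larger than one voxel diagonal
along a chain are an error, not an interpolation.

Rasterisation to the 72 DPI film lattice uses separable linear
interpolation: along `u` within each slice, then along `v` across slices
at every raster column. With per-slice samples this is exact for fields
linear in `(u, v)` and avoids a triangulation dependency; pixels outside
the sampled support are invalidated. Provenance (pixel to source voxel)
is retained so every raster value can be traced back to a 3D point.

## DVH conventions

DVHs use trilinear dose sampling at structure voxel centres with equal
voxel weighting (no partial-volume subdivision -- the analysis is
explicitly voxel-level) and 0.5% bins. `Dx%` follows the hottest-x%
convention resolved at the bin width: the largest dose edge at which the
cumulative fraction still reaches `x/100`. This makes the uniform-dose
case exact and agrees with the order-statistic quantile to within one bin
width; a crossing interpolation between bin edges would instead bias the
uniform case by half a bin. Commercial DVH bin widths and interpolation
are not public, so no equivalence to any vendor implementation is
claimed.

## Gamma analysis

The gamma index uses global normalisation (maps are already percent of
prescription), 0.5 cm DTA, 7% or 10% dose tolerance, no low-dose
threshold by default, the evaluated map upsampled 3x by bilinear
interpolation, and the spatial search truncated at 3 x DTA. The compiled
implementation visits candidate positions in order of increasing distance
and stops when the pure distance term exceeds the current minimum; the
test suite holds it to within 1e-6 of an exhaustive full-scan oracle on
the same convention, and verifies the closed forms (identical maps give
gamma 0; a uniform 7% offset at 7% tolerance gives gamma exactly 1) and
tolerance monotonicity. Reference pixels whose entire search
neighbourhood is invalid are excluded from pass-rate denominators. Local
normalisation is deliberately a stub that errors.

## Dose-difference statistics

Differences are calculated-minus-measured on the intersected valid masks,
pooled over cases into 1%-wide bins centred on integers. The Gaussian
`A exp(-(x - mu)^2 / (2 sigma^2))` is fitted to bin counts (R^2 is
computed against counts, consistent with what is fitted) by
Levenberg--Marquardt initialised from the count-weighted moments.

Whether the between-algorithm t-test in this kind of analysis is run on
pooled pixels or per-case summaries is usually not stated; pooled pixels
are spatially autocorrelated and inflate n. Both variants are exposed and
reported: `per_case_paired` (the conservative default) and `pooled_welch`
(the literal pixel-pool reading). A mixed-effects model would be better
still and is noted as out of scope.

## What the generator does and does not emulate

Emulated: the tilted-cradle contact geometry and its 170 cm^2 stencil,
clinical CT and dose-grid resolutions, surface buildup with
algorithm-specific surface bias and scatter-surface deficits, film noise
with a systematic offset and inferior ridge artefacts, per-fraction
misalignment, and between-case anatomical variation.

Not emulated: real anatomy (skin folds, variable curvature), beam
modelling of any kind, spatially *correlated* film noise, scanner lateral
response, and film darkening kinetics. The white-noise film model has one
visible consequence: 5x5 filtering plus 3-fraction averaging suppresses
white noise far more effectively than it suppresses the structured
residuals of real film, so the cohort's dose-difference SDs (1--2%) are
narrower than the 7--11% a clinical comparison reports, and gamma pass
rates are correspondingly optimistic. Passing tests therefore demonstrate
correctness of the machinery, not clinical error magnitudes. A related
effect: the pooled full-region histogram is a mixture of two regional
means, so its Gaussian R^2 falls below the per-region fits when the
regional separation exceeds the residual spread.

## Numerical choices and degenerate inputs

* Distance comparisons against thresholds use a 1e-9 cm slack so voxels
  exactly on a rind boundary are included deterministically; HU bands are
  inclusive at both ends for the same reason.
* The body/cradle "Boolean AND" is realised as body AND (cradle dilated
  by one voxel): the literal intersection of disjoint masks would be
  empty. Face adjacency (6-connectivity) keeps the contact contour one
  voxel thick along the surface normal; 26-connectivity is available for
  masks that only touch diagonally.
* Published body-segmentation HU bands are occasionally quoted inverted
  (an air-only band); `validate_config()` flags any band lying entirely
  below -950 HU as a warning. The body threshold defaults to HU >= -300
  with largest-connected-component filtering and makes no guess at any
  particular clinic's value.
* Empty contact surfaces, empty masks, non-monotone calibration data,
  degenerate (single-slice or zero-area) unfolded point sets and
  registration without usable overlap raise errors with diagnostics.
* Rinds are restricted to the contact region's plane footprint by default
  (`restrict_rind_to_footprint`), since the skin structures under study
  are those of the contact region; the flag disables it.

## Problem sizes

The test suite runs the full 18-case cohort for the DVH ordering check,
a 4-case cohort for the end-to-end film comparison (the sign pattern is a
property of the documented profiles, not of the case count), 50 seeded
32x32 map pairs for gamma oracle equivalence, and 1e5-voxel DVHs; unit
tests use a reduced phantom (1.2 cm radius, 6 cm length) that preserves
every geometric feature. The acceptance script runs the full 18-case
cohort at study resolutions end to end.

## Known limitations

* The unfolding assumes per-slice contours that chain into a single open
  curve; closed contours (full cylinders) would need a cut convention.
* The per-slice arc-length construction defines "preserving vector
  magnitude and angle" for developable surfaces only; on doubly curved
  surfaces it reports distortion rather than minimising it (no LSCM-style
  parameterisation, by design).
* DICOM-RT I/O is not provided in this R implementation; grids, masks and
  maps persist as CSV/JSON text containers and TIFF. The synthetic mode
  is self-contained, and the module boundaries accept in-memory objects
  so a DICOM front-end could be added without touching the analysis.
* Real-scan mode expects maps already co-registered to within the
  capture range of the NCC pyramid (about 1 cm / 6 degrees by default).
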