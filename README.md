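# dermadose

Quantitative comparison of **in-vivo radiochromic film measurements of
breast skin dose** against **treatment-planning-system (TPS) dose
calculations**, as an R package plus a scripted analysis workflow.

## The problem

The epidermal basal layer (~0.007 cm deep) drives acute skin toxicity in
breast radiotherapy, but it sits at the air–tissue interface where photon
dose engines are least trustworthy and where the finest TPS lattice
(0.1 cm) cannot resolve it. When film is placed between the skin and a
tilted breast-support cradle during treatment, the measured 2D dose can be
compared with the calculated dose on the skin — if the 3D surface dose can
be extracted, flattened into the film plane, registered, and analysed
consistently. That chain is what this package implements:

* **Skin structures** on the CT voxel grid: HU thresholding, an extended
  body contour, the body–cradle *surface voxel contour* (contact layer),
  and 0.2 / 0.5 cm interior skin rinds built with an anisotropic Euclidean
  distance transform.
* **Surface unfolding**: per-slice arc-length flattening of the contact
  surface that preserves consecutive 3D vector magnitudes (an isometry on
  developable surfaces), then linear interpolation onto the 72 DPI film
  lattice.
* **Film processing**: rational green-channel calibration
  `X(D) = (a + bD)/(c + D)`, 2-pixel edge trim, 5×5 adaptive (Wiener-type)
  and median filtering, NCC-based rigid registration, 3-fraction
  averaging.
* **Statistics**: cumulative DVHs with D50% (hottest-half convention),
  pixel-wise calculated−measured differences pooled into 1% histograms
  with Gaussian fits and t-tests, and 2D gamma analysis at 0.5 cm DTA
  with 7% / 10% tolerances, reported for the full, lateral (upper 11 cm)
  and inferior (lower 14 cm) film regions.
* **Synthetic mode** (default and fully tested): a breast-on-cradle
  phantom at clinical CT/dose resolutions with parametric buildup dose
  profiles (`truth`, `aaa_like`, `axb_like`) and a film noise model, so
  the whole pipeline runs against a known ground truth.

The core dose model per profile is
`D(d) = Rx·[S + (1−S)(1−e^{−d/λ})]·[1 − sc·δ·e^{−d/λ}]`, with depth `d`
below the body surface, surface dose fraction `S`, buildup length `λ` and
a scatter-surface deficit `δ` on the inferior region. The gamma index is
`γ(r) = min_e sqrt(‖e−r‖²/DTA² + (D_e(e)−D_r(r))²/ΔD²)` with the
evaluated map upsampled ×3 and verified against an exhaustive brute-force
oracle.

## Worked example

A reduced two-case cohort (small phantom, default profiles):

```r
library(dermadose)
cfg <- run_config(n_cases = 2, seed = 42,
  phantom = list(breast_radius = 1.2, breast_length = 6,
                 lateral_extent = 2.5, inferior_extent = 3.5,
                 dose_grid_spacing = 0.15),
  extended_body_cm = 0.5,
  registration = list(max_shift = 0.3, max_rotation = 3))
bundle <- run_pipeline(cfg)
print(bundle$table1, row.names = FALSE, digits = 3)
```

```
 statistic aaa_like_surface aaa_like_rind02 aaa_like_rind05 axb_like_surface
      mean            82.25           83.50           86.50            88.00
        sd             1.77            2.12            1.41             2.12
 axb_like_rind02 axb_like_rind05
           89.00           91.00
            2.12            1.41
```

D50% (percent of prescription) rises with rind thickness for both
algorithm profiles — thicker rinds sample deeper into the buildup region.
The difference table shows the sign pattern of the two engines: the
AAA-like profile *underestimates* the measured surface dose (most on the
inferior, scatter-dominated surface), the AXB-like profile slightly
*overestimates* it:

```
          row aaa_like_surface aaa_like_rind02 aaa_like_rind05 axb_like_surface ...
 tps_increase             0.00            1.25           4.250            0.000
         full            -4.49           -3.24          -0.235            1.426
      lateral            -3.08           -1.83           1.171            2.103
     inferior            -5.44           -4.19          -1.194            0.696
```

(`full` row: Gaussian-fit mean of the pooled calculated−measured pixels,
−4.49% for AAA-like vs +1.43% for AXB-like; rind columns add the D50%
shift of that rind.) `bundle$table3` holds the gamma pass rates and
`plot_dose_difference_histograms(bundle)` draws the six-panel histogram
figure.

The numbered scripts under `analysis/` run the same workflow at full
study scale (18 cases, 0.1 cm dose grid, 170 cm² contact region) and
write their tables under `results/`:
`01_simulate_cohort.R → 02_skin_structure_dvh.R → 03_film_vs_tps.R →
04_gamma_analysis.R`.

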