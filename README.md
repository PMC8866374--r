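# sarcnet

Quantitative, standardised evaluation of sarcomere network maturation in
striated cells — iPSC-derived and primary cardiomyocytes, skeletal muscle
cells — from super-resolution images of the α-actinin channel.

Contractile maturity shows up in the z-disc lattice: mature cardiomyocytes
have dense, regularly spaced z-lines aligned perpendicular to the cell's
long axis, while immature iPSC-CMs have sparse, disordered filaments.
`sarcnet` turns one image + cell outline into a tidy row of the metrics
used to grade that maturation, and provides the cohort statistics and a
ground-truthed synthetic image generator to validate every estimator.

Per cell it computes:

* **Shape** — area, perimeter, aspect ratio (moment-fitted ellipse),
  circularity `4πA/P²`, roundness `4A/(π·major²)`, long-axis orientation.
* **Sarcomere density** — percent of cell area covered by the detected
  z-line footprint, classified low (< 20 %), medium (20–30 %), high
  (> 30 %). Z-lines are detected by a Steger-style curvilinear ridge
  detector (Gaussian-derivative Hessian eigen-analysis, sub-pixel
  zero-crossing, hysteresis linking) with local width estimation.
* **Orientation** — structure-tensor orientation field; histogram of the
  relative angle δ to the cell axis; axial circular mean θ̄ ∈ [0°, 90°]
  ("main direction"; 90° = perpendicular, the mature configuration);
  fractions in 0–30°, 30–60°, 60–90°; colour-coded orientation maps.
* **Sarcomere length** — mean of 20 adjacent intensity-peak spacings along
  the myofibril axis (plausibility window 1–3 µm).
* **Z-disc thickness** — mean width of the 50 strongest filaments.
* **Calcium kinetics** — CD50, T50on, T50off and decay constant τ of a
  single fluorescence transient (ms; 83 fps-style sampling supported).

Group comparison uses one-way ANOVA with Bonferroni or Dunnett post hoc
tests for linear metrics and the Watson–Williams F test — the circular
analogue of ANOVA, on doubled (axial) angles with the `K = 1 + 3/(8κ̂)`
correction — for the main direction.

## Worked example

Everything below is runnable without any microscopy data: the synthetic
generator renders a striated cell with recorded ground truth.

```r
library(sarcnet)

# an adult-like rod cell: 40 x 12 um, z-disc spacing 1.90 um, orientation
# von Mises(mu = 86.08 deg, kappa = 8) about the long axis, 30% coverage,
# 0.05 um/px, SNR 5
spec <- synthetic_spec(shape = "rod", cell_length_um = 40,
                       cell_width_um = 12, spacing_um = 1.90,
                       orient_mu_deg = 86.08, orient_kappa = 8,
                       target_coverage_pct = 30, pixel_size_um = 0.05,
                       seed = 1)
out <- render_sarcomere_image(spec)
out$truth$realized_coverage_pct
#> [1] 30.00063

row <- analyze_cell(out$image, out$truth$mask)
dplyr::glimpse(dplyr::select(row, aspect_ratio, density_pct,
                             density_category, main_direction_deg,
                             frac_60_90, sarcomere_length_um,
                             zdisc_width_um))
#> Rows: 1
#> Columns: 7
#> $ aspect_ratio        <dbl> 3.327347
#> $ density_pct         <dbl> 29.58856
#> $ density_category    <chr> "medium"
#> $ main_direction_deg  <dbl> 83.73808
#> $ frac_60_90          <dbl> 0.9915283
#> $ sarcomere_length_um <dbl> 1.865534
#> $ zdisc_width_um      <dbl> 0.2607048
```

Reading the row: the detected z-line footprint covers 29.6 % of the cell
against a ground truth of 30.0 % (which sits exactly on the medium/high
category boundary); the main filament direction is 83.7° — close to
perpendicular, as generated (this seed's sample truth is 84.3°) — with
99 % of orientation mass in the mature 60–90° band; the mean of 20
peak-to-peak spacings is 1.87 µm against a generated spacing of 1.90 µm
(the 10-seed cohort mean is 1.92 µm); and the z-disc thickness 0.261 µm
matches the PSF-broadened rendered width (2·σ_eff = 0.233 µm) within the
estimator's tolerance.

Cohorts chain the same verbs:

```r
report <- analyze_cells(cells_tbl)        # one tidy row per cell
summary <- compare_groups(report, control = "stanCon")
glance(summary$circular)                  # Watson-Williams on theta-bar
autoplot(hist, rose = TRUE)               # rose diagram of delta
```

A thin command-line wrapper (`inst/cli/sarcnet.R`) exposes `analyze`,
`simulate`, `compare` and `calcium` subcommands over the same functions.

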