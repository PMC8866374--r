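---
title: "Quantifying sarcomere network maturation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcomere network maturation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiomyocytes differentiated from induced pluripotent stem cells
(iPSC-CMs) are structurally immature: their sarcomeres are shorter,
sparser, and less aligned than in adult heart cells. Protocols that push
maturation (longer culture, micropatterned surfaces, thyroid hormone) are
judged by how much they improve the sarcomere network, so a standardised,
quantitative readout of that network is the tool this package provides. The
input is a super-resolution image of the α-actinin channel (z-discs appear
as bright transverse lines) together with a cell outline and the physical
pixel size; the output is a tidy per-cell row of structural metrics, plus
cohort-level statistics, and — because real reference data cannot ship with
the package — a fully seeded synthetic generator that renders striated
cells with known ground truth so that every estimator is testable.

`sarcnet` computes, per cell:

* **shape descriptors** — area, perimeter, aspect ratio, circularity
  `4πA/P²`, roundness `4A/(π·major²)`, and the long-axis orientation;
* **sarcomere density** — the percentage of the cell area covered by the
  detected z-line footprint, with the three-class categorisation
  (low < 20 %, medium 20–30 %, high > 30 %);
* **orientation statistics** — the distribution of filament orientation
  relative to the cell's long axis, its axial circular mean ("main
  direction", 90° = perpendicular, the mature configuration), interval
  fractions (0–30°, 30–60°, 60–90°), and the Watson–Williams test across
  groups;
* **sarcomere length** — mean spacing of adjacent intensity peaks along the
  myofibril axis (protocol: 20 spacings per cell);
* **z-disc thickness** — mean local line width of the 50 strongest
  detected filaments;
* **calcium kinetics** — CD50, T50on, T50off and the exponential decay
  constant τ of a single fluorescence transient.

## Ridge detection (Steger's method)

Z-discs are bright curvilinear structures, so the detector follows
Steger's classic construction. The image is convolved with Gaussian
derivative kernels at scale σ; at each pixel the Hessian is
eigen-decomposed and the eigenvector **n** of the most negative eigenvalue
is the direction across the line. The first directional derivative along
**n** vanishes at

$$t = -\frac{r_x n_x + r_y n_y}{r_{xx} n_x^2 + 2 r_{xy} n_x n_y + r_{yy} n_y^2},$$

and the pixel contributes a centreline point at `p + t·n` when
`|t·n| ≤ 0.5` px in both coordinates, giving sub-pixel centrelines with
local tangents. The ridge response is `−λ_min`; candidate points are linked
by hysteresis (8-connected components that contain at least one strong
point) and ordered into polylines by walking the chain, restarting at
branches so that junctions split rather than being resolved.

Parameters and defaults, all configurable through `sarcnet_config()`:

* `sigma_px` — detection scale. A line of full width `w` px needs
  `σ ≥ w/(2√3)`; the default is `max(1, w/(2√3) + 0.3)` with `w` taken
  from `expected_zdisc_width_um` (default 0.25 µm, a PSF-broadened z-disc).
* Hysteresis thresholds — quantile-based so they adapt to image contrast:
  `upper = 0.5 × (95th percentile of the in-mask response)`,
  `lower = upper/2`. The lower ratio was validated on the generator:
  in dense networks, weak *phantom* ridges form between close parallel
  z-lines of overlapping myofibrils and touch genuine lines, so a more
  permissive lower threshold lets them survive hysteresis and inflates the
  density footprint by several percentage points. The quantile rule is
  additionally guarded by a noise ceiling: the image noise level is
  estimated as the robust MAD of a 1-px high-pass residual over the mask
  and converted to ridge-response units with a fixed unit-noise
  calibration at the detection scale; `upper` never drops below six times
  that level. Without the guard, sparse networks (≲ 15 % coverage) put
  the 95th response percentile inside the noise, and hysteresis keeps
  noise blobs.
* `min_length_um` (default 0.5 µm) — discards fragments, balancing the
  loss of real fragments created by junction splitting (dense, highly
  aligned networks) against crossing artefacts (dispersed networks);
  chosen from generator validation across both regimes.

**Width estimation.** At every centreline point the gradient magnitude is
sampled along the unit normal on both sides (up to `max_width_um`, default
0.8 µm). The edge on each side is the *first* interior local maximum
reaching at least half the in-range peak — taking the global maximum
instead latches onto the stronger edges of neighbouring structures. Two
numerical details matter. First, the gradient field is computed on a 2×
bicubically supersampled grid: the gradient peak spans only ~2 samples at
native resolution and any interpolated extremum is biased by ~0.1 px.
Second, the measuring kernel blurs the profile it measures: for a Gaussian
profile of scale σ_line, the gradient extremum sits at
`√(σ_line² + σ_g²)`, so each side is corrected by quadrature subtraction
of the gradient scale σ_g. After correction the width of an isolated
Gaussian line converges to the analytic edge-to-edge value `2σ_line`.
Widths below 1 px are unresolvable and flagged 0. No asymmetric-contrast
bias correction is applied; widths are geometric edge-to-edge distances.

**Density footprint.** The binary image that density is defined on uses
the `width` mode of `ridge_footprint()`: every pixel whose centre lies
within half the estimated width of a centreline (exact sub-pixel
positions; rounding to the grid first would widen the tube by up to half
a pixel). Each ridge is stamped at its *median* valid width — a z-disc
has near-constant width along its length, and local estimates at
crossings capture the crossing structure's edges. Ridges up to twice the
cell-wide median keep their own width, because two unresolvably close
parallel z-lines merge into one ridge whose outer-edge width is the union
of both tubes; anything wider is clamped. A 1-px `skeleton` mode exists
for comparison; it cannot reproduce published density levels (~23–32 %),
which is why the width mode is the default.

## Orientation analysis

The dense orientation source is the structure tensor
`J = G_ρ * (∇I ∇Iᵀ)` with differentiation scale 1 px and integration scale
`tensor_sigma_um` (default 0.25 µm). The line orientation is perpendicular
to the dominant gradient direction,
`θ = 0.5·atan2(2J_xy, J_xx − J_yy) + 90°`; `energy = trace(J)` and
`coherence = (λ₁−λ₂)/(λ₁+λ₂)` grade how structured and how anisotropic
each pixel is. Histograms of the relative angle `δ = fold(θ − axis)` over
(−90°, 90°] are weighted by `energy × coherence`, which suppresses
background without a segmentation step; a pure-count mode and a
length-weighted ridge-tangent source exist as cross-checks (which
weighting the original plugins used is not documented, so both are
exposed).

All orientation statistics are **axial**: filaments are undirected, so
angles are doubled before averaging or testing and halved afterwards.
Without doubling, a tight population straddling ±90° would appear bimodal
and its mean would be meaningless. The main direction is reported as
`|δ̄| ∈ [0°, 90°]`; when the doubled-angle resultant length drops below
0.05 the mean is unstable and the result is flagged `dispersed`.

The cell axis comes from the mask's second central moments (with the
per-pixel 1/12 correction, so analytic shapes are matched exactly). For
near-circular cells (aspect ratio < 1.05) the axis direction is
numerically unstable; it is still computed but flagged
`axis_unreliable` — the package does not guess a better convention because
none exists for round cells.

## Sarcomere length

At the strongest detected ridge points (deterministic response rank,
sites kept ≥ 1 µm apart so the 20 spacings probe different regions), an
intensity profile 6 µm long is cast along the local myofibril axis
(perpendicular to the z-line tangent), sampled bicubically at 0.25-px
steps. Peaks need a topographic prominence of ≥ 20 % of the profile's
dynamic range and ≥ 1 µm separation; positions are refined parabolically.
Only the two spacings flanking the central peak (the profiled z-line
itself) are candidates — they are the distances to the *neighbouring*
filaments — and they are accepted only when both lie in the plausibility
window 1.0–3.0 µm *and* agree within 15 %: the sarcomere lattice is
locally periodic, so mismatched flanks indicate an interloping structure
(typically a crossing myofibril), which would otherwise bias the mean.
The window brackets published z-disc spacings (1.75–2.3 µm) with margin
against harmonics and missed peaks. Cells with fewer than 3 accepted
spacings report what exists plus an `unreliable` flag.

## Circular statistics

`watson_williams()` is the circular one-way ANOVA on doubled angles: with
group resultant lengths `R_i`, pooled resultant `R`, and `N = Σn_i`,

$$F = K \cdot \frac{(N - r)(\sum R_i - R)}{(r - 1)(N - \sum R_i)},
\qquad K = 1 + \frac{3}{8\hat\kappa},$$

where `κ̂` inverts `A(κ) = I₁(κ)/I₀(κ)` at the weighted mean resultant
length by Newton iteration (Banerjee-style start, tolerance 1e-10,
asymptotic series above κ = 1000). p-values come from the upper tail of
`F(r−1, N−r)`. The test assumes concentrated samples; below a pooled mean
resultant length of 0.45 the result is returned with
`assumption_ok = FALSE` rather than refused. Groups with zero angular
dispersion make the statistic diverge and are an explicit error. Group
sizes below 3 are refused and below 10 warned about.

## Calcium kinetics

With the trace normalised to `g = (f − F0)/A` (baseline `F0` = mean of
pre-peak samples below 10 % of prominence), all threshold crossings are
located by linear interpolation between samples. CD50 is the time between
the first 0.5 up-crossing and the last 0.5 down-crossing; T50on runs from
the transient onset (last 5 % up-crossing before the peak — CalTrack-style
tools do not publish their exact definition, so this one is ours and
configurable) to the 0.5 up-crossing; T50off from the peak to the 0.5
down-crossing. τ is fitted from the peak to the end of the trace
(`F0 + A'·exp(−(t−t_p)/τ)`, baseline fixed, started at `T50off/ln 2`);
fitting from the peak rather than from 90 % decay maximises the number of
points at 83 fps. If several samples tie at the maximum (a degenerate,
square-pulse-like trace), upstroke metrics reference the first and decay
metrics the last such sample. Times are milliseconds throughout; 83 fps
gives dt ≈ 12.05 ms. Single-transient traces only — pacing-train
segmentation is the caller's responsibility.

The synthetic transient is `g(t) = (1 − e^{−t/τ_r})·e^{−t/τ_d}` normalised
to peak 1; its ground truth is measured on a 1000×-finer grid of the
noiseless closed form (`transient_truth()`), and `tune_transient()`
bisects one constant until a chosen oracle metric hits a prescribed value.
In the truth record `tau_ms` is the model's asymptotic decay constant τ_d;
a fit over the full decay differs by a few percent because the rise term
lingers past the peak, so τ accuracy is asserted on pure-exponential
segments.

## The synthetic generator

`render_sarcomere_image()` emulates the α-actinin channel: a cell
silhouette (rounded-rectangle rod or radial-Fourier blob), myofibril
bundles placed at seeded anchors inside the mask, each bundle drawing one
relative orientation from an axial von Mises distribution (sampled as
`δ = φ/2`, `φ ~ VM(2μ, κ)`) and laying 3–8 parallel z-lines spaced
`spacing_um` apart along the bundle axis; Gaussian transverse profiles
(FWHM `zdisc_fwhm_um`), ±20 % amplitude jitter, Gaussian PSF, background,
optional Poisson shot noise and Gaussian read noise, all driven by one
seed (per-cell seeds are `seed + index`, so cohorts are reproducible and
individually regenerable).

Default conditions mirror the emulated acquisitions: pixel size
0.05–0.1 µm, z-disc FWHM 0.2 µm, PSF σ 0.08 µm (SIM-scale resolution),
amplitude 1000 with read-noise SD 200 (SNR 5) and Poisson noise on,
spacings 1.56–1.90 µm, coverages 23–32 % and von Mises κ between 1.5
(standard-culture iPSC-CMs) and 8 (adult cells), matching the group
statistics reported for those conditions. Two presets bundle these:
`"adult"` (rod, aspect ratio 5, μ = 86.08°, κ = 8, spacing 1.90 µm,
coverage 32 %) and `"stancon"` (irregular blob, μ = 42.07°, κ = 1.5,
spacing 1.80 µm, coverage 23 %).

**Ground-truth coverage** is defined on the noiseless render as the
fraction of mask pixels within σ_eff of a z-line centreline, where
`σ_eff = √(σ_line² + σ_PSF²)` is the PSF-broadened transverse scale. The
tube's full width `2σ_eff` is exactly the gradient-extremum
(edge-to-edge) width of the blurred profile — the same convention the
width-mode footprint estimates — so density recovery is a meaningful
estimator check rather than a convention mismatch. This coupling is
deliberate and the ±2 pp density-recovery expectation depends on it.

What the generator does *not* emulate: structured-illumination
reconstruction artefacts, intensity inhomogeneity across the cell,
out-of-focus light, A-bands/M-lines, spacing jitter within a bundle, and
curvature of long myofibrils. Passing recovery tests therefore show that
the estimators are correct for well-formed striated geometry under
realistic noise — not that they are robust to every pathology of real
microscopy. The deliberately overlapping straight bundles do, however,
exercise the crossing/merging failure modes that dominate real images.

## Validation scale and determinism

Recovery checks run on cohorts of 10 seeded cells of 40 × 12 µm (rods) or
radius 10 µm (blobs) at 0.05 µm/px for length and density (where sub-pixel
accuracy matters) and 0.1 µm/px for orientation (where it does not); the
Watson–Williams type-I level is checked on 1000 simulated same-mean pairs
(n = 30, κ = 4). These sizes keep a full validation run in the
tens-of-minutes range on one core while leaving cohort-level Monte-Carlo
error well inside each tolerance. Everything downstream of the seed is
deterministic: measurement sites are chosen by response rank, ties break
by index, and repeated runs are bit-identical.

## Known limitations

* Junctions are split, not resolved; a myofibril crossing another is
  reported as several ridges.
* Nearly-parallel z-lines closer than about `2σ_eff` merge into one
  detected ridge; the clamped median-width footprint compensates on
  average but individual widths there are not trustworthy.
* The density of very dispersed networks at coarse pixel sizes
  (≥ 0.1 µm/px with 0.2 µm lines) is biased upward by a few percentage
  points; use ≥ 2 samples per FWHM when density is the endpoint.
* The Watson–Williams test is a mean-direction test; it does not compare
  concentrations, and its F approximation is rough below n = 10 per group.
* `analyze_cells()` trusts the mask; the Otsu fallback is a convenience
  that is flagged in the report, not a validated segmentation method.
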