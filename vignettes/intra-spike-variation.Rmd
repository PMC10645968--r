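---
title: "Measuring intra-spike variation in wheat grain size from images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intra-spike variation in wheat grain size from images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spikemorph)
```

## The trait and the statistic

Wheat grains are not uniform along the spike: proximal florets and middle
spikelets generally fill better than distal florets and the top spikelets,
and terminal drought or heat stress sharpens those differences. When the
threshed grains of one spike are laid out on a dark background in spikelet
order and photographed, a particle-analysis pipeline can measure every grain
individually while preserving its position along the spike, giving an
affordable proxy for intra-spike assimilate distribution.

The headline statistic is **ISVAD** — intra-spike variation as standard
deviation. For one grain-size parameter $x$ (width, length, projected area,
or perimeter) measured on the $N$ grains of a spike,

$$\sigma \;=\; \frac{\sqrt{\sum_i (x_i - \mu)^2}}{\sqrt{N}},$$

the *population* standard deviation, with divisor $N$ rather than $N-1$.
`isvad()` implements exactly this form; a single grain therefore gives 0,
and two grains give $|x_1 - x_2|/2$. The same statistic is computed within
the bottom, middle and top regions of the spike.

Per-grain size proxies follow the standard particle-analysis conventions:
grain **length** is the maximum caliper (Feret) diameter, grain **width**
the minimum caliper (MinFeret) width, area the projected pixel area, and
the shape descriptors are circularity $4\pi A/P^2$, aspect ratio
(major/minor of the equal-area fitted ellipse), roundness
$4A/(\pi\,\mathrm{major}^2)$ and solidity (area / convex area).

## Pipeline

1. **Calibration** — `set_scale(line_px, line_mm)` converts a reference
   line of known physical length into a pixels-per-millimetre scale,
   applied globally to a session.
2. **Thresholding** — `threshold_binarize()` recomputes a per-image
   automatic threshold. Otsu's method is the default; the iterative
   intermeans (IsoData) variant and a fixed level are provided because
   different particle-analysis tools default differently. Colour input is
   reduced by BT.601 luminance.
3. **Particle analysis** — `label_particles()` finds 8-connected
   components, fills holes, and removes components below 2.5&nbsp;mm² — the
   conventional lower limit that excludes debris and, in the synthetic
   scenes, the thin scale bar — then renumbers survivors.
4. **Ordering** — `order_grains()` groups grains into spikelet rows by
   their vertical centroids (a new row starts where the gap between
   consecutive sorted centroids exceeds half the median grain height),
   orders rows bottom→top and grains left→right, and numbers them in that
   order. Raster row 1 is the *top* of the image, so "bottom" means the
   maximal pixel-row coordinate.
5. **Morphometrics** — `measure_spike()` computes the full record per
   grain (see below).
6. **Summaries** — `summarize_spike()` produces whole-spike and per-region
   means and ISVADs; `batch_process()` runs a whole session and writes
   ImageJ-dialect results CSVs plus a combined summary.

```{r pipeline}
sim <- generate_spike_image(spike_sim_config(n_rows = 10, seed = 42))
cal <- set_scale(sim$scale_bar$length_px, sim$scale_bar$length_mm)
seg <- segment_spike(sim$image, cal)
morph <- measure_spike(seg$labeled, seg$layout, cal)
summarize_spike(morph, spike_id = "demo")
```

## Design choices in the measurements

**Boundary and perimeter.** Each grain's outline is the marching-squares
contour of its filled mask at iso-level 0.5 (`boundary_polygon()`), a
closed sub-pixel polygon. Raw midpoint contours overestimate the perimeter
of smooth shapes by roughly 5% (the staircase effect), which would bias
circularity down by ~10%. Measured perimeters therefore use a circular
boxcar smoothing of the contour (±2 vertices), which we verified brings
rasterized disks and ellipses at 10&nbsp;px/mm within about 0.4% of their
analytic perimeters. Caliper diameters and the convex area are measured on
the same smoothed contour; `boundary_polygon()` itself returns the raw
polygon so the geometric substrate stays inspectable.

**Calipers.** The maximum Feret diameter is the largest pairwise distance
between convex-hull vertices; the minimum width comes from rotating
calipers (minimum over hull edges of the farthest vertex distance to the
edge's line). Both are exact on the polygon; an exhaustive rotation scan is
used as an oracle in the tests.

**Fitted ellipse.** Orientation and axis ratio come from the central
second moments of the pixel coordinates, and the axes are rescaled so the
ellipse area equals the particle's pixel area (the equal-area convention),
so `pi * major/2 * minor/2` always reproduces the measured area.

**Capping.** Circularity, roundness and solidity are capped at 1; on
coarse rasters the estimators can otherwise exceed 1 slightly.

**Degenerate inputs.** A constant image yields an empty mask with a
warning rather than an error; collinear "grains" fall back to a one-pixel
width and are flagged; spikes with fewer than 3 rows have no defined
regions, and region-level ISVADs are reported as missing. A single grain
gives ISVAD 0 by the formula.

**Region split.** The assignment of rows to bottom/middle/top is not
standardized; we fix it as contiguous thirds counted from the bottom —
`ceiling(r/3)` rows bottom, `floor(r/3)` top, remainder middle (so middle
≥ top) — implemented in `region_of_rows()` and used identically by the
generator and the segmentation, so truth and measurement always agree on
region membership.

## The synthetic generator

`generate_spike_image()` renders each grain as an anti-aliased filled
ellipse (inside-test on a 4× supersampled grid, block-averaged), rows of
two grains (one per paired floret) from the bottom of the canvas upwards,
plus a 20&nbsp;mm vertical scale bar drawn 0.1&nbsp;mm wide so that its
area (2&nbsp;mm²) stays below the 2.5&nbsp;mm² particle filter, exactly as
a thin ruler edge would. Options add Gaussian pixel noise, a linear
illumination gradient, and sub-threshold debris speckles. Every image
carries an exact truth table (per-grain length, width, analytic area
$\pi LW/4$, rotation, centroid), and a fixed seed reproduces image and
truth bit-identically. `simulate_spike_truth()` samples truth tables
without rendering, for statistic-level simulation studies.

Defaults describe a typical bread-wheat grain: 7.0 × 3.5&nbsp;mm
(projected area ≈ 19&nbsp;mm², within the 3–30&nbsp;mm² range seen in
field material), 10&nbsp;px/mm resolution, background/grain gray levels
0.05/0.85 (a strongly bimodal dark-background scene), 2&nbsp;mm grain
spacing, ±5° rotation jitter. The within-spike SDs default to
0.6&nbsp;mm (length) and 0.35&nbsp;mm (width) — the magnitudes reported
for unstressed field-grown spikes — so a default simulated spike carries
realistic intra-spike variation. Multiplicative `region_effects` shrink or
enlarge whole regions, emulating poorly filled spike tips.

What the generator does *not* emulate: grain texture and wrinkling,
shadows, awns and rachis fragments, touching grains (the layout protocol
guarantees no contact, and the generator enforces a ≥3&nbsp;px gap or
raises a layout-overflow error), and lens or perspective distortion.
Passing tests on synthetic scenes therefore demonstrate correctness of the
geometry, calibration and statistics — not robustness to photographic
artifacts beyond additive noise and smooth illumination gradients.

## Validation and trial statistics

`fit_calibration()` regresses caliper reference measurements on
image-derived values and reports slope, intercept and $R^2$;
`kfold_cv()` cross-validates that linear model with a seeded
shuffle-then-blocks fold assignment. Per fold, the held-out observations
are predicted from a model fitted to the complement; the per-fold mean
absolute and squared errors are kept, and the overall error is
$\sqrt{\mathrm{mean}(\mathrm{fold~MSE})}$. With $k = n$ the predictions
reproduce the closed-form leave-one-out identity
$e_i/(1 - h_{ii})$ to numerical precision, which the tests assert.

`anova_split_plot()` fits the balanced split-plot RCBD analysis:
environments are main plots, tested against the block×environment error;
genotype and genotype×environment are subplot effects tested against the
residual. With a multi-year table, year and block are folded into a single
replicate factor, so environments remain main plots within years and
blocks; a plain two-way factorial mode is also provided since published
trial reports frequently leave the exact error strata unstated. Unbalanced
tables are rejected rather than approximated.

`dmrt()` implements Duncan's multiple range test: for a range of $p$
ranked means the critical value is
$R_p = q_{\alpha_p, p, \nu}\sqrt{\mathrm{MSE}/n}$ with protection levels
$\alpha_p = 1-(1-\alpha)^{p-1}$; studentized-range quantiles come from
`stats::qtukey`. A difference is declared only if it exceeds its $R_p$ and
no wider non-significant range contains the pair; the letter display is
the set of maximal non-significant ranges. The tests verify the letters
against a brute-force pairwise implementation of that definition on
randomized configurations.

The heat susceptibility index uses the Fischer–Maurer (1978) form
$\mathrm{HSI} = (1 - y_s/y_c)/D$ with $D$ the trial-wide mean depression
($1 - \bar Y_s/\bar Y_c$); published ISVAD work cites HSI values without
printing a formula, so this standard formulation is an interpretation and
is documented as such. Percent decreases of trait means are reported
rounded half-up to one decimal (`percent_change()`), the convention that
reproduces printed values such as 6.3% from means 0.48 → 0.45.

## Problem sizes and numerical tolerances used in the tests

The test-suite simulations are sized for precise yet quick verification:
50 spikes of 10–25 rows for grain-count fidelity, 200 truth-table spikes of
40 grains per SD level for ISVAD recovery (expected within 5% of
$s\sqrt{(N-1)/N}$), 500 null ANOVA replicates for p-value uniformity, 100
randomized 6-group configurations for the Duncan letters. Geometric
accuracy on rasterized references at 10 px/mm: area within 1%, calipers
within 2%, disk circularity ≥ 0.98, roundness of a 2:1 ellipse 0.50 ± 0.02.
Exact identities (OLS normal equations, leave-one-out hat-matrix identity,
ANOVA sum-of-squares partition) are asserted at 10⁻⁸–10⁻¹⁰.

## Known limitations

* Perimeter, Feret and area estimators are sub-pixel but still carry a
  bias of up to about half a pixel per edge; at 10 px/mm this is ≈1% on a
  3.5 mm grain width. Working at higher resolution reduces it linearly.
* Touching grains are not split; the layout protocol must keep grains
  separate.
* The ImageJ-compatibility of the CSV dialect covers the measurement
  columns, not ImageJ's exact perimeter weighting; small systematic
  differences from a genuine ImageJ session are expected and absorbed by
  the calibration regression.
* The split-plot ANOVA requires balanced, complete tables; mixed-model
  alternatives for unbalanced trials are out of scope.
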