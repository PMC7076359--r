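---
title: "Quantifying leaf xylem vulnerability with the optical method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf xylem vulnerability with the optical method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(ovpipe)
```

## The measurement problem

When a leaf dehydrates, the water columns in its xylem are under growing
tension and eventually cavitate: a gas bubble (embolism) fills the conduit
and blocks water transport. The water potential at which half of the vein
network has embolized, $\Psi_{50}$, is a key drought-tolerance trait. The
optical method detects embolism non-destructively: a leaf is clamped over a
light source and photographed repeatedly while it dries; the transition of
a vein from water-filled to gas-filled changes its light transmission
abruptly, so subtracting consecutive frames reveals each embolism event as
a localized bright patch, while slow changes (illumination drift, gradual
tissue changes) cancel.

`ovpipe` implements the complete processing chain behind this measurement:

1. **stack ingestion** — calibrated, time-ordered grayscale frames plus a
   YAML sidecar with capture times, mm/pixel and measured water potentials
   (`read_stack()`, `lamina_mask()`);
2. **event detection** — consecutive-frame subtraction, thresholding,
   component filtering (`subtract_frames()`, `threshold_events()`,
   `accumulate_events()`);
3. **vein quantification** — skeleton length of every event in mm, the
   embolized vein length per unit area
   $\mathrm{VLA}_{embolized} = L_{embolized} / A_{leaf}$
   (in mm mm$^{-2}$), and the conventional embolized-area fraction
   (`skeleton_length()`, `compute_vla()`, `area_fraction()`,
   `analyze_stack()`); cleared-leaf vein density with a major/minor split
   (`vein_density()`);
4. **vulnerability curves** — per-leaf $(\Psi_{leaf},$ response$)$ couples,
   sigmoid fitting with a free asymptote, $\Psi_{12/50/88}$ and a bootstrap
   confidence interval (`build_curve()`, `fit_sigmoid()`,
   `psi_at_fraction()`);
5. **a synthetic simulator** that fabricates ground-truthed leaves so every
   stage above can be validated without any real data (`sim_config()`,
   `simulate_leaf()`, `simulate_curve_points()`).

## The models

### Event detection

Embolism is an abrupt, local, persistent brightening. The detector forms
$|f_{t+1} - f_t|$ on Gaussian-smoothed frames restricted to the lamina
mask, then applies hysteresis thresholding: pixels above the full cutoff
(default 0.05 on the 0–1 intensity scale) seed events, and pixels above
half that cutoff are kept when connected to a seed. Components smaller than
`min_event_px` (default 10 px) are discarded as sensor speckle; an optional
maximum-area cap suppresses slow large-area shrinkage artifacts near the
lamina edge. With deduplication on (default), pixels already flagged in an
earlier frame are excluded, so a flickering vein is counted once and event
masks are pairwise disjoint.

Consecutive-frame differencing (rather than subtracting a fixed baseline)
is what makes the detector insensitive to slow drift and to any constant
intensity offset; both invariances are asserted in the test suite. The
defaults are starting points in the spirit of per-stack manual thresholds
used in optical-method practice, and every one of them is a
`detection_config()` argument.

### Skeleton length

The physical quantity is vein *length*, not vein *area*, so each event
mask is reduced to its medial axis. No installed package provides binary
thinning, so the package implements Guo–Hall parallel thinning (in C++)
followed by two corrections the raw algorithm needs at stroke ends: a
medialization step that straightens the one-pixel sideways hooks thinning
leaves on diagonal strokes, and an endpoint reconstruction that re-extends
the blunt ends thinning erodes (bounded by the local stroke radius from
the distance transform, so rounded caps are not overshot).

Length is then measured by polygonal path reconstruction: the skeleton is
decomposed into paths between endpoints and junctions, each path is
simplified with Douglas–Peucker at a 1 px tolerance, and Euclidean lengths
are summed, calibrated by mm/pixel. On axis-aligned and 45° strokes this
equals the classical step count (orthogonal step = 1, diagonal =
$\sqrt 2$); at intermediate angles it avoids the step count's staircase
bias, which reaches +8.2% at 22.5° — too coarse for a 5% accuracy target
on arbitrary-angle veins. Residual error is dominated by ±1–2 px endpoint
discretization: strokes of $\geq$ 40–50 px are measured within ~3–5%,
while a 13 px stub can be off by ~15–20%. Vein-scale structures are well
above that floor.

### Vulnerability curves and $\Psi_{50}$

Each leaf is dehydrated for a different interval and contributes one
endpoint couple: its final cumulative response paired with its final
pressure-chamber $\Psi_{leaf}$ (`build_curve()`; at least 5 leaves, and at
least 1 MPa of $\Psi$ span, are required for a fit). Two response metrics
are supported: $\mathrm{VLA}_{embolized}$ (the functionally meaningful
one, since gas exchange scales with vein length per area) and the
conventional embolized-area fraction.

`fit_sigmoid()` fits either of two families by multi-start
Levenberg–Marquardt least squares:

$$V(\Psi) = \frac{V_{max}}{1 + e^{s(\Psi - \Psi_{50})}} \quad (s > 0),
  \qquad
  V(\Psi) = V_{max}\left(1 - e^{-(|\Psi|/b)^c}\right),$$

with the asymptote $V_{max}$ free in both: observed plateaus sit near, but
not exactly at, the major-vein density, and pinning the asymptote to the
maximum observed response would bias $\Psi_{50}$. The Weibull family is
the default for comparability with common vulnerability-curve fitting
conventions; $\Psi_{12}$, $\Psi_{50}$, $\Psi_{88}$ come from the exact
closed-form inversions, so `psi_at_fraction(fit, 0.5)` reproduces the
fitted midpoint to machine precision. Multi-start matters: sparse noisy
curves make the least-squares surface multimodal, so fits start from a
grid of data-quantile-derived midpoints and slopes and keep the best
converged solution. Points are unweighted (no replicate-variance structure
is assumed).

Uncertainty uses the nonparametric bootstrap prescribed for this design:
couples are resampled with replacement `n_boot` times (default 500), each
replicate refit (warm-started at the point estimate), and the 95%
percentile interval of $\Psi_{50}$ reported. The seed is an explicit
argument, recorded in the fit object, and the bootstrap is run on an
isolated RNG stream, so results are bit-reproducible and the caller's RNG
is untouched.

Two $\Psi$-attribution modes exist. The endpoint mode above is the
faithful default. The *interpolated* mode (`assign_psi_continuous()`,
`continuous_curve()`) additionally needs an initial water potential and
attributes a $\Psi$ to every event by linear interpolation in time; it
turns a single fully-dehydrated stack into a whole curve. It is an
extension, not a reconstruction of the endpoint workflow, and all its
outputs carry an explicit `"interpolated"` label.

## The simulator: what it emulates, and what it does not

`simulate_network()` grows a hierarchical network inside an elliptical
lamina: one midrib (order 1), order-2 branches leaving it at alternating
sides and randomized 40–65° angles, order-3 sub-branches, and optional
short order-4 stubs, with decreasing rasterized widths (5, 4, 3, 2 px).
Branches never cross: a candidate whose course (outside its junction zone)
comes within 0.9 mm of an accepted vein is rejected, as is any major-order
branch too short for that test to apply. All geometry is in mm with exact
analytic lengths; with the default 220 × 300 px image at 0.1 mm/px the
major-vein density lands around 0.3–0.35 mm mm$^{-2}$, the scale reported
for temperate broadleaved trees.

`simulate_schedule()` draws each segment's embolism-trigger potential from
a normal distribution around the configured $\Psi_{50}$ (SD 0.25 MPa) with
order-dependent mean shifts (+0.5, +0.15, −0.1, −0.35 MPa): the midrib
embolizes first, minor veins last, reproducing the observed midrib-first
propagation. After drawing, all triggers are shifted rigidly so that the
length-weighted median trigger of the major network (orders 1–3) equals
the configured $\Psi_{50}$ *exactly* — the configured value is then the
true half-embolism point of that leaf, not merely its expectation, which
makes closed-loop recovery experiments well-posed per leaf.

`render_stack()` draws a bright lamina (0.5) with darker water-filled
veins (0.35) on a dark background (0.08); when a segment triggers, its
pixels brighten abruptly by 0.2 and stay bright. Gaussian pixel noise
(SD 0.01) and a linear illumination drift (0.001/frame) emulate a consumer
phone sensor; order-4 veins receive only 15% of the event amplitude,
emulating the observation that phone cameras resolve embolism only in
veins up to the third order. Dehydration is linear from −0.4 to −4 MPa
over 30 frames at 5-min cadence. Ground truth records every segment's
trigger potential, trigger frame, raster pixels, and — crucially — its
*novel* pixels (those not already brightened by an earlier-triggering
segment at a shared junction), which is exactly what image subtraction can
see.

Not emulated: optically realistic leaf texture, specular artifacts,
partial-segment embolism spread, cell-collapse signals, leaf shrinkage or
movement, and spatially correlated sensor noise. Passing tests therefore
demonstrate the correctness of the *processing chain* under a controlled
image-formation model, not robustness to every real-world artifact; on
real stacks the thresholds and the optional translation alignment and
area-cap guards will need per-rig attention.

## Validation results computed by the test suite

The `tests/testthat/test-acceptance.R` suite and `scripts/acceptance.R`
recompute, from scratch:

* exactness of the length operator on reference shapes (a 3 × 11 px bar at
  0.1 mm/px is exactly 1.0 mm) and ≤ 5% error on 50 random-angle
  self-avoiding polylines;
* pixel-exact equality of detected and true event sets on noise-free
  stacks; per-event pixel recall ≥ 0.9 and zero spurious components at
  noise SD 0.01 / amplitude 0.2;
* monotone non-decrease of cumulative embolized pixels and cumulative
  VLA;
* saturation: a fully dehydrated leaf's final $\mathrm{VLA}_{embolized}$
  is ≤, and within 10% of, the network's true major-vein VLA;
* $\Psi_{50}$ recovery on 100 simulated 20-leaf curves (response noise
  SD 0.02, true $\Psi_{50} = -2.5$ MPa): median error < 0.1 MPa and
  bootstrap CI coverage within [90%, 99%];
* closed-loop recovery through the full image pipeline on 20 simulated
  stacks: median $|\hat\Psi_{50} - \Psi_{50}|$ < 0.15 MPa;
* machine-precision identity of the VLA quotient and of
  `psi_at_fraction(fit, 0.5)` with the fitted midpoint.

Problem sizes (220 × 300 px frames, 30-frame stacks, 20-leaf curves,
100-curve recovery batches, 300 bootstrap replicates) were chosen so the
full validation runs in a few minutes on a single core while keeping every
estimate's Monte-Carlo error well below the tolerance it is compared to.

## Worked example

```{r example, eval = FALSE}
library(ovpipe)
library(dplyr)

# simulate five leaves dehydrated to different final potentials,
# run the full detection + quantification chain on each
leaves <- lapply(1:6, function(i) {
  cfg <- sim_config(seed = i, psi_end = -0.8 - 0.55 * i)
  analyze_stack(simulate_leaf(cfg)$stack)$leaf
}) |> bind_rows()

curve <- build_curve(leaves, metric = "vla")
fit <- fit_sigmoid(curve, family = "weibull", n_boot = 500, seed = 1)
fit
tidy(fit)
autoplot(fit)
```

## Design choices made where the design was open

* **How leaf area enters Eq. (1).** How the reference area was obtained is
  not standardized; both pathways are provided: an Otsu-based lamina mask
  from the first frame (holes filled, area = pixel count × px²), or a
  user-supplied `leaf_area_mm2` which then overrides the mask-derived
  value. For cleared-leaf crops the imaged-region area is used instead,
  matching the ~5 mm² crop practice; the output records which.
* **Counting re-embolizing pixels.** Whether a pixel region that flickers
  twice should count twice is ambiguous; the default (dedup = TRUE)
  counts each vein pixel once, which keeps cumulative VLA a true set
  union. Turning dedup off reproduces the double-counting behaviour.
* **Major vs minor veins by width, not topology.** Order labelling from
  images is unreliable; the operable proxy for "veins up to the third
  order" is the local width at the skeleton (twice the distance
  transform), split at a user cutoff (`width_cutoff_px`). The published
  phenotyping tools do not disclose their internal cutoff, so it is
  deliberately a user decision.
* **Normalization of the response.** Whether published fits used absolute
  VLA or per-leaf normalized fractions is ambiguous; the free-asymptote
  fit makes $\Psi_{50}$ invariant to any positive rescaling of the
  response (asserted as a property test), which sidesteps the ambiguity.
* **Grayscale conversion** uses fixed Rec. 709 luminance weights, so
  results cannot depend on an image backend's conversion choice.
* **Calibration is mandatory.** mm/pixel is never inferred from EXIF
  metadata: phone focal-length tags cannot give a transmitted-light rig's
  object-plane scale, and uncalibrated lengths would silently corrupt
  VLA.

## Known limitations

* Frame registration is off by default (the rig tapes the leaf to a rigid
  panel); handheld or drifting rigs need the translation pre-alignment or
  will smear events across frames.
* The interpolated $\Psi$ mode assumes the leaf dehydrates linearly in
  time between the two measured endpoints; real dehydration decelerates
  as stomata close, so interpolated per-event potentials are
  approximations and are labelled as such.
* Sub-50 px structures are at the skeleton discretization floor;
  measuring very fine minor-vein networks needs higher spatial
  resolution, not a different estimator.
* The percentile bootstrap undercovers slightly (a few percent) for steep
  transitions sampled by few points — a known small-sample property of
  pairs-percentile intervals, visible in the coverage experiment.
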