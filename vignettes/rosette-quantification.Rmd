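---
title: "Quantifying rosette-based cell internalization"
author: "rosettes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rosette-based cell internalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosettes)
```

## The biology being measured

During *C. elegans* gastrulation, cells that internalize (first the
endodermal precursors Ea/Ep, later mesodermal, germline and ectodermal
cells) accumulate pulsatile foci of non-muscle myosin (NMY-2) on their
exposed apical surface.  These foci flow centripetally, cluster, and
contract; the surrounding cells respond by advancing centripetal
extensions that converge into a multicellular rosette sealing over the
internalizing cell.  Globally, the surface monolayer thins and spreads by
synchronized coplanar divisions whose spindles deviate on average by 36°
from the anterior–posterior (A-P) axis, and the germline precursor P4
translocates anteriorly by stochastic cortical blebs.

This package implements the quantifications of that process as a reusable,
tested pipeline:

* **profiles** — line profiles (mean ± SD over parallel lines) and
  kymographs of cortical intensity;
* **foci** — detection and greedy tracking of contractile foci, contraction
  counting, bleb detection from outline series;
* **coupling** — time-lagged correlation between integrated local
  contraction intensity and extension-tip advancement;
* **spread** — measured circumferential tissue spread from cross-sections
  and its theoretical counterpart under coplanar divisions;
* **tracks** — migration-path smoothing, left/right movement correlation
  matrices, displacement and midline metrics;
* **morpho** — axis ratios and flatness, covering fractions, and the bleb
  area → translocation regression;
* **synthgen** — a seeded generator that emulates the statistical structure
  of the raw recordings so every estimator can be exercised against ground
  truth without microscope data.

No recording is bundled: raw 4D stacks are not deposited with the study
this pipeline reproduces, so the synthetic generator defines the study
conditions under which the pipeline is validated.

## The coupling model

The central quantitative claim the pipeline reproduces is that extension
advancement tracks local contraction intensity with a delay of roughly
20 s (r² ≈ 0.9 at the 20-s shift), consistent with a viscoelastic apical
cortex.  The generator models this as a pure transport delay with
smoothing:

* the integrated local intensity $I(t)$ is a saturating accumulation of
  cortical myosin plus a train of Gaussian contraction pulses (width 3 s,
  roughly one pulse per 20 s, amplitudes growing as foci become more
  numerous) plus white measurement noise;
* the extension tip position is
  $E(t) = \gamma\,\tilde I(t - \delta) + \varepsilon(t)$, where
  $\tilde I$ is the max-normalized, smoothed clean intensity, $\delta$ is
  the transport delay (default 20 s) and $\gamma$ the gain (default 10 µm).

Two modeling choices deserve emphasis.  First, the tip is coupled to the
*level* of the delayed intensity, not to its increments, because the lag
scan regresses tip **position** on lagged intensity (the published axes
plot normalized position); under an increment model the position-vs-lagged-
intensity scan would not peak at the transport delay at all.  A velocity
variant can be emulated by differencing the traces before scanning.
Second, the smoothing is a **centered** moving average (half-width
`coupling_tau`, default 2 s): a causal exponential filter would add its
centroid to the effective delay, so the configured 20 s would no longer be
the recoverable lag.  `coupling_delay` is therefore the total transport
delay, which is what the lag scan estimates.

`lag_scan()` computes, for every lag $\tau$ on a grid (default 0–60 s in
sampling-interval steps), the r² of the ordinary least-squares fit of $E(t)$
against $I(t-\tau)$ over the overlapping window; the peak lag is the
argmax with ties broken toward smaller $\tau$.  r² is the squared Pearson
correlation, so it is invariant to the normalization conventions (intensity
scaled to its maximum, tip scaled to its final position), and the scan
commutes with `normalize_traces()`.  Negative lags are excluded by default
(the asserted causal direction) but available to verify that reversed lags
score worse.

```{r coupling}
cfg <- synth_config(seed = 42)
tr <- generate_coupled_traces(cfg)
nt <- normalize_traces(tr$intensity, tr$extension)
scan <- lag_scan(nt$intensity, nt$extension)
scan
```

With the default study conditions (2-s frames, 150 frames, 20-s delay,
noise SD 5 AU on a ~100 AU signal) the scan recovers the 20-s delay in
every one of 100 seeded replicates and the r² at the 20-s shift is ≈ 0.95;
the noise level and pulse geometry were fixed once so that the synthetic
traces reproduce the r² ≈ 0.9 lagged-correlation signature of the original
measurement, and are not tuned per run.

## The coplanar-division spreading model

The measured circumferential spread of a tissue is the summed angular
extent of its cells in a transverse cross-section at the embryo midpoint,
as a percentage of the full circumference; the two lateral halves of the
ectoderm are added.  The theoretical counterpart assumes perfectly
symmetric divisions at the measured division times.  The original
calculation states those assumptions but not its formula, so the closed
form used here is a **reconstruction**, flagged as such: a cell footprint
(unit circle in the surface plane) stretches two-fold along the spindle at
angle $\theta$ to the A-P axis while its thickness halves (volume
conserved — the surface cells cycle cuboidal → columnar → cuboidal).  The
circumferential semi-axis of the stretched footprint is

$$g(\theta) = \sqrt{4\sin^2\theta + \cos^2\theta},$$

with $g(0°) = 1$, $g(90°) = 2$, $g$ monotone, and $g(36°) = 1.427$.  The
test suite checks the closed form against a polygon-stretching oracle, so
the reconstruction is falsifiable independently of its derivation.

`theoretical_spread()` propagates an initial spread through a division
list by reconstructing relative footprint widths from the parent names
(each division hands each daughter $g(\theta)/2$ of the parent's width)
and capping the total at 100 %.  When all angles in a synchronized round
are equal this reduces to multiplying the tissue spread by $g$ once per
round.  Whether the published curve used per-division measured angles or
the 36° mean throughout is not stated; both modes are provided
(`angle_mode = "per-division"` / `"mean"`).

```{r spread}
lin <- generate_lineage(synth_config(seed = 5))
times <- c(0, 300, 700, 1600, 2100)
meas <- measured_spread(cross_sections(lin, times), "AB")
theo <- theoretical_spread(meas$spread_pct[1], lin$divisions, times)
compare_spread(meas, theo)$rms_pct
```

## Measurement conventions

* Pixel coordinates are 0-based and pixel-centered (x right, y down);
  times are seconds from stack start; embryo axes are A-P (x, anterior
  positive), D-V (y), L-R (z).  Stated once, used everywhere.
* Line profiles sample bilinearly at exactly 1 px steps.  With two lines
  (the default) the second line is offset one pixel to one side of the
  requested line; with an odd count the offsets are symmetric.  The SD is
  the sample standard deviation across lines (n − 1 denominator), so for
  two lines it is $|a-b|/\sqrt2$.  The offset geometry is not specified by
  the original measurement description; the one-sided convention is this
  package's reading of "two lines spaced at 1 pixel parallel to and on the
  line".
* A kymograph row is exactly the single-line profile of that frame (one
  shared sampler), and `superimpose()` over the whole movie equals the
  temporal maximum projection.
* Focus detection thresholds (`min_intensity`, `min_sep`, the integration
  disk radius) are configuration with documented defaults, not calibrated
  claims — the recordings define a "focus" only visually.  Linking is
  greedy nearest-neighbour in order of increasing distance, which makes it
  invariant to detection order; global assignment is unnecessary at these
  focus densities.
* Contractions are path-convergence events: tracks whose end points
  cluster within `cluster_radius` (single linkage) form a group, and a
  pulse of the group's summed intensity (rise ≥ `min_gain`, fall ≥ half
  that) is one contraction.
* Movement correlations use per-step L/R displacement increments by
  default, because raw-position correlations are dominated by shared
  drift; a positions mode is available.  Pairs sharing fewer than three
  timepoints yield `NA` and are excluded.  The ±0.8 clip applies only to
  rendered heat maps, never to stored values.
* Left/right partners are matched by swapping `l`/`r` in the lineage name.
  The midline angle is derived from the mean left-minus-right difference
  vector in the (A-P, L-R) plane; it is 0° for perfect mirror symmetry and
  positive when the right-side group sits posterior to its left partners.
* Flatness is `1 − min/max` of the two perpendicular extents, printed with
  every output because the original formula is cited to an unavailable
  reference; treat absolute flatness values as this package's definition.
* Covering fractions and bleb excess areas are exact polygon-boolean
  areas, computed by a vertical trapezoidal decomposition written for this
  package (no polygon-clipping dependency); the Monte-Carlo point-in-
  polygon oracle lives only in the test suite.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* the estimators
assume: pulsatile foci born at the periphery drifting centripetally
(isotropic Gaussians, sin² intensity envelope, birth positions avoiding
live foci so puncta stay resolvable), delayed-coupled trace pairs,
lineages on an ellipsoid surface whose footprints grow by $g(\theta)$ per
division, bilateral track groups converging on the midline, and bleb
series with a linear area → translocation law and retraction uniform in
30–60 s.  Defaults are the study conditions where stated (2-s frames,
20-s delay, 36° mean spindle angle, 30–60 s retraction); free parameters
with no published distribution (focus lifetime, pulse amplitudes, bleb
area scale ~20 µm² log-normal, embryo radii 15/25 µm) were chosen once at
values realistic for a ~50 µm embryo and are documented as uncalibrated.

It deliberately does **not** model a microscope PSF, photobleaching,
shot-noise statistics, mechanical force balance (no vertex or
finite-element model), or segmentation errors.  Passing tests therefore
demonstrate correctness of the *measurements* under the stated stochastic
structure, not robustness to every imaging artifact of real recordings.

## Numerical choices and degenerate inputs

* Generators seed a private RNG stream (restoring the caller's state) and
  consume it in a documented order, so tests can replay the stream;
  identical config + seed is bit-identical output.
* The trapezoidal area engine places strip boundaries at every vertex and
  pairwise edge-crossing ordinate; strips thinner than 1e-13 are skipped.
  Self-intersecting outlines are rejected where they would corrupt areas.
* Lags that are not multiples of the sampling interval are evaluated by
  linear interpolation of the intensity trace; the minimum overlap per lag
  is 10 samples and violating it is an error naming the minimum.
* Zero-variance series (flat extension traces, constant-area bleb sets)
  are errors, not NaNs; too-short track overlaps are `NA` sentinels.
* TIFF export stores integer-valued stacks as 16-bit samples (exact
  round-trip) and everything else as 32-bit samples scaled by a
  power of two (relative quantization below 2⁻³¹); metadata live in a YAML
  sidecar and missing metadata is an explicit error.

## Problem sizes used by the test suite

The suite validates on deliberately small instances chosen to exercise
every code path: 150-frame trace pairs (100 replicates for the delay
estimate), 60-frame 64×64 movies, lineages of 2–6 division rounds,
50 randomized instances per brute-force oracle comparison, and 10⁵-point
Monte-Carlo covering checks.  These sizes are the package's validation
conditions; all estimators accept arbitrarily larger inputs.

## Known limitations

* The spreading formula is a reconstruction (see above); absolute
  theoretical curves inherit its assumptions.
* `measured_spread()` treats the circumference as a circle at the embryo
  midpoint; no ellipsoid geodesics.
* Bleb translocation measurement assumes the anterior axis is +x unless a
  track table supplies an embryo frame, and aligns the resting outline by
  its posterior extreme, which presumes the posterior side does not bleb.
* The lag scan quantifies lagged correlation only; it makes no causal
  claim beyond the direction asserted by its default lag grid.
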