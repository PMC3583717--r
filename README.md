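# rosettes

Quantification of rosette-based cell internalization in early
*C. elegans* embryos.

During gastrulation, internalizing cells (the endodermal precursors Ea/Ep
and, later, mesodermal, germline and ectodermal cells) show pulsatile
apical flows of non-muscle myosin (NMY-2), while their neighbours advance
centripetal extensions that converge into a multicellular rosette sealing
over them.  Globally the surface monolayer thins and spreads by coplanar
cell divisions, and the germline precursor P4 translocates anteriorly by
cortical blebbing.  `rosettes` implements the measurements that
characterize this process, for anyone analysing time-lapse fluorescence
recordings and lineage tracks of early embryos:

- **line profiles and kymographs** of cortical intensity (bilinear
  sampling, mean ± SD over parallel lines);
- **contractile-focus detection and tracking** (local maxima, greedy
  nearest-neighbour linking) and contraction-event counting from
  converging focus streams;
- **contraction → extension coupling**: for lag τ, the r² of the OLS fit
  of extension-tip position *E(t)* against integrated local intensity
  *I(t − τ)*; the peak of the lag scan estimates the viscoelastic
  transport delay (≈ 20 s, r² ≈ 0.9 at the 20-s shift);
- **circumferential tissue spreading**, measured from cross-section
  occupancy and predicted under symmetric coplanar divisions, where one
  division at spindle angle θ to the A-P axis stretches a cell footprint
  circumferentially by *g(θ) = √(4 sin²θ + cos²θ)* (g(36°) = 1.427);
- **migration-path analysis**: moving-average smoothing (width 5),
  left/right movement-correlation matrices (increments of the L-R
  coordinate, heat maps clipped at ±0.8), displacement as percent embryo
  length, and midline-angle symmetrization;
- **morphometrics**: apical/basolateral axis ratios and flatness,
  covering fractions by exact polygon-boolean areas, and the bleb
  area → anterior-translocation regression;
- a fully **seeded synthetic-data generator** for all of the above, so
  the entire pipeline is exercised against ground truth with no imaging
  data.

## Worked example

Generate a coupled intensity/extension trace pair under the default study
conditions (2-s frames, 20-s transport delay), normalize it by the display
conventions (intensity to its maximum, tip to its final position), and
scan lags 0–60 s:

```r
library(rosettes)

tr <- generate_coupled_traces(synth_config(seed = 42))
nt <- normalize_traces(tr$intensity, tr$extension)
lag_scan(nt$intensity, nt$extension)
#> lag_scan: peak r^2 = 0.953 at lag 20 s (31 lags scanned)
```

The scan recovers the generating 20-s delay, with r² at that shift ≈ 0.95:
extension advancement is well explained by the local contraction intensity
20 s earlier.

Measured versus theoretical circumferential spread of the ectoderm for a
synthetic dividing lineage (two lateral founder blocks, divisions at the
configured round times, spindle angles ~N(36°, 10°)):

```r
lin  <- generate_lineage(synth_config(seed = 5))
times <- c(0, 300, 700, 1600, 2100)
meas <- measured_spread(cross_sections(lin, times), "AB")
theo <- theoretical_spread(meas$spread_pct[1], lin$divisions, times)
round(cbind(time_s = meas$time_s, measured = meas$spread_pct,
            theory = theo$spread_pct), 2)
#>      time_s measured theory
#> [1,]      0    27.78  27.78
#> [2,]    300    27.78  27.78
#> [3,]    700    40.85  40.85
#> [4,]   1600    58.55  58.55
#> [5,]   2100    58.55  58.55
```

Each division round multiplies the tissue's circumferential extent by
g(θ); the measured occupancy of the rendered cross-sections reproduces the
model exactly on generator-consistent input.

Bleb area against anterior translocation (log-normal areas, linear law
plus noise):

```r
ev <- generate_blebs(synth_config(seed = 8, n_frames = 600))
bleb_regression(ev)
#> bleb regression: translocation = 0.0960 + 0.0154 x area (um, um^2); r^2 = 0.651, n = 16
```

`run_pipeline(synth_config(seed = 1), "out/")` runs every stage
(synthesis, profiles, foci, coupling, spread, tracks, morphometrics) and
writes one CSV per result, byte-reproducibly for a fixed seed.  A thin
command-line wrapper with the same operations ships in `inst/cli/rosettes`.

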