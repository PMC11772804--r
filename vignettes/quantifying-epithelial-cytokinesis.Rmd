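---
title: "Quantifying cytokinesis failure in curved epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytokinesis failure in curved epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follicleQuant)
```

## The measurement problem

Epithelial cells that fail cytokinesis become multinucleated. In a
post-mitotic epithelium — the stage-10 *Drosophila* follicular epithelium is
the motivating tissue — the nuclei-per-cell ratio is therefore a cumulative,
permanent record of cytokinesis efficiency, and a shift in that ratio under an
RNAi treatment reads out genetic modifiers of cytokinesis. Three practical
obstacles stand between a confocal z-stack and that number:

1. the tissue is **curved**, so no single optical section contains all nuclei
   and membranes;
2. cells and nuclei must be **segmented and matched** over hundreds of cells
   per chamber;
3. the screen statistic must be referenced to **same-replicate sensitised
   controls**, because the baseline failure rate drifts between experiments.

`follicleQuant` implements the full path — projection, segmentation, counting,
screen statistics — together with kinetic (ring constriction rate),
intensity (cortical fluorescence) and time-lapse (failure category) read-outs,
and a synthetic-data generator that provides exact ground truth for every
stage. Everything the package claims is demonstrated on that generator by the
test suite and `scripts/acceptance.R`; no microscopy data ships with it.

## Nucleus-anchored local projection

A z-stack `(y, x, z, channel)` with membrane and nuclear channels is flattened
by a *local* projection: nuclei are detected in 3D
(`locate_nuclei_3d()`: pooled-histogram Otsu threshold, 6-connected component
labelling, intensity-weighted centroids), and each image pixel projects the
planes whose physical z lies within half a `thickness_um` (default 1 µm) of
the **nearest nucleus's** axial position. Pixels are assigned to anchors by
Euclidean xy distance, ties to the smaller nucleus id; if no plane centre
falls inside the window the single nearest plane is used; the reducer is `max`
by default (`mean` and `sum` are available). Because each pixel follows its
local nucleus, the projection tracks a domed surface; the package also ships
`midstack_projection()`, the naive fixed-window alternative, which the test
suite shows losing off-apex nuclei almost entirely on a dome whose sag spans
8 z-planes while the anchored projection retains ≥ 95 % of every nucleus's
in-focus intensity.

Conventions: R arrays, 1-based indices, column-major `[y, x, z, channel]`;
physical z of plane *k* is `(k − 1) · z_spacing_um`; physical calibration
travels in a JSON sidecar next to the TIFF.

## Multinucleation scoring

Quantification is restricted to a central region (`select_central_roi()`,
default a rectangle shrunk by `margin_fraction = 0.2` per side; a
tissue-adaptive eroded-foreground mode is available) because membranes and
nuclei near the chamber outline can be missed by any projection.

`segment_cells()` smooths the membrane channel (Gaussian, σ = 2 px), inverts
it, and applies a tolerance-merged watershed (`h = 0.1` in intensity units,
playing the role of an h-minima depth) so each membrane-bounded basin is one
cell. `segment_nuclei()` uses Otsu + hole filling + a distance-transform
watershed to split touching nuclei. `count_nuclei_per_cell()` assigns each
nucleus to the cell under its centroid; centroids on background are reported
as unassigned rather than guessed. The ratio is total nuclei over cells among
interior cells with ≥ 1 nucleus; zero-nucleus cells are excluded and surfaced
in a QC attribute (on real images they would be fixed at the manual-validation
step, for which the label maps round-trip through 16-bit TIFF).

### Why the border rule is a counting frame

Cells at the ROI edge must be excluded, but *how* matters. Discarding every
cell that intersects the ROI boundary is size-biased: a cell of diameter *D*
inside a frame of side *L* is retained with probability ≈ ((L−D)/L)², so
larger cells — and multinucleated cells are roughly twice mononucleated area —
are preferentially lost, deflating both read-outs by more than the package's
own recovery tolerance. `segment_cells()` therefore defaults to the standard
unbiased **counting frame**: cells touching the ROI's forbidden boundary (the
leftmost ROI pixel of each row and bottommost of each column — the left and
bottom edges of a rectangular ROI) or the image frame edge are flagged
`touches_border` and excluded from the statistics, while cells crossing the
top/right ROI boundary are included at full extent (nuclei are segmented
frame-wide so such cells keep all their nuclei). Under translation this
attributes every cell to exactly one frame position, making inclusion
independent of cell size. The intersection rule remains available as
`border_rule = "intersect"`.

With the counting frame, the end-to-end pipeline on the default synthetic
tissue recovers planted binucleation fractions f ∈ {0, 0.05, 0.10, 0.20} with
the pooled nuclei/cell ratio within ±0.03 of 1 + f and the multinucleated-cell
frequency within ±2 percentage points of 100·f (acceptance suite, 10 chambers
per fraction).

### The screen statistic

For a sample egg chamber with ratio *r* and same-replicate sensitised controls
*c₁…cₙ*:

Δ multinucleation ratio = *r* − (1/n) Σᵢ *cᵢ*.

`assemble_screen()` enforces the replicate pairing (rows without
same-replicate controls are an error, not silently pooled), computes
per-chamber Δ, compares each target group to its pooled same-replicate
controls with the Mann–Whitney test, and calls `enhancer` (p < α, median
Δ > 0), `suppressor` (p < α, median Δ < 0) or `no_effect`. α = 0.05 by
default; an optional Benjamini–Hochberg column is off by default so the
per-line p-values stay comparable with per-experiment practice. Under a
simulated null the call rate matches α to within binomial error (acceptance
suite, 1000 replicates).

`mann_whitney_u()` computes U from midranks; p-values use the exact null
distribution when the combined sample is ≤ 12 without ties and the normal
approximation with tie and continuity correction otherwise (the switch point
is an argument). The exact path is verified against full enumeration of all
label assignments for every rank split with group sizes ≤ 5.

## Ring constriction rate

From a uniformly sampled trace of ring diameters d(t):

* `detect_onset()` — t₀ is the frame before the first sustained drop:
  the first frame below (1 − δ)·d[1] (δ = 0.05) followed by `persist = 3`
  frames that rise by no more than δ·d[1]/2.
* `normalize_trace()` — d/d(t₀), exactly 1 at t₀.
* `fit_constant_phase()` — among all windows of 4 consecutive post-onset
  timepoints whose normalized diameters lie inside [0.40, 0.80] (the roughly
  linear stretch of closure), fit d = α + βt by OLS on the *absolute*
  diameters, keep windows with R² > 0.95, and return the best window (highest
  R², earliest on ties). The rate is |β| in µm/min. Flat windows (zero total
  sum of squares) are skipped as R²-undefined. Traces with no candidate
  window, or none passing the gate, raise distinct errors so cohorts can
  report exclusions.

The trace simulator produces a plateau, a constant phase, and a
slope-continuous exponential tail toward a small midbody plateau (5 % of d₀).
Defaults: d₀ = 8 µm, onset 2 min, rate 0.6 µm/min, tail at 30 % of d₀,
dt = 1 min, 18 frames, chosen so that a 4-point window spans 3 min of the
constant phase and the fit has useful power at realistic noise.

**A statistical limit worth knowing.** With measurement noise of 2 % of d₀ the
R² > 0.95 gate on 4-point windows is a hard filter: the pass probability per
window is P(χ²₂ < 0.05·SStot/σ²), and the [0.40, 0.80] band only ever contains
two or three heavily overlapping windows. A design analysis over initial
diameters 5–8 µm and sampling intervals 0.5–1.5 min shows the per-trace
success rate saturating around 90–93 % — denser sampling buys more windows but
each has less signal, and coarser sampling leaves too few windows in the band.
The default design sits at that optimum; expect the gate to reject a handful
of traces per hundred at this noise level (the acceptance script reports the
realized rate), with the rate estimate itself essentially unbiased (< 5 %,
typically < 1 %). Shortening the interval below ~0.75 min also inflates |β|
through selection effects, which is why the default is not simply "as fast as
possible".

`mean_trace_with_sd()` aggregates t₀-aligned normalized traces into the
pointwise mean ± SD profile used for cohort comparisons at stated timepoints
(e.g. 1.5 and 3 min after onset); SD is reported missing where fewer than two
traces remain.

## Cortical intensity and failure scoring

`zsum_project()` sums the two planes that cross-section a mitotic cell.
ROI means (`measure_roi_mean()`) use pixel-centre membership: an annular band
of total width 3 px along the cortex circle, a 3 px band along a segmented
line at the ring, and a 10 px diameter cytoplasmic disk whose mean is
subtracted (`background_correct()`); corrected values are invariant to global
additive offsets by construction.

`score_division_events()` operates on event logs (one row per division), not
raw movies: after dropping cells larger than `max_area_px` (default twice the
median pre-division area — large cells are suspected products of earlier
failures) and cells observed less than 20 min post-constriction without
regression (failure could not be ruled out), each event falls in exactly one
of three categories: no failure, failure during constriction (ring regressed
before completing), failure post-constriction (regression after completion,
with regression time summarised as mean ± SD). The two eligibility filters
commute, which the suite checks explicitly.

## The synthetic-data generator

`generate_epithelium_stack()` emulates, deterministically per seed:

* a near-hexagonal monolayer as the Voronoi tessellation of jittered-grid
  seeds (default 448 px = 224 µm field, 400 cells ≈ 11 µm across — a 40×
  confocal field of a stage-10 chamber);
* a domed surface (clipped elliptic paraboloid, `curvature_sag_um` = 4 µm
  peak-to-edge by default) that sets the z-position of membranes and nuclei;
* multinucleated cells as merged neighbour pairs sharing their longest
  membrane facet (≥ 6 px): merging across a sliver facet produces dumbbell
  cells whose pinched waist any watershed correctly splits, which would test
  the geometry artefact rather than the pipeline. Merged cells are larger and
  carry one nucleus per constituent, as real post-failure cells do;
* nuclei as 3D Gaussian blobs (σ = radius/2, radius 2.2 µm) on the surface;
* image formation as per-plane Gaussian PSF blur (σ = 1 px), Poisson shot
  noise (`rpois(scale·I)/scale`, scale 200) and additive Gaussian read noise
  (sd 0.01).

The planted multinucleated-cell count is exactly
`round(fraction · n_cells_target)` and every nucleus lies inside its cell, so
ground truth is exact, not approximate. What the generator does **not**
emulate — and what green tests therefore do not certify on real data —
includes stage drift and photobleaching (corrected upstream by standard
plugins on real movies), anisotropic PSFs, intensity inhomogeneity across the
field, irregular cell-size distributions, debris, and genuinely 3D nuclear
shapes. Parameters for real data will need the usual per-dataset adjustment
of `h`, smoothing σ and minimum areas, and segmentation should be manually
validated; the TIFF round-trip of label maps exists precisely for that.

`generate_constriction_trace()`, `generate_intensity_scene()` and
`simulate_division_events()` provide the corresponding ground-truthed inputs
for the kinetic, intensity and scoring modules; the intensity scene splits its
values evenly across two planes so the z-sum reconstructs nominal intensities
exactly.

## Numerical and degenerate-input choices

* Projection window: plane centres within ±thickness/2, inclusive (1 nm
  slack for floating point); empty window → single nearest plane; no anchors →
  an error pointing at `midstack_projection()`.
* Blank nuclei channel → zero anchors (empty data frame), blank images →
  empty nucleus maps; a boundary-free membrane image yields a single region
  rather than a watershed error.
* Otsu thresholds are computed on the pooled histogram (256 levels) over
  whatever region is being segmented.
* All RNG goes through one seeded generator per simulator call and restores
  the caller's RNG state; identical spec + seed reproduces outputs
  bit-exactly.
* Label ids are contiguous positive integers in deterministic (raster)
  order; nearest-anchor and tie-break rules are deterministic, so the whole
  pipeline is replayable.

## Problem sizes used by the shipped checks

The acceptance suite runs the full-size study condition (448 px chambers,
10 seeds per fraction, 100 traces, 1000 screen-null replicates); the unit
suite exercises the same code paths on 128–192 px tissues and smaller cohorts.
These sizes were chosen as the smallest at which the sampling error of the
recovered quantities is comfortably below the stated tolerances.
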