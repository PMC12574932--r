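---
title: "Generating and calibrating agricultural landscapes with agriscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and calibrating agricultural landscapes with agriscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agriscape)
```

`agriscape` simulates agricultural landscape mosaics for use as inputs to
spatially explicit ecological and agro-economic models. This vignette
documents the models and algorithms behind each step, the parameters that
matter, the numerical choices made where the design was genuinely open, and
what the package's tests do and do not establish about real landscapes.

## The raster substrate

All computation happens on a plain 2-D numeric matrix with a cell
resolution in meters (`ag_grid`). Indexing is 0-based `(row, col)` with row
0 at the north; grids are bounded (no wrap-around), and `NA` cells are
outside the landscape for every placement and metric computation. The
default resolution is 10 m, so a 200 x 200 grid spans 2 km x 2 km and one
hectare is exactly 100 cells — the scale at which the default parameters
are calibrated. Raster interchange uses the ESRI ASCII grid format, a
plain-text standard readable by GIS software and FRAGSTATS; values are
written with 17 significant digits so continuous grids round-trip at
double precision. Cells must be square.

## Step 1: potential space

The potential space is the binary mask of cells eligible for arable
fields. Three routes produce it.

**Fractal gradient noise.** `generate_perlin_slope()` sums `octaves` layers
of classic 2-D Perlin (lattice gradient) noise — each octave multiplying
the spatial frequency by `lacunarity` (default 2) and the amplitude by
`gain` (default 0.5) — and min–max rescales the sum to slope degrees in
[0, 90]. Rescaling over the generated grid means every map attains both 0
and 90 somewhere; only the *relative* relief is meaningful. The default
`frequency` of 4 base cycles per grid span gives hill structures of a few
hundred meters at the default extent, a plausible scale for terrain-driven
agricultural limitation. Low values are read as gentle, farmable terrain:
`categorize_by_threshold()` keeps cells at or below a slope threshold,
while `categorize_by_share()` keeps exactly the requested share of
lowest-slope cells (ties broken by row-major scan order, so the realised
share is within one cell of the request and the result is deterministic).
The raw slope map is also retained for least-cost routing.

**Hybrid world.** To embed simulated mosaics in a real-map context,
`fit_hybrid()` fits a single cell-wise binomial logistic regression of
arable membership on covariate rasters, treating cells as independent
observations (IRLS via `glm`, gradient tolerance 1e-8, at most 100
iterations; complete separation returns finite capped coefficients with
`converged` reporting the IRLS status). `apply_hybrid()` then draws an
independent Bernoulli realisation of the fitted probabilities and applies
synchronous majority-vote sweeps: each cell adopts the strict-majority
state of its 8-neighbourhood, keeping its state on ties. Strict majority is
the only vote rule idempotent on homogeneous regions, which is why it was
chosen; the default of 2 sweeps visibly clusters the mask without erasing
mid-sized structures. Because maximum-likelihood logistic fits reproduce
the observed arable share in expectation, any *surplus* of potential space
over current arable land comes from the spatial model: where covariates
mark more suitable terrain than is currently farmed, per-cell probabilities
sit above one half across that whole region and the majority vote fills it.
One property of the vote worth knowing: it increases spatial
autocorrelation in every run (the package tests assert this), but it can
occasionally *raise* the component count of a class by cutting thin
bridges between blobs — clustering and component count are not the same
thing.

**External masks.** `load_external()` accepts any binary raster (values
checked after NA removal), so thresholded real maps can replace both
built-in routes.

**Roads and rivers.** `least_cost_path()` runs on a weighted 8-neighbour
lattice graph: a road step between two cells costs the mean of their cell
costs `1 + slope/90`, a river uses the inverted relief `1 + (90 -
slope)/90` so that it follows valleys, and diagonal steps are weighted by
sqrt(2) to avoid axis bias. Endpoints may be explicit or drawn uniformly
from a uniformly chosen pair of opposite grid edges. The path is globally
optimal (tested against an independent Dijkstra implementation);
`buffer_path()` widens it by Chebyshev radius and
`exclude_from_potential()` removes it from the mask, idempotently. The
inverted river cost and the opposite-edge endpoint rule are design choices
of this package — both are exposed as parameters with documented formulas
so users who prefer a different routing model can supply explicit
endpoints or treat either cost surface as a road.

## Step 2: field placement

Both placement algorithms draw, per field, a size (hectares; normal with
redraw-truncation at one cell, at most 100 redraws then clamped, or
lognormal moment-matched to the requested mean and sd) and a shape ratio
rho >= 1 (normal, truncated at 1). A field of `A` cells is laid out as
`n_segments = max(1, round(A / L))` one-cell-wide segments of up to `L =
round(sqrt(A * rho))` cells, so `rho` is approximately the bounding-box
length:width ratio on unconstrained ground. Hectares convert to cells via
the grid resolution, rounded half-up.

**Place-and-conquer** (`establish_pac()`) repeatedly picks a uniform-random
free anchor cell and orientation, lays the first segment through the
anchor (window slid to fit the maximal free run), and adds parallel
segments at the offset maximising the number of rook-adjacent cell pairs
with the previous segment — ties resolved toward the smaller offset —
using free cells only. Growth proceeds on one side of the first segment
and switches to the other side when blocked, letting fields wrap around
obstacles; a segment with no contact to its predecessor would disconnect
the field and therefore ends it. Fields are thus always 4-connected,
disjoint and inside the mask (asserted as test invariants), and their
realised size and shape are a joint product of the parameters and the
space — truncated fields are kept, down to a single cell. Placement stops
with the field that first reaches the requested coverage, so the realised
coverage overshoots by at most one field (the documented "one-field
slack"). Because every free cell remains a legal anchor, any coverage up
to 1 is eventually reachable; the degenerate-exhaustion branch returns a
flagged partial landscape rather than erroring, as a defensive contract.

**Dead leaves** (`establish_dl()`) first covers the mask completely by
stamping random rectangles (drawn dimensions, uniform centre and
orientation), each occluding whatever it overlaps, until every mask cell
is covered or 10,000 consecutive stamps add nothing; surviving 4-connected
same-id regions become fields, so occluded fragments split. The second
phase deletes fields from the smallest up until the remaining coverage is
at or below target — pruning smallest-first avoids the over-fragmentation
that random pruning would leave behind, and guarantees the invariant that
every kept field is at least as large as every removed one.

## Step 3: enrichment

`distribute_farmers()` creates farmers sequentially; each draws its number
of fields from a uniform (on a mean/sd-matched interval), normal or
moment-matched lognormal distribution (rounded, minimum 1) and receives
either a random unassigned field plus its nearest unassigned fields by
centroid Euclidean distance (spatial mode) or uniform-random fields. The
number of farmers is emergent, not a parameter, and the last farmer may
fall short — batch-nearest selection was chosen over greedy contiguous
growth as the simpler reading of "nearby fields go to the same farmer";
the package tests verify that spatial mode beats random mode on
within-farmer distances in at least 95 of 100 seeded runs.

`distribute_crops()` assigns exactly one crop per field: fields are
visited in a seeded random order and each receives the crop with the
largest remaining area deficit relative to its target share. This greedy
rule consumes the whole portfolio and bounds every crop's share error by
the largest field's share of total field area, which is why landscapes
with more or smaller fields track a portfolio better. Both identities can
instead be set directly from two-column tables.

`extract_view()` produces the categorical rasters: field ids, arable land
with border cells removed (a field cell is a border cell if any rook
neighbour — including cells beyond the grid edge — is outside its field;
this conservative rule makes one-cell-wide fields entirely border), crop
and farmer codes (crop labels map to integer codes through a JSON legend
side-car), and the mask itself.

## Landscape metrics

`compute_profile()` implements the FRAGSTATS raster formulations with
deliberately simple, brute-force-verifiable definitions: patch areas in
hectares, perimeters in meters counting grid-boundary faces, edge density
per hectare of non-NA landscape, largest patch index as a percentage,
shape `0.25 p / sqrt(a)`, fractal dimension `2 ln(0.25 p) / ln(a)`,
perimeter-area ratio, landscape shape index, and the adjacency-entropy
contagion over all classes with rook adjacencies counted from both sides.
Patches default to 8-connectivity (the common patch rule; 4 is available).
Euclidean nearest-neighbour distances are measured between cell centres —
dialects differ here, and edge-to-edge implementations will disagree by up
to one cell size. Standard deviations are sample standard deviations.
Metrics undefined for a configuration (a single patch's `area_sd`, `enn`
with fewer than two patches, `contag` of a one-class map) are `NA`, never
silent zeros. Every metric is tested to 1e-9 against an independent
direct-definition oracle on random maps. Because connectivity rules and
ENN dialects vary between implementations, absolute metric values from
other software are comparable only qualitatively; internal consistency is
what the tests guarantee.

`profile_distance()` scores two profiles as `1 - mean(min(1, |g - r| /
max(|r|, 1e-9)))`: each metric contributes a scaled distance clipped at 1
so that one wildly-off metric cannot dominate the score; 1 means a perfect
match on the compared subset.

## Calibration

`run_ga()` is a conventional elitist genetic algorithm — tournament
selection of size 3, uniform crossover with probability 0.8, per-gene
Gaussian mutation (probability 0.1, sigma 10% of the gene range, clipped
to bounds), one elite — over a named, bounded subset of generator
parameters. Fitness averages the `profile_distance()` score of (by
default) 3 generated replicates per evaluation to damp generator noise;
the elite's cached fitness is carried over unchanged, making the
best-fitness trace non-decreasing by construction, and every evaluation
seed derives deterministically from the configuration seed. Degenerate
chromosomes that generate no fields score 0 rather than erroring. The
default optimisation goal is the `np`/`area_mn`/`area_sd` triple computed
on the binary arable class (field presence), since those metrics are the
common currency of landscape characterisation. These operator choices and
hyperparameters are conventional defaults; nothing in the method depends
on them finely, and the package's tests verify optimum-finding on an
analytic fitness as well as parameter recovery end-to-end.

Identifiability deserves a caution: different parameter combinations can
produce indistinguishable metric profiles (a smaller potential space at
higher coverage, for instance), so "the" recovered parameterisation is one
of possibly several solutions — which is exactly what makes the
equivalent-map workflow useful. `generate_equivalents()` re-runs the
generator under the calibrated parameters with distinct derived seeds and
summarises optimised plus held-out metrics as quartiles across the sample.

## Problem sizes, tests and what they show

The test suite and the acceptance script work at what we consider desk
scale: 100 x 100 grids (1 km x 1 km at 10 m) for calibration runs, 50 x 50
for placement invariants, 20 x 20 for metric-oracle equivalence, with 5–100
seeds per property. These sizes were chosen so the full suite exercises
every contract — determinism, disjointness, coverage slack, optimality
against Dijkstra, oracle equality to 1e-9, GA convergence within 30
generations on self-generated references — while each individual check
stays in the seconds-to-minutes range; none of the algorithms change
behaviour with grid size.

The synthetic-data path (Perlin surface, share categorisation, seeded
placement) emulates terrain-constrained European-style field mosaics:
smooth relief, compact fields, coverage as a policy-like control. It does
not emulate sharp geological discontinuities, road- or settlement-driven
layouts, hydrology, or the socio-economic history behind real farm and
crop patterns — so passing tests demonstrate the *algorithms'* contracts
and internal consistency, not that any particular real region is
reproduced. For real-map work the hybrid-world and external-mask routes
exist precisely so the mosaic can inherit observed structure.

## Known limitations

Single-band rasters only, no reprojection or vector field outlines; the
Perlin surrogate produces smooth gradients and will under-represent sharp
constraints in geologically complex terrain; the enrichment rules are
deliberately simple (no economics, no rotations); and the GA is a
single-objective search — multi-metric trade-offs beyond the scaled-mean
score require re-weighting the metric subset by hand.
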