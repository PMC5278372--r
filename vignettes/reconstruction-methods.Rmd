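---
title: "Reconstructing historical land-use maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing historical land-use maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hlurm)
```

## The problem

Spatially explicit historical land-cover maps predate systematic remote
sensing only where topographic maps or archives happen to survive, yet
ecological and carbon-cycle studies need them on a regular grid with a
complete legend. `hlurm` reconstructs such maps by *backcasting*: it
assumes the present spatial pattern of land use is intrinsically linked to
the historical one, estimates *how much* of each class existed at the
reconstruction date, estimates *where* each class was likely to sit, and
then allocates quantities to cells with a cellular automaton. The
reconstruction is validated against an independently digitised historical
map with a three-map comparison.

The pipeline has four stages, each usable on its own:

1. **Quantity control** — per-class total areas for the target year, fused
   from multiple sources and/or backcast through a transition matrix.
2. **Spatial conversion rules** — cross-tabulation and trajectory analysis
   of the observed map series; supplies the transition model and the
   unchanged-land constraint.
3. **Probability (suitability) surfaces** — per-class 0–255 scores from
   weighted environmental, human-disturbance and autocorrelation factors
   under boolean constraints.
4. **Spatial allocation** — ordered CA assignment of cell quotas by
   descending suitability.

## Data model

A `lu_grid` is an integer lattice over an `lu_schema` (the legend; the
default is 1 arable, 2 forest, 3 grassland, 4 water, 5 settlement,
6 wetland, 7 other unused) with a square-cell geometry. Row 1 is the
northernmost row and indices are row-major, matching the ESRI ASCII Grid
body order; rasters are read and written in that plain-text format.
Areas are reported in hectares, `cell_area = cell_size^2 / 10^4`, so the
default 90 m cell is 0.81 ha. All rasters entering one operation must be
co-registered bit-exactly — the package never resamples — and a cell that
is nodata in *any* input is excluded from every statistic of that
operation. The source material never states how border/nodata cells were
handled; ANY-input exclusion is this package's contract, chosen because it
is the most conservative and keeps margins consistent across operations.

## Quantity control

`fuse_sources()` combines per-class area estimates from several sources as
a weighted sum, with per-class source weights derived by Saaty's Analytic
Hierarchy Process (`ahp_weights()`: normalised principal eigenvector of a
reciprocal pairwise-comparison matrix, computed by power iteration to
1e-10 in at most 10⁴ steps; consistency ratio from Saaty's random-index
table, warning above 0.10). Published studies typically print only the
resulting weights, so `weight_vector()` accepts a weight vector directly,
validated to sum to 1 (tolerance 1e-3 for 3-decimal published tables).

```{r}
fused <- fuse_sources(zhenlai_source_areas())
round(fused, 2)
round(100 * fused / sum(fused), 2)
```

Backcasting (`backcast_quantities()`) treats an observed later-interval
cross-tabulation as the model of the earlier interval. Only the final-year
(column) class areas are known for the earlier interval, so each column is
rescaled to its known margin in a single pass — that scaling is unique, no
iterative proportional fitting is needed — and the backcast initial-year
areas are the rescaled row totals, which always sum to the known total. A
zero column with a nonzero target margin is an error (proceeding would
silently break that conservation). Narrative adjustments to the model
("this flow should have gone elsewhere in the earlier period") are
expressed as `move_flow()` rules applied in list order by
`edit_transitions()`; each rule preserves its source row total, hence the
grand total, exactly. The rules are supplied by the analyst — nothing is
hard-coded for any particular study area. `areas_to_cells()` converts
areas to integer cell quotas by largest-remainder apportionment (ties on
the fractional part go to the larger share, keeping the result invariant
under class reordering up to exact ties).

## Suitability surfaces

Factors are fuzzy-membership surfaces standardised to 0–255; constraints
are binary and multiply the score, so a single 0 excludes a cell
absolutely (`wlc_suitability()` computes
`round(sum(w_i * x_i) * prod(c_j))`).

* **Categorical environmental factors** (soil, geomorphology, and
  elevation/slope/aspect binned into user-chosen intervals with
  `bin_continuous()` — percentages need classed factors): the score of
  factor category *k* is the percentage of the class's observed union area
  lying on *k*, stretched linearly from the hundred-mark to the 255-mark
  scale (`round(2.55 * percent)`, rounding half away from zero; no other
  stretch is applied). The percentage is of the class union across factor
  categories (the categories partition it, so percents sum to 100), not of
  each category covered by the class; the former is the reading most
  consistent with "the percentage of each land-use category distributed in
  these factors".
* **Distance factors** (settlements, rivers, roads) and
  **autocorrelation factors** (distance to the class's own cells in the
  reference map): exact Euclidean distance (via `EBImage`'s distance
  transform), normalised by the maximum distance over the valid cells of
  the study mask — not a fixed radius, since no cap is stated — and
  reverse-stretched so a feature cell scores 255 and the farthest cell 0.
* **Constraints** (`build_constraints()`): water bodies exclude every
  class but water; cells whose class never changed over the observed
  period are assumed to have held that class at the reconstruction date
  and exclude all other classes; human-modified classes (arable,
  settlement by default) are confined to the union of their observed
  extents.

Factor weights per class are again AHP weights; each class's weights must
sum to 1, and a factor can be absent for a class (blank cells in
`zhenlai_factor_weights()`).

## Spatial allocation

`allocate()` assigns integer cell quotas class by class in a fixed order —
default settlement, arable, water, wetland, forest, grassland, other
unused, i.e. the most human-determined and best-evidenced classes first.
Cells fixed by the unchanged-land constraint are pre-assigned and debited
from the quotas (step 0); they seed the automaton. Candidate cells are
ranked by descending suitability with row-major index as the
deterministic tie-break, and a strict pass accepts a candidate only if

(a) its suitability for the class is the *strict* maximum across classes
    (ties fail and fall through to relaxation, resolved by class order);
(b) the partial evidence map, where it has a value, names this class;
(c) at least 5 (configurable) of its Moore-8 neighbours already hold the
    class — off-grid and nodata neighbours count as non-matching, so the
    rule is stricter at borders.

Passes are *synchronous*: neighbour counts are frozen at the start of a
pass and all acceptances commit together, the classic CA update. The
per-cell-sequential alternative would make results depend on scan order
within a pass; the synchronous rule is order-free given the ranking,
fully deterministic, and fast. Strict passes repeat (the accepted cells
enlarge the neighbourhoods for the next pass) until the quota is met or a
pass accepts nothing; then rules are dropped one at a time — neighbour
rule first, then max-probability, then evidence — and passes resume. The
drop order makes quantity control the binding constraint: allocation for
a class stops exactly at its quota, and a quota that cannot be met even
unconstrained is an error, never silently truncated. Changing
`class_order` can legitimately change the map; determinism is guaranteed
only for a fixed configuration.

## Validation

`three_map_components()` overlays reference time 1, reference time 2 and
simulated time 2 and classifies each cell as null success, hit, miss or
false alarm; `comparison_budgets()` derives observed change `OC = H + M`,
predicted change `PC = H + F`, quantity error `EQ = |M − F|`, allocation
error `EA = 2·min(M, F)` (so `EQ + EA` is the total error), the figure of
merit `FOM = H/(H + M + F)` and the ratios HOC/MOC/FOC of hits, misses
and false alarms to observed change. Two bookkeeping modes are exposed
because printed component tables do not always say which was used:
`"categorical"` (default) requires a hit to predict the *correct* new
class and counts wrong-class changes (partial hits) among the misses,
matching a figure of merit that removes partial hits from the numerator;
`"binary"` counts any predicted change on an observed-change cell as a
hit, which is the bookkeeping under which `PC = H + F` holds. Partial
hits are always reported separately, and results should state the mode.
Both modes satisfy every budget identity. Kappa-style whole-area
agreement statistics are deliberately out of scope.

## Synthetic landscapes

Real historical rasters are rarely redistributable, so the package tests
itself on generated ones. `generate_landscape()` draws one uniform noise
field per class, smooths each with a uniform box filter (radius in cells;
dependency-light spatial autocorrelation), and carves class extents by
rank: classes in decreasing target share each take their
largest-remainder cell count from the highest-ranking unassigned cells of
their own field. Realised proportions therefore match the targets exactly
up to integer rounding, and patches are contiguous. The default
proportions are the reconstructed Zhenlai 1930s composition (grassland
63.17%, arable 24.45%, wetland 9.69%, water 1.74%, settlement 0.71%,
forest 0.13%, other unused 0.12%); the default grid is 200 × 200 cells of
90 m. `generate_factors()` adds categorical factors correlated with the
classes (each factor repeats its class's preferred category with
probability 0.7, a value giving factor–class mutual information
comfortably above noise while keeping factors imperfect), point/line
feature masks, and a partial evidence raster (10% coverage by default).
`simulate_forward_change()` moves each cell independently under a
row-normalised transition matrix. One explicit seed per generator call
(`withr::with_seed`) determines every output; no global RNG state leaks.

What the generator does *not* emulate: real terrain gradients,
hydrology-driven class geometry, historical cartographic generalisation,
or classification inconsistency between map sources — typically the
dominant error source when validating against digitised historical maps.
Passing tests on synthetic data
therefore demonstrate the *mechanics* (conservation, determinism,
constraint handling, statistical recovery), not reconstruction accuracy
on real archives.

## Test problem sizes

The recovery experiments use sizes at which the stated tolerances are
statistically meaningful: transition-matrix recovery and two-interval
backcast recovery run on 500 × 500 grids with equal class proportions
(≈35 700 cells per class keeps per-row rate noise near 0.25%, so the ±2%
bands test the method, not the sample); the allocation invariants run on
one hundred random 100 × 100 problems with ~8% fixed cells, partial
evidence, and constraint layers. The Zhenlai composition is deliberately
*not* used for the recovery experiments because its rarest classes
(≈0.1%) would leave transition rows with a few hundred cells and make the
bands vacuous; it remains the generator default.

## Known limitations

* Quantity fusion takes published per-source weights as given when the
  underlying pairwise matrices were not published; the bundled
  other-unused figure is a published fused value carried verbatim.
* Settlement reconstruction inherits the method's weakness: socioeconomic
  drivers are outside the factor set, so settlement placement is the
  least reliable output — small, mobile classes driven by factors the
  model does not see.
* Raster I/O is the ESRI ASCII Grid dialect only (plus CSV for tables);
  projection metadata is not carried.
* The allocation loop structure (per-class sweeps of synchronous passes
  with scheduled rule relaxation) is one deterministic realisation of the
  CA procedure; other loop orders are defensible, which is why both the
  class order and the relaxation schedule are configuration, not code.
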