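---
title: "Analysing land-cover change: budgets, systematic transitions and zonal dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing land-cover change: budgets, systematic transitions and zonal dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(changescape)
```

## The problem

Two categorical maps of the same landscape at two dates — say six
land-cover classes (forest land FL, immature forest land IFL, cultivated
land CL, orchards O, construction land CoL, water W) classified from
satellite scenes taken a decade apart — contain far more information than
the usual "class X grew by Y%" summary. This package implements three
layers of analysis on such a pair:

1. a **change budget** per class, separating how much area a class kept,
   gained, lost, exchanged in place (swap) and shifted in quantity (net);
2. a **systematic-vs-random transition screen**, which asks whether a
   given inter-class conversion is larger or smaller than what class
   prevalences alone would produce;
3. a **zonal change dynamic index (LUCDI)** with a kernel-smoothed
   surface, which locates *where* the landscape was most active.

All three consume one object, the cross-tabulation (transition) matrix.

## The transition matrix and the change budget

Let \(C_{ij}\) be the percent of the jointly valid study area occupied by
class \(i\) at time 1 and class \(j\) at time 2; \(C_{j+}\) and
\(C_{+j}\) are the row (time-1) and column (time-2) marginals and the
diagonal \(C_{jj}\) is persistence. Per class \(j\):

* gross gain \( \mathrm{Gain}_j = C_{+j} - C_{jj} \)
* gross loss \( \mathrm{Loss}_j = C_{j+} - C_{jj} \)
* net change \( N_j = |\mathrm{Gain}_j - \mathrm{Loss}_j| \)
* swap \( S_j = 2\min(\mathrm{Gain}_j, \mathrm{Loss}_j) \) — equal gain
  and loss at different places, i.e. pure relocation
* total change \( TC_j = \mathrm{Gain}_j + \mathrm{Loss}_j = N_j + S_j \)

Swap is the term the familiar net-change summary silently drops: a class
can relocate massively while its total area barely moves. These
identities, and the conservation property
\(\sum_j \mathrm{Gain}_j = \sum_i \mathrm{Loss}_i = 100 - \mathrm{trace}\),
are enforced to 1e-9 in the test suite on random full-precision matrices.

```{r budget}
t00 <- table1_fixture("2000-2013")
change_budget(t00)
```

## Expected transitions under a random process

A large conversion between two big classes is not evidence of a process —
big classes collide by prevalence alone. The screen therefore compares
each observed off-diagonal \(C_{ij}\) with its expectation under a null
model in which a class gains (or loses) the *amount it actually gained
(lost)*, distributed over partner classes in proportion to their
prevalence:

\[ G_{ij} = \mathrm{Gain}_j \frac{C_{i+}}{100 - C_{j+}}, \qquad
   L_{ij} = \mathrm{Loss}_i \frac{C_{+j}}{100 - C_{+i}}, \qquad i \ne j .\]

The deviation \(D_{ij} = C_{ij} - G_{ij}\) (gain side; analogously with
\(L_{ij}\) on the loss side) is in percent of study area; the ratio
\(R_{ij} = D_{ij}/\mathrm{expected}\) removes the prevalence scale, so a
small class transitioning far above expectation still registers.
Deviations near zero mean the transition is indistinguishable from random
mixing; large positive (negative) \(D\) and \(R\) together mark a
transition the landscape systematically seeks (avoids). Per gaining class
the deviations sum to zero — an algebraic consequence of the closed form
that doubles as a strong internal check on any transcription of a
published table.

```{r signals}
S <- transition_signals(t00)
head(S[order(-abs(S$d_gain)),
       c("from", "to", "observed", "expected_gain", "d_gain", "r_gain",
         "label_gain")])
rank_signals(S)
```

### Labelling thresholds

The null model gives no significance test (and none is attempted — the
inputs are exhaustive censuses of the map, not samples). Labels therefore
need explicit cutoffs: a pair is `systematic-to` when \(D >\)
`threshold_d` *and* \(R >\) `threshold_r`, `systematic-avoid` for the
mirrored negative condition, `random` otherwise. The defaults are
`threshold_d = 0.2` (percentage points of study area) and
`threshold_r = 0.5`. The ratio threshold does the discriminating; the
deviation threshold exists to suppress pairs whose absolute area is
negligible. We deliberately keep `threshold_d` low because the regime the
ratio exists for — small classes with strong tendencies, such as orchards
converting to construction land at 13–35 times their expectation —
produces deviations of only a few tenths of a percent. On
the two packaged fixtures these defaults select exactly the three
transitions the source narrative calls dominant (IFL→FL, CL→O, O→CoL)
and nothing else; both thresholds are plain arguments, and any serious
use should report them (the pipeline writes them to
`run_metadata.json`).

Rankings take only pairs systematic on *both* the gain and loss side and
order them by `min(|d_gain|, |d_loss|)`: a transition is only as dominant
as its weaker line of evidence.

### Published (rounded) tables as input

A matrix re-keyed from print is rounded to 2 decimals, and its printed
marginals, gain and loss columns are *not* exactly the sums of its
printed cells. `from_published_table()` therefore stores the printed
marginals and gain/loss columns as authoritative when given, tolerates a
total-sum residual up to ±0.2 (recorded in the object and in
`run_metadata.json`), and the budget and expectation formulas use those
stored values. Recomputing the deviations for both packaged fixtures this
way reproduces the independently printed signal table within ±0.02
per cell — with one instructive exception: the printed gain-side FL→IFL
cell for 1992–2000 (−0.28) cannot be produced from the printed inputs
(rounding bounds the recomputable value to [−0.32, −0.31]), and it is the
one printed cell that breaks the per-class zero-sum identity. We read it
as a misprint; the tests assert the algebraically consistent value.

Ratios with tiny expectations are rounding-fragile: recomputed at full
precision, an expectation of 0.0083 printed as 0.01 turns a printed ratio
of 29.00 into 35.3. `transition_signals(..., rounding = "paper")` rounds
the deviation and the expectation to 2 decimals before dividing, which is
the arithmetic a reader of the printed table would do; the default
(`"full"`) keeps full precision. Analyses comparing against published
ratio tables should restrict attention to cells with expectation ≥ 0.5,
where both modes agree.

## Zonal dynamics (LUCDI)

Per zone (village, township, grid block), with \(\mathrm{Increase}_i\),
\(\mathrm{Decrease}_i\) and \(\mathrm{Nochange}_i\) the areas entering,
leaving and persisting in class \(i\):

\[ \mathrm{LUCDI} = \frac{\sum_i \mathrm{Increase}_i + \sum_i
   \mathrm{Decrease}_i}{2A}, \]

where \(A\) is the zone's valid area. Each changed cell is counted once
as an increase and once as a decrease, so the index is exactly the
changed-area fraction: 0 iff the zone persisted entirely, 1 iff no cell
persisted. Unlike one-way dynamic-degree formulations it is symmetric in
gains and losses, so a zone that swaps heavily without net change is not
reported as inert. Two readings of annualization circulate; dividing by
the elapsed time inside the index would break the [0, 1] bound, so we
emit `lucdi` (bounded) and `lucdi_annual = lucdi / (t_2 - t_1)`
separately and let the analyst pick.

Zone values are assigned to each zone's geometric centre (polygon
centroid, or the mean cell centre for raster zones; a non-convex zone's
centre may fall outside it and is used regardless) and smoothed into a
surface by weighted kernel density — by default the quartic (biweight)
kernel \(K(u) = \tfrac{3}{\pi h^2}(1-u^2)^2,\ u = d/h < 1\), the kernel
of the common GIS density tools, with a Gaussian option. The surface is a
*relative* intensity: it is linear in the weights and carries no
probability normalization, matching what a density-tool raster gives you
up to a constant. The default bandwidth is 1/10 of the longer grid
extent; there is no principled universal choice at village scale, so the
bandwidth is always recorded in the outputs and worth varying.

```{r lucdi}
cfg <- synthetic_config(n_rows = 60, n_cols = 60, n_zones = 8, seed = 7)
st <- generate_study(cfg)
zd <- zone_dynamics(st$map_1, st$map_2, st$zones)
zd[, c("zone_id", "valid_cells", "changed_cells", "lucdi", "lucdi_annual")]
```

`covariate_report()` closes the loop descriptively: Spearman rank
correlations of zone LUCDI against per-zone covariates (population growth
rate, GDP, distance to roads …). It is a screen, not an attribution — the
package makes no causal claim.

## What the synthetic generator emulates — and what it does not

`generate_study()` produces landscape pairs with *known* ground truth:
time-1 cells drawn i.i.d. from specified class shares (defaults: the
2000 composition of the packaged fixtures), optionally spatially
clustered by deterministic 3×3 majority smoothing (ties to the lowest
class code, so maps stay reproducible); time-2 classes drawn per cell
from a row-stochastic Markov matrix (default: the 2000–2013 fixture rows
normalized); wall-to-wall Voronoi zones grown from uniformly sampled
seed cells (30 m cells, 200×200 grid and 25 zones by default — a
plausibly village-sized zoning of a small county at Landsat resolution).
All randomness flows through explicit seeds.

This emulates the *statistical* structure the analysis consumes: joint
transition shares converging to `share × markov` (recovered within ±0.5
percentage points entry-wise on a 500×500 grid in the tests), spatial
autocorrelation of cover, compact contiguous zones. It does **not**
emulate classification error, registration error, scene/cloud masking,
real village geometry, or spatially *heterogeneous* transition regimes
(the Markov matrix is stationary in space unless you vary it yourself).
Passing tests on synthetic pairs therefore validate the bookkeeping and
the estimators, not the upstream mapping pipeline; with real
classifications, the error budget of the maps dominates and cells like a
suspiciously systematic O→CoL conversion deserve a classification-quality
check before a process interpretation.

## Numerical and degenerate-input policy

* All internal arithmetic is full double precision; the `"paper"`
  rounding mode exists only to mirror 2-decimal published arithmetic.
* Percentages are relative to cells valid (non-nodata) at *both* dates;
  this convention is stamped into `run_metadata.json`.
* Misaligned grids (shape, transform, or CRS text) are refused, never
  resampled; legends that disagree on a shared code are refused, never
  guessed.
* A class occupying the entire map at a date has no partners to draw
  from: its expectation column (row) is `NA` with a warning, and
  undefined ratios force the `random` label with an explicit
  `r_*_defined = FALSE` flag.
* Zero-expectation cells leave \(R\) undefined rather than infinite.
* Zones with no valid cells are kept, flagged, and get `NA` indices;
  empty rankings and all-zero surfaces are returned, not errors.
* Ties in majority smoothing and in Voronoi growth break to the lowest
  code/id, making every synthetic artefact a pure function of its seed.

## Problem sizes used in the shipped checks

The test suite validates the estimators against brute-force per-cell
oracles on twenty 200×200 pairs with 4–25 zones, recovers the fixture
Markov matrix on five 500×500 simulations, and checks conservation
identities on one hundred random matrices — sizes at which every
property asserted is already stable, chosen to keep a full run around
twenty seconds.

## Limitations

* Two dates only; no chained multi-date matrices or trend tests.
* No accuracy-adjusted (error-matrix-weighted) area estimation.
* The random-process screen is descriptive; no sampling variance is
  attached to \(D\) or \(R\).
* ESRI ASCII grid is the raster interchange format (GeoTIFF must be
  converted on the way in); zones come as GeoJSON polygons (outer rings)
  or zone rasters.
* Kernel surfaces ignore zone shape and size beyond the centroid — a
  deliberately simple interpolator, not an areal disaggregation model.
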