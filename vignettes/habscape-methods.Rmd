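---
title: "Methods: landscape simulation, suitability surfaces, and scenario costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape simulation, suitability surfaces, and scenario costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habscape)
```

## What the engine computes

`habscape` is the computational core of a decision-support workflow for
upland gamebird (ring-necked pheasant) habitat management on agricultural
landscapes. Given a landcover *composition* — the area proportions of CRP
grassland, row crop, small grain, rangeland, trees, wetland, and a
residual "other" class — it:

1. realises the composition as a categorical raster over a hypothetical
   township (a 9324 ha public-land-survey block) plus a buffer;
2. computes, for each model covariate, the proportion of that landcover
   within a circular moving window around every core pixel;
3. evaluates a log-linear species–habitat model at every pixel to produce
   a relative habitat-suitability surface, classified into ordinal
   categories; and
4. prices the conversion of a baseline composition into a management
   scenario over a 10-year horizon.

## The landscape model

### Proportional random rasters

The township raster is *compositionally exact and spatially neutral*.
Pixel counts per class are fixed by largest-remainder (Hamilton)
apportionment: each class receives the floor of its exact quota
`proportion × n_pixels`, and leftover pixels go to the largest fractional
remainders, ties broken by the canonical class order (`crp`, `row_crop`,
`small_grain`, `rangeland`, `trees`, `wetland`, `other`). Every count is
therefore within one pixel of its quota and the total is conserved
exactly. Whether to round or apportion was an open design choice; we
chose apportionment because it is deterministic and conserves area
exactly, which in turn makes the per-class counts invariant under the
placement seed.

Placement is a seeded uniform random permutation (Fisher–Yates via R's
Mersenne–Twister `sample.int`) of all pixel positions — deliberately
*no* spatial autocorrelation, patches, or edges. The simulated landscape
is a visualisation of a landscape-scale statistical model, not a map of
any real place; spatially structured generators are an explicit
non-goal, though `generateTownship` is the natural extension point for
rule-based placement.

### Geometry

The default core is 84 × 111 pixels of 100 m (1 ha each), i.e. exactly
9324 ha. The source application states the township area and two window
radii ("10 pixels = 1 km", "50 pixels = 5 km") but never the grid
dimensions; 100 m pixels are the only size consistent with both radius
equivalences, and 84 × 111 is a near-square integer factorisation of
9324 (a square would need a non-integral 96.56² grid). The raster is
generated over core *plus* a 50-pixel buffer, with buffer pixels drawn
from the same proportional assignment, so windows centred on core pixels
see an unbiased landscape and no edge correction is ever needed — edge
correction schemes (toroidal wrap, partial windows) are a non-goal
because the buffer contract makes them unnecessary.

## Focal statistics

A circular window of radius *r* contains every integer offset with
center-to-center Euclidean distance ≤ *r* (boundary included): 5 cells
at *r* = 1, 317 at *r* = 10, 7845 at *r* = 50. The boundary-inclusive
rule is the simplest defensible reading of "radius" and is what makes
the 317-cell count reproducible.

Window class counts are accumulated in exact integer arithmetic — for
each row offset the circular window covers a contiguous column run, so
per-row cumulative sums give the count with no floating error — and a
single division by the kernel cell count happens at the end. The test
suite exploits this: a brute-force double-loop recount must agree
*bit-for-bit*, not merely within tolerance.

Each covariate is evaluated at one of the two analysis scales, 10 px
(1 km) or 50 px (5 km). The published model states that two scales exist
but not which covariate uses which; the shipped default — crop classes
and rangeland at 5 km, CRP, trees and wetland at 1 km — is an
**assumption** chosen to reflect that cropping systems operate at
broader extents than the patch-scale habitat features, and must be
overridden via `scale_map` when the true mapping is known. The residual
class "other" appears on rasters for visualisation only and has no
focal layer: it is not a predictor of the species' abundance.

## The suitability model

At pixel *p* with focal proportions R (rangeland), C (CRP), RC (row
crop), G (small grain), T (trees) and W (wetland):

$$\mathrm{HS}_p = \exp\!\big(\beta_0 + \alpha_R R_p + \alpha_C C_p +
\alpha_{RC} RC_p + \alpha_{RC2} RC_p^2 + \alpha_{RC3} RC_p^3 +
\alpha_G G_p + \alpha_{G2} G_p^2 + \alpha_{G3} G_p^3 +
\alpha_T T_p + \alpha_W W_p\big)$$

Inputs are un-centered and un-standardized; the quadratic and cubic crop
terms are powers of the *same* focal value. The default intercept is
$\beta_0 = 3.07$. The ten slopes ship only as a clearly labelled
**placeholder** configuration
(`inst/extdata/coefficients_placeholder.yaml`, signs plausible, values
arbitrary), because the fitted slope values were published elsewhere and
re-stating them as fact here would be fabrication; any substantive
analysis must supply its own `CoefficientSet`. Predictions use mean
coefficient values only — no uncertainty propagation, by design: the
workflow exposes prediction variability by re-running with different
seeds instead. There is no detection-probability parameter anywhere
(constant detection is assumed), no elevation covariate, and refitting
the regression is a non-goal.

The value $\exp(\eta_p)$ is a *relative* abundance-scale index:
comparable across pixels, not an absolute count, and reported without
further interpretation.

### Categories

The source application displays suitability *categories* without
defining them. The default here is k = 5 equal-count (quantile)
categories of the current surface — scale-free, so they remain
meaningful whatever the slope configuration — with ties always sharing a
category so that category order respects value order. Explicit value
thresholds are supported (`breaks=`) for users who have a fixed legend.

## The economic model

Costs are computed on acres (2.47105381 acres/ha) over a configurable
horizon, default 10 years — the length of a typical CRP contract.

* **Agricultural incentive cost** = (baseline annual gross income −
  scenario annual gross income) × horizon + CRP rental × max(0, ΔCRP
  acres) × horizon. Gross income counts crop acres × yield × price
  (row crop, small grain) plus rangeland acres × pasture rental; CRP,
  trees, wetland and "other" contribute nothing there, so CRP rental is
  never double-counted. Charging rental only on the CRP *increase*
  treats baseline contracts as sunk; a `crpMode = "all"` flag prices
  every scenario CRP acre instead, since the alternative reading cannot
  be ruled out. A negative agricultural cost (scenario more profitable
  than baseline) is reported as-is with a sign note.
* **Management cost** is one-sided: tree removal ($650/acre) is paid
  only when tree acres *decrease* (planting is free, removal yields no
  revenue); wetland restoration ($6250/acre) only when wetland acres
  *increase* (draining costs the manager nothing).
* **Total** = agricultural + tree + wetland, an invariant enforced by
  the `CostBreakdown` class. Discounting, inflation and
  landowner-behaviour modelling are non-goals.

## Synthetic county profiles

No real county composition or economics table is bundled. The fixture
generator (`generateFixtureProfiles`) emulates the *schema* of a
NASS-style county table: compositions drawn from a symmetric
Dirichlet(2) over the 7-class simplex (concentration 2 keeps draws away
from degenerate vertices while still covering the simplex, favouring no
class), and economics drawn uniformly from order-of-magnitude-realistic
ranges — yields 20–200 bu/acre, prices $2–15/bushel, rentals
$10–250/acre/yr. These are placeholders with the right shape and units,
not estimates of any county; passing tests demonstrate the engine's
arithmetic and contracts, not the economics of any real landscape. Real
data show spatial correlation among neighbouring counties, correlated
compositions and prices, and far less simplex coverage than the
Dirichlet draw — none of which the fixtures emulate, and none of which
the engine's correctness depends on.

## Numerical choices and problem sizes

* Compositions must sum to 1 within 1e-9; the residual "other" class is
  recomputed as `1 − sum(named classes)` when absent.
* Focal arithmetic is exact (integer counts, one final division); the
  log-link identity `log(predictSurface) == linearPredictor` is tested
  at 1e-12 relative tolerance; `predictSurface` fails loudly (naming the
  pixel and its linear predictor) on overflow rather than returning Inf.
* Seeds: every stochastic operation takes an explicit seed and
  restores the caller's RNG state, so library use never perturbs a
  session's random stream. Identical inputs + seed give bit-identical
  rasters; changing the seed changes placement but never class counts,
  category partitions of a constant surface, or costs.
* Test and vignette problem sizes: brute-force window oracles run on
  30 × 30 cores at radius 3 (20 replicates); the empirical-uniformity
  check uses 500 seeds of a 20 × 20 grid; full-size (84 × 111 + 50 px
  buffer) runs appear where the 9324 ha geometry itself is under test.
  These sizes were chosen so the whole suite exercises every contract in
  well under a minute while the full pipeline still runs at the real
  township scale.

## A worked run

```{r run}
profiles <- tempfile(fileext = ".csv")
invisible(generateFixtureProfiles(3, seed = 11, path = profiles))
cfg <- list(profiles = profiles, county_id = "SYN001",
            deltas = list(crp = 0.05, trees = -0.05))
res <- runScenario(cfg, seed = 42, outDir = NULL)
res$baseline$summary
res$cost
```

The scenario enrols 5% of the township into CRP and removes 5% tree
cover; the cost breakdown prices the income shift, the new CRP
contracts, and the tree removal over 10 years.

## Known limitations

* Spatial neutrality: the simulated rasters carry no autocorrelation,
  so landscape metrics beyond composition (edge density, patch size)
  are meaningless on them.
* The placeholder slopes make default suitability *values* arbitrary;
  only structural properties (intercept recovery, monotonicity, the
  closed-form homogeneous limit) are meaningful until real coefficients
  are supplied.
* The covariate-to-scale mapping is an assumption (see above).
* Economics ignore discounting and partial-contract proration, and
  assume pasture rental is symmetric with crop sales as landowner gross
  income.
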