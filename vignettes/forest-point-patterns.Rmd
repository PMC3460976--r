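---
title: "Methods: spatial pattern and association analysis of mapped forest plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial pattern and association analysis of mapped forest plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestspat)
```

## The problem

Large stem-mapped forest plots record every tree above a census minimum
(here 1 cm diameter at breast height, DBH) with coordinates, species and
diameter. Two classes of question drive the analyses this package
implements:

* **Niche structure** — are species concentrated in particular topographic
  habitats (valleys, slopes, plateaus, canopy gaps)?
* **Biotic interactions** — are individual species aggregated or regular at
  small scales, how does that change across life stages (a fingerprint of
  density-dependent mortality, the Janzen–Connell mechanism), and do
  heterospecific pairs attract or repel each other at neighbourhood scales
  (the prediction of species herd protection and of facilitation)?

Both questions demand careful null models: habitat association must be
judged against the spatial autocorrelation of the habitat mosaic, and
small-scale interactions must be separated from the large-scale intensity
variation that habitat preference itself creates.

## Life stages

Stems are classified per species as saplings (1–5 cm DBH; 1–3 cm for
treelet species, whose maximum DBH is at most 20 cm), poles (from the
sapling cutpoint to `D95_0.1`) and adults (above `D95_0.1`).
`D95_0.1` is the 95th percentile of DBH among stems at least one tenth of
the species' maximum DBH; restricting to that subset stops a flood of tiny
recruits from dragging the "canopy-size" threshold down. The percentile is
computed as the nearest-rank order statistic (`ceiling(0.95 n)`-th), which
is deterministic and well defined for small samples; a stem exactly at
either cutpoint is a pole. If a species' `D95_0.1` does not exceed its
sapling cutpoint, its pole class is simply empty. Treelet status is an
input flag; when absent it is inferred from the data as maximum DBH ≤ 20 cm.

Importance values rank species as `IV = RD + RA + RF` (relative density,
relative dominance by basal area `pi (dbh/2)^2`, relative frequency by
20 m quadrat occupancy, each in percent summing to 100 over species).
The summation form of IV (maximum 300%) and the 20 m occupancy quadrat are
conventions chosen here and recorded as such: the underlying field
descriptions leave both open, and any consistent choice only affects the
ranking, not the analyses downstream.

## Topographic habitats

A corner-elevation lattice at 20 m spacing yields per-quadrat metrics:

* *mean elevation* — mean of the four corner elevations;
* *slope* — mean inclination of the four planes through corner triplets,
  the convention used for large forest-dynamics plots;
* *convexity* — focal quadrat mean elevation minus the mean of its up to 8
  neighbours (edge quadrats use the neighbours they have), positive on
  ridges and negative in gullies.

Quadrats are classified with thresholds of 27.1° (slope), 764.87 m
(elevation) and 0 (convexity): low ground splits into *valley* (gentle) and
*low-slope* (steep); high ground is *high-gully* when concave, otherwise
*high-slope* (steep) or *high-plateau* (gentle). The published rule set
leaves two boundary situations open: a slope of exactly 27.1°, and
non-convex high ground at gentle slope. We resolve them as "ties go to the
steeper class" and "concave high ground is high-gully regardless of
slope", so that the classification is total and exclusive; both choices
are confined to `classify_habitat()` and configurable through its
threshold list. Canopy *gaps* (total open area above 200 m²) are a canopy
property, not derivable from elevation, so they enter as a quadrat mask
and by default override the topographic class, keeping the six categories
a partition; the non-overriding variant is available because testing gaps
alongside topographic classes is also defensible.

## Torus-translation tests

The association statistic is relative density
`(n_sh / n_s) / (a_h / A)` — the species' share of stems in a habitat over
the habitat's share of plot area. Its null distribution comes from
relocating the habitat map, not the stems, so within-species clustering is
preserved: every toroidal translation of the quadrat lattice, combined
with the four symmetries (identity, mirror, mirrored rotation, 180°
rotation) and excluding the untranslated original, gives `4N - 1` maps for
`N` quadrats — 1999 on the 25 × 20 lattice of a 500 × 400 m plot. A
seeded random-map null (region growth from one random seed quadrat per
habitat, preserving habitat areas and contiguity) is provided as an
alternative, since "randomly seeded maps" admit several constructions.
Tail probabilities use the add-one rank rule with ties counted as extreme,
and a habitat is labelled positive (negative) when its upper (lower) tail
probability is at most α/2 with α = 0.05; this tail-based labelling is
what makes the documented invariant "positive implies upper tail ≤ α/2"
hold exactly.

On very small lattices some generated torus maps coincide as label
arrays; the test nevertheless uses all `4N - 1` of them, which keeps the
null distribution exchangeable.

## Pair-correlation analysis

The univariate pair-correlation function `g11(r)` is estimated from the
neighbourhood density `O11(r)` — the mean density of further conspecific
stems in rings of radius `r` and width `dr` centred on each stem — as
`g11 = O11 / lambda1`. The bivariate `g12(r)` uses rings around species 1
and counts species 2, normalised by `lambda2`; it is computed separately
for both orders because interactions need not be symmetric. Rings are 2 m
wide with centres at 1, 3, ..., 49 m, matching the 2 m working resolution;
bins are half-open `[r - w/2, r + w/2)`.

Edge effects are removed geometrically: each count is divided by the
exact area of its ring clipped to the rectangular window, computed in
closed form from circular-segment geometry (`annulus_area_in_window()`).
This exact disc–rectangle correction is used instead of a
nearest-neighbour-style correction because it is well defined for ring
counts and directly testable against Monte-Carlo areas; for interior
stems it reduces to the full annulus area. Rings with zero clipped area
(impossible for the geometries used here) would be excluded from the
average rather than counted as zero. Distances are exact Euclidean
distances; grid-based implementations that count cells instead can differ
in the last digits.

## Null models, envelopes and the GoF test

Complete spatial randomness (`simulate_csr`) places `n` points uniformly.
The heterogeneous Poisson null (`simulate_hpp`) draws points from an
intensity surface estimated with the radial Epanechnikov kernel,
bandwidth `h = 30` m on a 2 m grid, edge-corrected by the kernel mass
inside the window and renormalised to integrate to `n`. Smoothing at 30 m
erases structure below the bandwidth while keeping the larger-scale
intensity trend, so departures from this null isolate small-scale
interactions — the separation-of-scales argument. Simulations condition
on the observed point count (rather than drawing Poisson counts) so the
null patterns are directly comparable to the data; the unconditional
variant would only widen envelopes slightly.

Pointwise envelopes take the 5th highest and 5th lowest of 199 simulated
functions per distance, a nominal two-sided level of
`2k/(m+1) = 0.05`. Because one test is run per distance, overall
significance is guarded by a goodness-of-fit rank test: for the observed
function and every simulation, the squared deviation from the
leave-one-out mean of all other functions is summed over 0–30 m (the
scales the heterogeneous Poisson null constrains), and the observed
statistic's add-one rank gives the p-value, ties counted as extreme. The
observed function is included in the leave-one-out pool, which is what
makes the p-value exactly discrete-uniform under exchangeability — a
property the test suite checks directly.

For a species pair, species 1 stays fixed and only species 2 is
redistributed, from an intensity surface built on species 2's own
pattern, so the null keeps both species' large-scale structure. A pair is
labelled positive ("p") or negative ("n") only when the GoF test rejects
over 0–30 m *and* the observed `g12` leaves the envelope at some ring
within the 0–5 m association window; the excursion's direction at the
smallest such ring sets the sign, and everything else is "r" (random).
The combination rule (GoF gate + smallest-bin sign) is a design choice —
published analyses of this kind report the labels without spelling the
rule out — and both gated and ungated per-scale counts are available from
`tabulate_by_scale()`.

## The synthetic study system

No census of this kind is public at stem level, so the package generates
one with known ground truth (`generate_community()`):

* **Terrain** — base elevation + linear trend + Gaussian hills sampled at
  the 20 m quadrat corners. The default parameters were chosen once so
  that the relief spans roughly the documented 705–870 m, the highest
  ground sits in the north-west, and every topographic class occupies at
  least 5% of the 25 × 20 lattice; gaps are added as a few
  contiguous random patches (25 quadrats by default).
* **Species** — Thomas cluster processes: parents placed uniformly and
  thinned by per-habitat intensity multipliers, offspring displaced by an
  isotropic Gaussian (sd `sigma`) and redrawn until inside the window
  (which keeps requested counts exact; for `sigma` beyond twice the
  window diagonal the exact uniform limit is used instead). Default
  abundances, treelet flags and habitat-affinity signs follow the
  published twenty-species table shipped in `extdata`; multipliers are 4
  (positive) and 0.25 (negative), effect sizes picked once to be
  detectable at 200 stems per pattern.
* **Life stages** — DBH is lognormal, truncated at the 1 cm census
  minimum; the smallest diameters go to sapling positions, the largest to
  adult positions, and final stage labels are assigned by running the
  package's own threshold classifier on the generated census. Requested
  totals are exact; per-stage counts are approximate because the
  classifier's `D95_0.1` is an emergent property of the drawn DBH sample.
  Poles and adults are subsampled from a larger offspring pool with
  retention probability `exp(-c * local density)` (`c` = 0.08 and 0.25
  per neighbour within a ~15 m block), so clumping declines across
  stages as under density-dependent thinning.
* **Pair coupling** — attraction by letting the second species share a
  fraction of the first's parents (genuine small-scale cross-correlation);
  repulsion by redrawing second-species stems that fall within a
  cross-species hard-core radius of the first. A pair may have one or the
  other, never both.

What the generator does **not** emulate: dispersal mechanisms, demographic
dynamics, interactions of more than two species, anisotropy, and any
correlation between DBH and location beyond the stage structure. Passing
recovery tests therefore show that the pipeline detects the statistical
signatures it targets, not that real forests behave like Thomas processes.

A note on detectability: a small hard core between two *strongly
clustered* sparse species is nearly invisible, because the heterogeneous
Poisson null reproduces their cluster segregation and the species barely
mingle anyway. The repulsion validation pair is therefore weakly
clustered and denser (400 stems each, 200 parents, 20 m dispersion) —
under those conditions a 5 m hard core is detected essentially always,
which is the honest statement of what the method can and cannot see.

## Numerical choices and problem sizes

* Ring areas: closed-form circular-segment geometry, exact to rounding;
  checked against 10⁶-sample Monte-Carlo areas at 3 standard errors.
* Kernel edge mass: 48-ring quadrature of the Epanechnikov profile using
  the exact clipped-disc areas, self-normalised so interior cells are
  exactly 1.
* Seeds: every task seed is derived from a master seed and the task
  labels (`derive_seed()`), so serial and parallel runs agree and all
  results are bit-for-bit reproducible.
* The calibration experiments use 500 replicates (envelopes) and 400
  replicates (GoF) of 100-point patterns in a 200 × 200 m window — large
  enough that the binomial error on a 5% rate is about ±1%, small enough
  to run in minutes. Recovery experiments use 50 replicates (Thomas
  dispersion), 25 (habitat affinity) and 15 each (coupling signs); the
  analysis drivers default to a 10%-scale community for the same reason.

## Known limitations

* The exhaustive torus null yields `4N - 1` maps; published torus tests
  sometimes report other counts depending on lattice resolution and the
  variant set, so exact map counts are a property of the lattice, not a
  constant.
* The GoF statistic weights all rings in 0–30 m equally; a strictly
  small-scale signal is diluted and, at low intensity, can fail the gate
  while still leaving the envelope (visible in the repulsion example
  above).
* Relative-density tests ignore within-species clustering when judging
  habitat association (no cluster-level correction); the torus null keeps
  clustering in the observed statistic but its significance is still
  per-habitat and two-sided.
* The intensity estimator conditions all analyses on a 30 m separation of
  scales; genuine interactions at ranges near or above the bandwidth are
  absorbed into the null.
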