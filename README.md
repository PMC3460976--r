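# forestspat

Spatial point-pattern analysis of stem-mapped forest census plots:
who grows where, with whom, and how that changes as trees grow up.

Large forest-dynamics plots map every stem ≥ 1 cm DBH. Two families of
questions recur:

* **Habitat association** — is a species over- or under-represented in
  topographically defined habitats (valley, low-slope, high-slope,
  high-gully, high-plateau, gap), judged against the spatial structure of
  the habitat mosaic itself?
* **Spatial interactions** — is a species aggregated or regular at small
  scales, does aggregation fade from saplings to poles to adults (the
  signature of density-dependent mortality), and do heterospecific pairs
  attract or repel at neighbourhood scales (the prediction of species
  herd protection)?

`forestspat` implements the full pipeline in base R with no spatial
dependencies:

* life-stage classification by DBH (saplings 1–5 cm, poles up to
  `D95_0.1` — the 95th percentile of DBH among stems ≥ 0.1 × the species
  maximum — adults above; treelets use a 3 cm sapling cutpoint) and
  importance values `IV = RD + RA + RF`;
* quadrat topography (mean elevation, slope, convexity) from a 20 m
  corner-elevation lattice, and the six-way habitat classification;
* Harms-style **torus-translation tests** of species–habitat association
  (all `4N − 1` toroidal translations × symmetries of the habitat map,
  plus a seeded random-map alternative);
* uni- and bivariate **pair-correlation functions**
  `g(r) = O(r) / λ` estimated from ring counts with *exact*
  disc–rectangle edge correction (closed-form circular-segment geometry);
* **heterogeneous Poisson null models** from Epanechnikov-kernel intensity
  surfaces (bandwidth 30 m, 2 m cells), Monte-Carlo **simulation
  envelopes** (5th extremes of 199 simulations, pointwise α ≈ 0.05) and
  the Loosmore–Ford style **goodness-of-fit rank test** over 0–30 m;
* pairwise association labels (p / n / r) for all ordered species pairs
  per life stage, per-scale attraction/repulsion counts and proportion
  summaries;
* a **synthetic community generator** (Thomas clusters with habitat-affine
  parents, lognormal DBH, stage-wise de-clustering, shared-parent
  attraction and hard-core repulsion) with known ground truth, so every
  stage of the pipeline is validated by parameter-recovery tests.

## Worked example

Simulate a small community with one attracting pair, then test the pair:

```r
library(forestspat)

spec <- community_spec(
  species = list(
    species_spec("S1", abundance = c(sapling = 200, pole = 0, adult = 0),
                 sigma = 5, mu = 10),
    species_spec("S2", abundance = c(sapling = 200, pole = 0, adult = 0),
                 sigma = 5, mu = 10)),
  coupling = data.frame(sp1 = "S1", sp2 = "S2",
                        share_frac = 0.8, inhibit_radius = 0),
  gap_quadrats = 0, seed = 33)
cm <- generate_community(spec)

rec <- analyze_bivariate(cm$census, "S1", "S2", stage = "sapling", seed = 1)
rec$gof$p
#> [1] 0.005
rec$label
#> [1] "p"
head(cbind(rec$pcf[c("r", "g")], rec$envelope[c("lower", "upper", "flag")]), 3)
#>   r        g    lower     upper  flag
#> 1 1 20.21657 1.684714 10.950642 above
#> 2 3 22.18207 2.807857  8.704356 above
#> 3 5 19.79408 3.091413  8.327745 above
```

The two species share 80% of their cluster parents, and the analysis
recovers exactly that: the cross pair-correlation `g12` lies far above
its heterogeneous-Poisson envelope at 1–5 m, the 0–30 m goodness-of-fit
test rejects (smallest attainable p = 1/200 with 199 simulations), and
the pair is labelled "p" (positive small-scale association).

The `analysis/` directory chains the full workflow on a twenty-species
synthetic plot (`01_simulate_community.R` … `06_summaries.R`), writing
its tables under `results/`.

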