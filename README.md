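# invasinet

Analysis of the roles of non-native species in binary bipartite
mutualistic networks (plant–pollinator and plant–seed-disperser webs),
for community ecologists studying biological invasions and network
robustness.

Established non-natives tend to be generalists. If they occupy central
network positions — many partners, short paths to other species, large
shares of the interactions that well-connected natives receive — their
presence adds redundant links (supporting the persistence of network
*function* through disturbance) while leaving specialist natives as
exposed as ever. `invasinet` implements the complete pipeline for
testing this on a collection of networks:

* an annotated incidence-matrix data model (`InteractionNetwork`,
  rows = plants, columns = animals, per-species `native`/`nonnative`
  flags, study metadata) with CSV/TSV readers, writers and validation;
* species-level metrics — degree, normalized degree `k / n_opposite`,
  shortest-path betweenness and component-scaled closeness on the
  one-mode projections, and the binary Pollination Service Index
  `PSI_j = Σ_{i∈P(j)} (1/d_i) (1/d_j)^β`;
* network-level metrics — connectance `L/(I·J)`, mean links `L/(I+J)`,
  generality and vulnerability (simple or degree-weighted
  `Σk²/Σk`);
* removal experiments — natives-only networks, matched random-removal
  controls, and fixed-dimension fixed-fill null models (1000
  replicates, empty-margin rejection, optional curveball alternative);
* secondary-extinction accounting — one-step counts after targeted
  removal and Monte-Carlo random-loss curves with expected counts at a
  given number of removals;
* statistics — paired two-tailed t-tests across networks for each
  metric and contrast, and mixed-effects models
  `metric ~ origin + level + (1 | study)` for species-level contrasts;
* a synthetic-network generator (heavy-tailed native core, generalist
  non-natives preferentially attached to well-connected natives, and
  an exactly exchangeable null regime) so the whole pipeline is
  testable without external data.

## Worked example

```r
library(invasinet)

net <- toyNetwork()   # 3 plants x 3 animals, animal A1 non-native
net
#> InteractionNetwork 'TOY3' (pollination, study 'toy-study')
#>   3 plants x 3 animals, 6 links (connectance 0.667), 1 non-native

networkMetrics(net)[, c("connectance", "mean_links", "generality", "vulnerability")]
#>   connectance mean_links generality vulnerability
#> 1   0.6666667          1          2             2

psiIndex(net)
#>        A1        A2        A3
#> 0.6111111 0.4166667 0.3333333

removeNonnatives(net)
#> RemovalResult: removed 0 plant(s), 1 animal(s); 1 orphaned; excluded = FALSE

secondaryExtinctions(net, "A1")
#> [1] 1
```

Removing the supergeneralist non-native A1 leaves plant P2 partnerless:
one secondary extinction. A1's PSI of 0.611 (= 11/18) reflects that the
network's plants depend on it far more than on the other animals.

The same machinery scales to a collection; here a small synthetic
invaded ensemble (non-natives three times as generalist as the average
native, attached preferentially to well-connected natives):

```r
coll <- generateCollection(synthConfig(gamma = 3, alpha = 1, rngSeed = 1),
                           nNetworks = 12)
report <- runStudy(coll, nullReps = 200, extinctionReps = 200, rngSeed = 1)
report
#> StudyReport: 12 networks (0 excluded), seed 1
#> Paired network-metric comparisons (full vs natives-only):
#>         metric     mean_a     mean_b        t df p_two_tailed
#>    connectance 0.07422931 0.06229167 12.78451 11 6.051458e-08
#>     mean_links 1.59593023 1.24583333 18.04698 11 1.604522e-09
#>     generality 3.19186047 2.49166667 18.04698 11 1.604522e-09
#>  vulnerability 3.19186047 2.49166667 18.04698 11 1.604522e-09
#> Secondary extinctions: targeted 0.000 vs random 1.799 (t = -36.054, p = 8.995e-13)

compareSpeciesMetrics(coll, "normalized_degree")
#> Mixed model for normalized_degree: origin (nonnative - native) = 0.0768 +/- 0.0062 (t = 12.398, p = 5.314e-33)
#>   1032 observations, 6 studies; study variance 0
```

Full networks carry more links per species and higher generality and
vulnerability than their natives-only reductions, non-natives exceed
natives in normalized degree, and targeted non-native removal orphans
far fewer species (0.00 per network) than matched random removal
(1.80 per network) — the redundancy signature. Note that on this
homogeneous ensemble connectance is *higher* for full networks; the
methods vignette (`vignettes/invasinet-methods.Rmd`) explains why that
contrast's direction depends on ensemble size heterogeneity, along with
every other modeling choice and limitation.

Small example input files in the package's text formats are in
`inst/extdata/` (`toy3.csv`, `toy3_nativity.csv`); see
`?readIncidenceCSV` for the conventions.

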