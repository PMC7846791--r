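# frontassembly

Community assembly and functional diversity of eukaryotic phytoplankton
across a tidal front, from metabarcoding OTU tables.

Tidal fronts separate vertically mixed coastal water from stratified
offshore water and are suspected hotspots of plankton diversity. Given a
sample x OTU read-count table (with season / station / depth / size-fraction
/ replicate metadata), a rooted phylogeny of the OTUs, a mixed-type trait
table and per-sample hydrography, this package answers the questions such a
survey poses:

- **Who is there, and where?** Phototroph filtering, richness, analytic
  rarefaction and Chao1, shared vs station-specific OTUs, abundant / low /
  rare classes (> 0.1%, 0.1–0.01%, < 0.01% of seasonal reads), and an
  OTU-connectivity network (edge weight = OTUs shared between station ×
  season groups) with a curated-richness control.
- **Which processes assemble the communities?** For every sample pair, the
  β-mean-nearest-taxon distance
  `βMNTD(A,B) = ½[ mean_{i∈A} min_{j∈B} d(i,j) + mean_{j∈B} min_{i∈A} d(i,j) ]`
  on cophenetic distances d, its standardized effect size
  `βNTI = (βMNTD_obs − mean βMNTD_null)/sd βMNTD_null` over tip-label
  shuffles of the regional-pool tree, and the Raup-Crick index
  `RC ∈ [−1,1]` from richness-preserving null communities. Pairs are
  classified as Homogeneous/Variable Selection (βNTI < −2 / > 2), Dispersal
  Limitation / Homogenizing Dispersal (RC > 0.95 / < −0.95), or Ecological
  Drift.
- **What drives selection?** PERMANOVA (sequential sums of squares, raw
  permutation) of the βMNTD matrix against temperature, NOx, ammonium,
  silicate and PAR, per size fraction, with and without temperature.
- **Does taxonomic diversity translate into functional diversity?** Gower
  distance over 12 morphological/trophic traits, PCoA, convex-hull
  functional richness normalized to the global pool (FRic ∈ [0,1]), and
  complete-linkage clustering into 9 ecological strategies.

No external dataset is needed: a synthetic metacommunity generator
(`generate_metacommunity()`) reproduces the survey's design — 3 seasons × 5
stations (ocean → coast, with a frontal station receiving a nutrient pulse)
× ≤2 depths × 3 size fractions × 3 replicates — with phylogenetically
heritable niches and traits and tunable selection, dispersal and drift,
including five scenario presets whose generating process the pipeline should
(and, in the tests, does) recover.

## Worked example

Simulate a metacommunity assembled under homogeneous selection and ask the
null models which process dominates:

```r
library(frontassembly)

sim  <- generate_metacommunity(scenario_config("homogeneous_selection", seed = 1))
res  <- assembly_analysis(sim$otu, sim$tree, n_null = 999, seed = 1)
summ <- process_summary(res, sim$otu$metadata)
summ$counts
#>  HomogeneousSelection     VariableSelection   DispersalLimitation
#>                   149                     0                    16
#> HomogenizingDispersal                 Drift
#>                     0                    25

head(res[, c("sample_a", "sample_b", "bmntd_obs", "null_mean", "bnti", "rc", "process")], 3)
#>            sample_a          sample_b bmntd_obs null_mean       bnti          rc process
#> 1 July|O1|surface|1 July|O1|surface|2 0.6895171 0.8551395 -0.8708719  0.82482482   Drift
#> 2 July|O1|surface|1 July|O1|surface|3 0.5691228 0.8361873 -1.4815044  0.88888889   Drift
#> 3 July|O1|surface|2 July|O1|surface|3 0.4024395 0.5400471 -0.9862327 -0.02802803   Drift
```

149 of 190 sample pairs (78%) are classified as homogeneous selection — the
process that generated the data. Each row reports the observed phylogenetic
turnover for a pair, the mean of its 999 tip-shuffle nulls, the standardized
effect size βNTI, the Raup-Crick index and the resulting label.

The full survey-scale analysis is the numbered scripts under `analysis/`
(simulate → diversity → connectivity → assembly → PERMANOVA → functional
diversity); each prints what it found and writes its tables under
`results/`.

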