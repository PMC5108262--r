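# prwr: predicted rarity-weighted richness for site prioritization

Conservation planners rarely have species inventories for more than a
fraction of a planning area, yet site prioritization needs a score for
every site. `prwr` implements **predicted rarity-weighted richness**: score
the inventoried sites by rarity-weighted richness, model that score from
freely available environmental covariates, predict it landscape-wide, and
rank all sites by the prediction. The package also measures how much
species representation such a ranking actually buys, against optimal and
random baselines, and ships a virtual-landscape simulator so the whole
chain is testable without external data.

It is aimed at conservation scientists and biodiversity informaticians
working with site-by-species incidence data (inventory plots or atlas grid
cells) plus site covariates (climate, productivity, topography).

## The quantities

* **Rarity-weighted richness.** With `c_i` the number of sites occupied by
  species *i*, a site scores `RWR = Σ 1/c_i` over the species present. Rare,
  range-restricted species dominate the score; abundance is ignored. Summed
  over sites, RWR equals the number of occupied species.
* **PRWR.** A 500-tree random-forest regression of the inventoried subset's
  RWR on covariates (one representative covariate per Kaiser-significant
  PCA component), predicted for every site. Training sites receive
  out-of-bag predictions, so PRWR never secretly reuses the species data.
* **Species Accumulation Index.** Accumulating sites in PRWR order, with
  `S` species represented in the top sites, `O` the optimum for equally
  many sites (greedy maximum coverage, exhaustively verified on small
  instances) and `R` the exact hypergeometric expectation for random
  selection: `SAI = (S − R)/(O − R)`. 1 = as good as optimal selection,
  0 = no better than random, negative = worse than random. SAI is averaged
  over the top 5–50% of the landscape and summarized over 100 random
  inventoried subsets per inventory fraction q, with 95% percentile
  confidence intervals.

## Worked example

```r
library(prwr)
land <- simulateLandscape(landscapeSpec(nSites = 400, nSpecies = 150, seed = 7))
occ <- land$occ; env <- land$env
occ
#> OccurrenceMatrix: 400 sites x 149 species; 3510 presences
#>   occupancy c_i: min 1  median 11  max 167

computeRWR(occ)
#> RWR scores for 400 sites: min 0, median 0.2104, max 5.054

pca <- pcaFactors(env)
pca
#> PcaResult: 18 components, 6 retained (eigenvalue > 1)
#>   leading eigenvalues: 4.93, 3.64, 2.87, 2.60, 1.79, 1.55
ps <- selectPredictors(env, pca)
ps
#> PredictorSet: 6 variables
#>   PC1 -> var16 (|r| = 0.707)
#>   PC2 -> var01 (|r| = 0.743)
#>   ...

cfg <- experimentConfig(qValues = c(10, 20, 40), nReplicates = 20L,
                        masterSeed = 42L)
res <- sweepSAI(occ, env, cfg)
res
#> SaiSummary: 20 replicates per q
#>   q mean_sai  ci_low ci_high significant
#>  10    0.199 -0.3038   0.621       FALSE
#>  20    0.414  0.0211   0.611        TRUE
#>  40    0.565  0.2306   0.676        TRUE
```

Read: with inventories for 20% of this 400-site landscape, ranking sites by
PRWR captures about 41% of the improvement over random site selection that
full knowledge of species occurrences would give, and the effect is
distinguishable from zero; at 10% it is not yet reliable at this landscape
size. `plotSAI(res)` draws the SAI-versus-q figure with CI bars;
`writeSweepReport(res, "report.csv")` writes the table.

Real data enter through `readOccurrences()` (long `site_id,species_id`
records or a wide 0/1 table) and `readEnvironment()`; `alignSites()` puts
them on a common site set.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/prwr.R simulate --sites 1000 --species 300 --seed 7 --out data/
Rscript inst/cli/prwr.R sweep --occurrences data/occurrences.csv \
    --env data/environment.csv --q 5:60:5 --replicates 100 --seed 42 --out out/
```

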