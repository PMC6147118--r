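# sizeweb

Individual trait-based analysis of quantitative bipartite flower-visitor
networks.

## What it does, and for whom

Pollination ecologists usually summarize bee-flower communities as
species-by-species visit matrices.  `sizeweb` is for studies that measure
the *individuals* instead: every observed visit carries the bee's
intertegular distance (ITD, mm) and the flower's display size (FDS, mm),
and calibration specimens link those proxies to the traits that actually
mediate the interaction -- proboscis length (PL) and nectar holder depth
(NHD).  The package

* imputes PL from ITD (one pooled OLS regression) and NHD from FDS (one
  regression per plant species, with a fixed 1 mm depth for open flowers);
* clusters the interacting individuals into **functional-size nodes** by
  average-linkage (UPGMA) clustering on the 1-D trait, either
  *constrained* (k = number of species, for a like-for-like comparison) or
  *unconstrained* (k chosen by a five-index cluster-validity vote);
* builds quantitative bipartite networks (visit counts, never binarized)
  on species nodes and on trait nodes;
* compares them with weighted connectance `Cq`, weighted nestedness
  `WNODF` (0-100), interaction evenness `IE`, specialization `H2'` and
  node-level `d'` and strength, where for a plant node `i` with row total
  `A_i`, the dependency of `i` on bee node `j` is `a_ij / A_i` and the
  bee's strength is `st_j = sum_i a_ij / A_i`;
* tests metrics against fixed-margin (Patefield / `r2dtable`) ensembles,
  and nestedness against CRT/CCT/RCTA marginal-conserving nulls with an
  adaptive ensemble, reporting z-scores and empirical p-values;
* ranks nodes by normalized degree, closeness and betweenness centrality;
* ships a seeded synthetic-community generator
  (`simulate_community(meadow_preset())`) so the full pipeline is testable
  without field data.

See `vignettes/trait-based-networks.Rmd` for the model, the numerical
choices and the generator's known limits.

## Worked example

```r
library(sizeweb)
ds <- simulate_community(meadow_preset(seed = 7))   # 272 records
models <- fit_trait_models(ds)
print(models$bee)
#> trait model [bee/pooled]: response = 1.5870 * predictor + -0.7982  (R2 = 0.946, n = 140)

rec <- predict_functional_traits(ds, models)
net <- build_species_network(rec)
print(net)
#> quantitative bipartite network: 10 plant x 23 bee nodes, 272 interactions

print(network_metrics(net))
#> P = 10, A = 23, m = 272
#> Cq = 0.129  WNODF = 27.092  IE = 0.660  H2' = 0.442
#> d_prime_bee     0.326 +/- 0.167
#> d_prime_plant   0.393 +/- 0.129
#> strength_bee    0.435 +/- 0.625
#> strength_plant  2.300 +/- 2.003

ens <- null_distribution(net, wnodf, "r2dtable", n = 1000, seed = 7)
zscore_test(wnodf(as.matrix(net)), ens)
#> observed 27.0917 vs null 47.3406 +/- 3.3190 (n = 1000): z = -6.10, p = 0.001998
```

Reading the numbers: only 23 of the 28 simulated bee species were observed
in 272 records (rare species are missed, as in real transects).  `Cq`
near 0.13 says each node effectively uses about 13% of the available
partners once visit frequencies are weighted; `H2' = 0.44` is moderate
network-wide specialization; and the observed WNODF of 27.1 is far *below*
the fixed-margin null expectation (z = -6.1), i.e. this size-matched
community is significantly **less** nested than random tables with the
same margins -- size matching produces complementarity, not hierarchy.

The whole comparison (species vs constrained vs unconstrained trait
networks, with null tests and centrality) is one call:

```r
report <- run_pipeline(pipeline_config(sim = meadow_preset(seed = 7), seed = 7))
compare_networks(report)
```

A thin CLI wraps the same stages (see `?sizeweb_cli`):

```sh
Rscript -e 'sizeweb::sizeweb_cli()' simulate --out data/ --seed 2
Rscript -e 'sizeweb::sizeweb_cli()' run --preset meadow --seed 2 --out report.json
```

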