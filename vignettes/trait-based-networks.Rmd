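---
title: "Individual trait-based bipartite networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual trait-based bipartite networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeweb)
```

## The problem and the approach

Classical plant-pollinator networks use species as nodes, which averages
away the variation among conspecific individuals.  When the traits that
mediate an interaction are *sizes* -- how deep a flower's nectar sits, how
long a bee's proboscis is -- that averaging can hide the mechanism that
actually structures the community.  `sizeweb` implements the alternative:
cluster the *individually measured* interacting partners into
functional-size nodes, build quantitative bipartite networks on those
nodes, and compare them with the species-based network built from the very
same records.

The workflow has five stages.

1. **Trait imputation.**  Two field-measurable proxies stand in for the
   functional sizes: intertegular distance (ITD, mm) predicts proboscis
   length (PL) through one pooled ordinary-least-squares regression across
   all bee specimens, and floral display size (FDS, mm) predicts nectar
   holder depth (NHD) through one regression per plant species.  Open
   flowers whose depth is effectively unmeasurable are assigned exactly
   1 mm.  Negative extrapolations are clamped at 0.1 mm with a warning so
   downstream 1-D distances stay meaningful.
2. **Clustering.**  Each side is clustered separately on its single
   functional size trait (NHD for flowers, ITD for bees) by average-linkage
   (UPGMA) agglomeration on 1-D Euclidean distances.  The *constrained* cut
   uses k = the number of species on that side, so network dimensions match
   the species network; the *unconstrained* cut picks k by a
   cluster-validity vote (below).
3. **Network construction.**  Cell `a_ij` is the visit count between plant
   node `i` and bee node `j`; weights are never binarized.  Nodes are
   ordered by ascending mean member trait.
4. **Metrics.**  Weighted connectance `Cq` (Bersier-style entropy-based
   linkage density over total nodes), weighted nestedness `WNODF`,
   interaction evenness `IE`, network specialization `H2'`, and node-level
   `d'` and species strength.
5. **Inference.**  Fixed-margin (Patefield) null ensembles give z-scores
   and empirical p-values for `Cq`, `IE` and `H2'`; nestedness is tested
   against three marginal-conserving nulls (CRT, CCT, RCTA) with an
   adaptive ensemble; normalized degree, closeness and betweenness rank
   key nodes.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| depth floor for open flowers | 1.0 | mm | shallow nectaries cannot be measured reliably; a fixed small depth |
| prediction clamp | 0.1 | mm | keeps extrapolated sizes positive |
| linkage | average (UPGMA) | -- | mean pairwise distance respects 1-D contiguity |
| `k_range` for optimal k | 2..min(15, n-1) | -- | parsimony bound for community-scale data |
| IE denominator | `log(P*A)` | -- | the common software default; `realized_links` available |
| null ensemble `n` | 1000 | draws | stable z at two decimals |
| adaptive nestedness policy | start 500, double, stop at \|dp\| < 0.005 or 10000 | draws | avoids undersampling without a fixed oversized ensemble |
| kernel width `sigma_match` | 0.5 | mm | on the order of within-species trait SD: a proboscis may miss the depth by about one SD before visits become unlikely |
| matching strength `lambda` | 1 | -- | the generator's stated world is fully size-driven; set 0 for random mixing |

## Numerical choices

* **Effective partners** in `Cq` use base-2 entropy with `2^H`; all other
  entropies are natural-log Shannon forms, mirroring the sources that
  introduced each index.
* **WNODF variant.**  Rows and columns are ordered by decreasing *weighted*
  marginal totals (stable sort), and an ordered pair contributes 0 unless
  the upper total is strictly larger.  Other implementations (e.g. the
  `vegan` engine used by much published software) order and gate pairs on
  *binary fill* instead; the two variants agree on fully nested and
  equal-margin matrices but not in general, so published WNODF values
  should not be expected to match digit-for-digit.
* **`H2'` and `d'` extremes** come from the published greedy heuristics:
  the minimal-entropy table fills the largest remaining margins first;
  `dmax` allocates a node's visits to the rarest partners first (capped by
  their totals) and `dmin` is the largest-remainder rounding of the
  proportional allocation.  These are heuristics, not exact integer optima;
  the test suite checks them against independent naive reimplementations
  on small matrices.
* **UPGMA ties.**  Repeated trait values produce exactly tied merge
  heights; candidates are resolved toward the pair whose members carry the
  lowest original indices, so identical inputs always give identical trees
  (the reason the tree builder is implemented in-package rather than
  delegated to `stats::hclust`, whose tie order is unspecified for this
  purpose; on tie-free data the two agree exactly, which the tests assert).
* **Validity-index panel.**  Instead of a 30-index battery, `optimal_k()`
  votes over five classical indices -- silhouette, Calinski-Harabasz,
  Davies-Bouldin, Dunn, C-index -- with ties broken toward the smallest k.
  The panel is small enough to reason about and covers the three main
  index families (separation/compactness ratios, variance ratios, rank
  statistics).
* **z conventions.**  `zscore_test()` returns the standard
  `z = (obs - mean)/sd` and `z_reversed = -z`, because some reports print
  the reversed sign (positive meaning *below* the null mean).  Empirical
  p-values use `(r + 1)/(n + 1)` add-one smoothing.
* **RCTA.**  The weighted "row-column total average" null is implemented as
  one multinomial of all `m` interactions with cell probability
  `(A_i/m + B_j/m)/(P + A)`; only `m` is conserved.  This is a documented
  choice among the possible weighted readings of that model.

## What the synthetic generator emulates -- and what it does not

`simulate_community()` draws individual bees (species by relative
abundance, ITD truncated-normal, PL from the shared linear link plus
noise) and flowers (FDS, NHD from per-species links, or exactly 1 mm for
floor species), then accepts candidate pairs with probability
`(1 - lambda) + lambda * exp(-(PL - NHD)^2 / (2 * sigma_match^2))`.
The `meadow_preset()` fixes the stated world: 10 plant species (4 with the
floor), 28 bee species, NHD spanning 1-10 mm, ITD 1.4-6.4 mm, 272 records,
geometric rank-abundances (ratios 0.8/0.85, so a few species dominate as
in real transect data), within-species ITD SD of 7% of the mean.

The generator reproduces the *data shape* the pipeline consumes:
regression-recoverable trait links, a floor class, skewed abundances, and
seeded determinism.  It deliberately omits phenology, spatial structure,
observation bias, and -- importantly -- any species-level preference
beyond size.

That last omission has a measurable consequence worth understanding.  In
the generator's world the species partition is nothing but a noisy
blurring of the size partition, so the constrained trait-based network is
always at least as *informative* about the true (size-driven) niche as the
species-based one: across the 100 preset replicates run in
`test-acceptance.R` at `lambda = 1` the trait network shows **higher**
`H2'` (100/100) and **lower** WNODF (98/100) than the species network,
while field studies of this design report the opposite ordering.  The field pattern requires species to have
idiosyncratic partner preferences that size clustering then dissolves;
a symmetric mismatch kernel cannot produce it (an asymmetric
accessibility kernel was checked and does not either, because random
mixing over skewed abundances is itself strongly WNODF-nested).  The
corresponding end-to-end expectation in `test-acceptance.R` is therefore
left failing rather than weakened: a green run would require a generator
with species-level niche idiosyncrasy, which is outside the stated world.
Green tests here establish that every stage computes what it claims on
communities of realistic shape -- not that the generator reproduces every
qualitative field result.

## Known limitations

* Centrality is computed on the binary graph; weighted shortest-path
  variants are out of scope.
* Closeness for disconnected graphs uses component-size scaling
  (`(c-1)/sum(d) * (c-1)/(N-1)`); other normalizations exist and give
  different absolute values on fragmented networks.
* `H2'`/`d'` standardization depends on the greedy extremal tables; exact
  integer optima could shift third decimals on tiny matrices.
* The clustering operates on one trait per side by design; multi-trait
  niches need a different distance and are not supported.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = meadow_preset(seed = 7), seed = 7,
                       null_n = 200,
                       nestedness = list(enabled = FALSE))
report <- run_pipeline(cfg)
compare_networks(report)
```
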