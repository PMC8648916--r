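# guildnet

Co-occurrence network inference and temporal decomposition for microbial
time series in which the selection regime — *r*-selection (pulse feeding,
favouring fast-growing opportunists) versus *K*-selection (continuous
feeding, favouring high-affinity, high-yield competitors) — is switched
partway through the experiment. The package is aimed at microbial
ecologists analysing 16S OTU tables from such crossover microcosm designs,
and at anyone who wants a tested, scriptable implementation of the ReBoot
significance procedure with ground-truth validation.

## What it computes

**Noise-injected similarity.** For abundance vectors *x*, *y* the package
evaluates `f*(x, y) = f(x + εx, y + εy)` where *f* is the Pearson or
Spearman correlation and the ε components are i.i.d. `N(0, γ²)` with
`γ = s · x_min` (*s* the magnitude factor, `x_min` the smallest nonzero
abundance). The noise breaks double-zero patterns that otherwise produce
spurious correlations between rare OTUs.

**ReBoot significance.** For every unordered OTU pair the bootstrap
distribution of the similarity (samples resampled with replacement) is
compared with a permutation null (each OTU permuted across samples
independently; for relative abundances the permuted table is renormalized,
including the residual mass of OTUs excluded by the prevalence rule, to
preserve the compositional constraint). A two-sided z-test with
`z = (boot_mean − perm_mean) / perm_sd` yields p-values, adjusted into
q-values by the Benjamini–Yekutieli step-up procedure, which is valid
under arbitrary dependence. OTUs absent in more than `n·10^(−4/n)` of the
*n* samples are excluded from testing beforehand (the errthresh rule).

**Network and modules.** Edges are the top-*k* most significant pairs
(default 500) or all pairs below a q threshold; signs follow the z-value.
Modules are detected with the walktrap random-walk algorithm (walk length
20) on the positive-edge subgraph; nodes attached only by negative edges
stay unassigned.

**Temporal z-scores.** Per facet (selection group × resource supply),
each OTU's day means `x_{i,·,k}` are standardised with the population SD:
`z_{i,k} = (x_{i,·,k} − x_{·,·,k}) / σ_k`. Node colours (black/grey/orange
at z = ±1), node sizes `a + b·|z|` and edge colours (red/grey/blue at
z-product ±0.3) visualise each day's contribution to the network, and
`(1/N) Σᵢ z_{i,k} z_{i,l}` is exactly the Pearson correlation of the two
day-mean series (the Spearman correlation on the rank basis with one
replicate).

**Community level.** Bray–Curtis PCoA trajectories faceted by the current
regime, and sequential PERMANOVA on `1 − Spearman` dissimilarity
comparing selection group (first term) against current regime (second
term).

**Synthetic ground truth.** `generate_experiment()` simulates the 2 × 2
factorial crossover design (12 microcosms, 17 sampling days, switch
between days 28 and 29) with planted r/K guilds, AR(1) lognormal
dynamics, multinomial read sampling and total-density scalars, so module
detection can be scored against known guild membership via the adjusted
Rand index.

## Worked example

```r
library(guildnet)

cfg <- simulation_config(n_k_otus = 20, n_r_otus = 20, n_neutral_otus = 5,
                         depth = 20000, seed = 1)
sim <- generate_experiment(cfg)

run <- infer_cooccurrence_network(sim$counts, filter_level = "low",
                                  measure = "spearman", s = "low",
                                  iterations = 1000, k = 200, seed = 2)
run$network
#> # Co-occurrence network: 40 nodes, 200 edges (140 positive, 60 negative), 2 modules

guild_recovery_score(run$network$nodes, sim$truth)
#> [1] 1
```

The 200 most significant associations involve the 40 guild OTUs (the 5
neutral OTUs have no planted signal), split into 140 positive edges within
guilds and 60 negative edges between them; the two walktrap modules
reproduce the planted K/r partition exactly (adjusted Rand index 1).

```r
d <- spearman_dissimilarity(to_relative(sim$counts))
set.seed(3)
permanova_sequential(d, sim$metadata, permutations = 9999, days = c(28, 50))
#> # Sequential PERMANOVA (24 samples, 9999 permutations)
#>              term df    sum_sq  r_squared pseudo_f p_value
#> 1 selection_group  1 -0.006408 -0.0005119   -2.142   1e+00
#> 2  current_regime  1 12.460236  0.9954937 4165.903   1e-04
#> 3        Residual 21  0.062811  0.0050182       NA      NA
#> 4           Total 23 12.516639  1.0000000       NA      NA
```

At days 28 (just before the crossover) and 50 (the end point) the regime
active at sampling time explains essentially all community variance while
the selection *group* — the prehistory — explains none: the communities
converge to regime-specific configurations regardless of where they
started.

Plotting helpers: `autoplot(run$network)`, `plot_significance_curve()`,
`plot_ordination_trajectories()`, and `style_network_day()` +
`edge_z_products()` for the per-day styled snapshots.

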