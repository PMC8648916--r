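---
title: "Methods: co-occurrence inference for selection-switch time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence inference for selection-switch time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microbial communities under *r*-selection (pulsed resources) and
*K*-selection (continuous resources) assemble differently: opportunistic
fast growers dominate the former, high-affinity competitors the latter. In
a crossover design the regime is switched halfway (between days 28 and
29), so every microcosm experiences both regimes and one can ask whether
co-occurrence structure reflects current conditions or the community's
prehistory. guildnet implements the full analysis chain for such data:
association significance testing, signed-network module detection, per-day
z-score decomposition of the network, and community-level ordination and
variance partitioning — together with a generator of synthetic datasets
with planted guild structure, so every stage can be validated against
ground truth.

## The association model

For two OTU abundance vectors $x, y$ over $n$ samples, a similarity
measure $f$ (Pearson or Spearman correlation, average ranks for ties) is
evaluated after noise injection:
$$f^*(x, y) = f(x + \varepsilon_x,\; y + \varepsilon_y),\qquad
\varepsilon \sim \mathcal N(0, \gamma^2)\ \text{i.i.d.},\quad
\gamma = s\, x_{\min},$$
with $x_{\min}$ the smallest nonzero abundance in the working table and
$s$ the *magnitude factor* ($s = 0$ none, $1$ low, $10$ medium, $100$
high). Rare OTUs share long runs of zeros purely through detection
limits; the noise destroys those double-zero patterns while perturbing
genuinely abundant OTUs by far less than one count. For an absolute-scale
table the same rule is applied to that table's smallest nonzero value, so
the noise stays proportionally as small.

Significance follows the ReBoot logic. For each unordered pair:

* **bootstrap** — resample the $n$ samples with replacement, recompute
  $f^*$, repeat; record mean and SD;
* **permutation** — permute each OTU's values across samples
  independently, recompute $f^*$, repeat; record mean and SD. For
  relative abundances the whole permuted table (including the residual
  pool, below) is re-divided by its new per-sample totals first, so the
  null respects the compositional sum constraint. For absolute
  abundances renormalization is meaningless and requesting it is an
  error.
* **test** — $z = (\bar f_{\text{boot}} - \bar f_{\text{perm}}) /
  \mathrm{sd}_{\text{perm}}$, $p = 2\Phi(-|z|)$, and Benjamini–Yekutieli
  q-values over all testable pairs (the BY correction factor
  $c(m)=\sum_{k\le m} 1/k$ keeps FDR control under the strong dependence
  between pairs sharing an OTU).

Noise is drawn fresh inside every iteration — the noisy measure $f^*$ is
the unit being resampled — and the bootstrap and permutation phases use
independent iterations. One RNG stream drives the whole computation, so a
fixed seed reproduces results bitwise.

### Choice of the z denominator

Only "two-sided Z-test" is conventionally specified for ReBoot, which
leaves the denominator open: the permutation SD alone, or the pooled form
$\sqrt{\mathrm{sd}_{\text{boot}}^2 + \mathrm{sd}_{\text{perm}}^2}$. The
two differ materially. Under the null both the sampling SD of a
correlation and the permutation SD are $\approx 1/\sqrt{n}$, so the
pooled denominator is $\approx \sqrt{2}$ too large and the test becomes
strongly conservative: in simulation (20 independent uniform OTUs,
$n = 30$) the pooled form rejects at the 0.05 level for only ~0.6% of
pairs, while the permutation-SD form rejects for ~4.8% — the calibrated
behaviour a z-test should have. guildnet therefore defaults to
`variant = "permutation"` and exposes `variant = "pooled"` as an option
for users who want the conservative reading.

### The errthresh prevalence rule

With $n$ samples, an OTU absent in **more than** $n\cdot 10^{-4/n}$
samples is excluded from testing ("more than" is strict, so a zero count
exactly at the cutoff keeps the OTU — at $n = 202$ the cutoff is 192.996,
so 193 zeros exclude and 192 keep; at $n = 4$ it is 0.4 and any zero
excludes). Zeros are counted on the working table handed to association
testing (post-filter), the natural reading when the rule is applied at
testing time. The excluded OTUs' relative mass per sample is kept as the
*residual pool* and participates in permutation renormalization, so the
compositional total remains honest.

## Filtering and abundance scales

Counts are divided by per-sample totals (no other depth correction — the
totals are assumed informative, not artefactual), then OTUs whose
maximum relative abundance never reaches the threshold are dropped:
high $5\times 10^{-3}$, medium $10^{-3}$, low $5\times 10^{-4}$ (count
proportions). Optionally the proportions are scaled by per-sample total
cell densities (flow-cytometry-style estimates, cells/mL) to an absolute
scale; with equal densities this leaves all rank-based statistics
unchanged. The pipeline order is relative → max-abundance filter →
(optional absolute) → errthresh at association time.

## Network construction

Edges are selected either as all pairs with $q \le q_{\max}$ or as the
$k$ smallest-q pairs ($k = 500$ by default, ties broken by larger $|z|$
then lexicographic pair, the effective q of the last edge reported).
Edge signs follow $\mathrm{sign}(z)$. Walktrap community detection (walk
length `steps = 20`) runs on the positive-edge subgraph, unweighted by
default — no edge weights are part of the canonical procedure; a
$|z|$-weighted variant sits behind a flag. Nodes connected only by
negative edges never enter that subgraph and are reported unassigned
rather than forced into a module. Module ids are relabelled in
decreasing order of size so "module 1" is stable across runs; the
adjusted Rand index used for guild recovery and taxonomy concordance is
label-invariant anyway. Mean node abundance is exported from whichever
working table (relative or absolute) the network was built on.

## Temporal decomposition

Within one facet (selection group × resource supply), with
$x_{i,j,k}$ the abundance of OTU $k$ on day $i$ in replicate microcosm
$j$: the day mean $x_{i,\cdot,k}$ averages the replicates available that
day (missing replicates are dropped from the mean, not the day), the
series mean and the *population* SD ($1/N$, not $1/(N-1)$) standardise it,
$z_{i,k} = (x_{i,\cdot,k} - x_{\cdot,\cdot,k})/\sigma_k$. The population
form matters: it makes
$$\rho_{k,l} = \frac1N \sum_i z_{i,k}\, z_{i,l}$$
*exactly* the Pearson correlation of the two day-mean series (checked to
1e-10 in the tests), so the per-day products $z_{i,k} z_{i,l}$ decompose
each edge's correlation into daily contributions. Styling constants:
nodes are black/grey/orange for $z < -1$, $-1\le z\le 1$, $z > 1$
(bounds inclusive on grey), with size $a + b|z|$ ($a = b = 2$ display
units — purely cosmetic defaults, the rule's shape is what matters);
edges are red/grey/blue at z-product $\pm 0.3$, inclusive. A constant
series ($\sigma_k = 0$) yields flagged z-scores and a grey node of size
$a$ throughout.

For Spearman-based networks the decomposition runs on the **rank basis**:
each OTU's trajectory is ranked across the sampling days *within its
microcosm* before day means are taken. This definition (rather than
ranking OTUs within a sample) is the one under which the single-replicate
statement holds literally: with one replicate, $\rho_{k,l}$ equals the
Spearman correlation of the two trajectories, and all rank-basis outputs
are invariant under monotone transforms of the abundances.

## Community-level statistics

Bray–Curtis distances feed classical-scaling PCoA; axes with negative
eigenvalues (non-Euclidean distances) are dropped with a warning and
excluded from the proportion-explained denominator — no Cailliez/Lingoes
correction. Trajectory plots facet by the regime active at sampling time
and resource supply, joining each microcosm chronologically.

Sequential (Type I) PERMANOVA runs on $1-$Spearman dissimilarity of the
samples via `vegan::adonis2(by = "terms")`, selection group first and
current regime second, so the regime term is tested after prehistory has
taken whatever variance it can. Free permutations are used (no
microcosm-restricted scheme; the restricted alternative is a known
refinement but not part of the canonical procedure — noted as a
limitation). The defaults use 9,999 permutations, ample for the p-values
reported here; $10^6$ is supported for publication-grade precision. The
paper-mode restriction to days 28 and 50 (just before the crossover; the
end point) is exposed as `days = c(28, 50)`.

## The synthetic generator

`generate_experiment()` emulates the processed data of a selection-switch
microcosm study: 12 microcosms (2 selection groups × 2 resource supplies
× 3 replicates), 17 sampling days within 1..50 with the switch between
days 28 and 29, OTU baselines drawn lognormal (SD 1.5 log units, giving a
realistic rank-abundance curve and leaving some OTUs below the filtering
thresholds so the filters have work to do), guild effects of ±`guild_effect`
(default 2) log units under matching/opposing regimes, AR(1) temporal
noise (coefficient 0.5 — smooth trajectories without long-memory
artefacts — stationary SD 0.5), lognormal library sizes around
`depth = 60,000` reads (SD 0.3 log units, emulating realistic depth
variability without targeting any exact value), multinomial read
sampling, and total densities proportional to summed latent abundance
around $10^6$ cells/mL (halved under low supply). An optional
`disturbance` flag adds an extra shock on the first day and the first
post-switch day — the two instability periods such experiments show —
default off.

What the generator does *not* emulate: sequencing error and chimeras,
taxonomic structure, uneven taxon richness across guilds, environmental
covariates, and ecological interactions proper (the planted signal is
habitat filtering by regime, nothing else). Passing tests therefore show
that the pipeline recovers niche-driven co-occurrence structure planted
at realistic scale and noise — not that inferred edges on real data are
ecological interactions, nor that indirect-edge effects are handled (they
are deliberately out of scope).

## Problem sizes and numerical choices in the test-suite

The packaged checks run at desk scale, chosen as the smallest sizes at
which the statistical properties are stable: BY oracle comparisons on
1,000 random p-vectors; type-I calibration over 50 datasets of 20
independent OTUs at $n = 30$ with 200 iterations (9,500 pairs); power
over 50 runs of a planted Spearman > 0.9 pair at $n = 50$ with 1,000
iterations; full-pipeline guild recovery on 60 OTUs × 204 samples with
500 iterations and top-500 edges; PERMANOVA null calibration over 200
shuffled-label datasets at 999 permutations. Degenerate inputs are
flagged rather than fudged: constant vectors give `NA` similarity and
leave the testing family; zero pooled variance flags the pair; an
all-zero sample or a one-level factor is a hard error.

## Known limitations

* Correlation-based edges conflate direct and indirect associations; no
  conditional-independence correction is attempted.
* Compositionality is addressed only through permutation
  renormalization, not through a compositional estimator such as SparCC.
* Free permutations in PERMANOVA ignore the repeated-measures structure
  of microcosm time series; p-values for between-microcosm factors are
  anti-conservative in principle.
* The generator's guilds respond instantaneously to the regime switch;
  real communities lag.
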