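---
title: "Recurrent association networks from replicated microbial time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent association networks from replicated microbial time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mran)
```

## The problem

Cyanobacterial harmful blooms in eutrophic rivers and lakes are not the
doing of a single species: bloom formation, maintenance and collapse
involve the surrounding non-cyanobacterial community, which supplies
nitrogen, degrades cyanobacterial detritus, or attacks the bloom
outright. Co-occurrence networks built from amplicon time series are the
standard tool for mapping such interactions, but a network inferred from
a single time series is notoriously fragile: with a dozen or so monthly
time points, many "significant" correlations are site-specific noise.

`mran` implements a replication-based answer. When the same river is
sampled at several sites and depths, each (site, depth) series supports
its own association network, and only the associations that *recur*
across several of those independently inferred networks are trusted.
The merged result is the microbial recurrent association network (MRAN).
The package covers the full path: compositional data handling, lagged
local similarity analysis, per-series network construction, the
recurrence consensus, small-world topology against random baselines,
Louvain modules, Zi--Pi node roles, module seasonality, bloom-period
labelling, and collapse of taxa into functional groups.

## Local similarity with time lags

Each feature's series (OTU relative abundances and environmental
variables alike) is laid on a complete monthly grid. Interior gaps are
filled by linear interpolation on the month index. Leading and trailing
gaps have no two bracketing observations, so they take the nearest
observed value; this is a deliberate convention, recorded by the
`interpolated_mask`, and it only matters when a series starts or ends
with missing months.

Series are then rank-transformed to normal scores,
$\hat x_i = \Phi^{-1}\!\big(r_i/(n+1)\big)$, with average ranks for
ties. This makes the statistic invariant to any monotone transform of
the raw data -- important for abundances spanning orders of magnitude --
and gives a known marginal under permutation.

The local similarity (LS) score of two prepared series is the largest
partial sum of products over any contiguous aligned segment whose
offset (delay) is at most $D$ months, divided by $n$:

$$\mathrm{LS} = \frac{1}{n}\max_{|d| \le D}\; \max_{\text{segments } s}
\left| \sum_{i \in s} \hat x_i\, \hat y_{i+d} \right|,$$

computed by the usual pair of dynamic programs over positive and
negative running sums (`local_similarity_score()`, implemented in C++).
The sign of the optimum is the association's sign; the diagonal offset
is its delay (positive: the second series lags the first); the length
of the optimal chain is the alignment span that later feeds the
duration filter. Ties are resolved deterministically: smaller $|d|$
first, then positive sign, then the earliest alignment start. The
test suite holds the DP to an exhaustive enumeration of all aligned
segments on hundreds of random pairs.

The delay limit defaults to $D = 1$ month. Monthly sampling of a
fast-flowing river gives little support for longer memory, and the
consensus stage does not require member networks to agree on the delay,
only on the pair and sign, so $D$ mainly controls the search space.
It is a plain argument everywhere.

### Significance

P-values come from a permutation test: the time order of one series is
permuted, the LS score recomputed, and the add-one estimator
$p = (1 + \#\{\mathrm{LS}_{perm} \ge \mathrm{LS}_{obs}\})/(1 + n_{perm})$
reported. Whole-series permutation (no blocks) is the classical null
for this statistic and the honest choice at 15 time points, where block
permutation would leave almost no exchangeable units. The default
$n_{perm} = 2000$ makes the downstream screen $p < 0.001$ attainable
(the smallest reachable p is $1/2001$); `permutation_p_value()` warns
and flags refusal if asked to reach an unattainable level. One shared
permutation set per series-set scan keeps `all_pairs_lsa()`
deterministic and independent of pair enumeration order. Screening uses
raw p-values; a Benjamini--Hochberg `q` column is available behind
`fdr = TRUE` but off by default, matching the raw-p screening
convention of the field. Only permutation p-values are implemented;
no asymptotic approximation is offered.

A practical consequence of permutation testing on 15 monthly points:
at $\alpha = 0.001$ an association must essentially never be matched by
a permuted score, which requires a near-perfect monotone relationship.
The per-series networks are therefore sparse (a few percent of pairs),
and that is precisely why the recurrence consensus -- rather than any
single network -- carries the inference.

## Networks and the recurrence consensus

`build_network()` keeps associations with $p < \alpha$ (default 0.001)
whose alignment span is strictly longer than `min_span` months (default
6). "Strictly longer" operationalises a duration rule of *more than* 6
months on a monthly grid; the comparator is configurable.

`build_consensus()` counts, for every unordered pair *and sign*, the
number of member networks containing that edge. An edge enters the
consensus iff that count reaches `min_recurrence` (default 3 of 6).
Counting per (pair, sign) means a positive and a negative association
between the same two features never pool evidence -- sign conflicts are
evidence of instability, not support. Delay equality is *not* required
for recurrence: short noisy series can easily blur a true lag by a
month across sites, so the consensus records the modal member delay
instead (ties: smaller $|d|$, then positive). Environmental variables
participate exactly like OTU nodes.

The design intent is testable: in the synthetic study below, couplings
planted in all six series sets survive the $\ge 3/6$ filter while
couplings planted in exactly one set are provably removed (they cannot
reach a count of 3), yet contaminate the pooled union of single
networks. The acceptance checks assert both sides.

## Topology panel and the small-world coefficient

All topological metrics ignore sign (the positive-edge fraction is
reported separately) and run on the simple undirected graph via igraph:
mean local clustering $C$ (degree-$<2$ nodes contribute 0),
characteristic path length $L$ and diameter over connected pairs (with
a `disconnected` flag), density $2E/(N(N-1))$, mean neighbours $2E/N$,
degree heterogeneity (coefficient of variation of degree, population
variance) and Freeman degree centralization
$\sum_i (k_{max} - k_i)/((N-1)(N-2))$.

Random baselines are Erdős--Rényi $G(n, m)$ graphs with *exactly* the
observed node and edge counts (not $G(n, p)$ -- the comparison fixes
both sizes), averaged over `reps` replicates (default 100) with
Monte-Carlo standard errors. The small-world coefficient is
$\mathrm{SW} = (C/C_R)/(L/L_R)$; values above 1 indicate excess
clustering at comparable path length. A self-consistency check in the
test suite confirms that an ER draw measured against its own ensemble
yields $\mathrm{SW} \approx 1$.

One ambiguity is left documented rather than resolved: a printed
"ratio of positive/negative edge" near 0.9 can be read as the positive
fraction or as a pos:neg odds. The package reports the *fraction of
positive edges* and names it accordingly.

## Modules, roles, seasonality, blooms

Louvain modularity optimisation depends on vertex order, so
`louvain_partition()` shuffles vertices under a caller seed and is
reproducible given that seed. It runs unweighted on the unsigned graph
by default -- the consensus mixes positive and negative edges and no
signed-modularity method is implied by the workflow; LS weights can be
passed explicitly. Modules are labelled `M1, M2, ...` by decreasing
size, and "major" modules are the largest ones covering at least 85% of
nodes (configurable); on the real-data scale this rule reproduces a
handful of major modules covering most of the network.

Node roles use the within-module degree z-score
$Z_i = (k_{i,own} - \bar k_{own})/\sigma_{own}$ (population standard
deviation; $Z_i = 0$ when a module is degree-homogeneous, the
convention for the degenerate $\sigma = 0$ case) and the participation
coefficient $P_i = 1 - \sum_s (k_{is}/k_i)^2$. Thresholds $Z_i = 2.5$
and $P_i = 0.62$ classify peripherals, module hubs, connectors and
network hubs. `compute_roles()` is held to an independent brute-force
edge-count implementation, exactly, on hundreds of random graphs.

Module seasonality (`module_monthly_pattern()`) min-max scales each
non-cyanobacterial member OTU across *all* samples -- the global
feature-scaling reading, so that a module's profile reflects when its
members peak, not per-month renormalisation -- and averages over member
OTUs and the samples of each month. Constant series scale to zero.

Bloom labelling follows a two-clause rule with strict inequalities:
a sample is a bloom for a target cyanobacterial OTU when its relative
abundance exceeds 10% *and* chlorophyll-a exceeds 15 µg/L, or when the
OTU alone exceeds 80% of the community regardless of chlorophyll (the
dominance exception covers winter blooms of akinete-forming taxa whose
chlorophyll signal is weak). Both thresholds are arguments; the calls
record which clause fired, and labelling is monotone in both
thresholds.

## Functional collapse

`collapse_functions()` maps OTUs to functional groups through exact
taxon-string matching at any rank of the lineage (or by OTU id) against
a FAPROTAX-style map. A multi-function OTU contributes fully to every
function it matches (no fractional splitting); unmapped OTUs contribute
nowhere; a function with no mapped member present is an explicit zero
row. The per-module, per-month value is the summed abundance of mapped
member OTUs averaged over that month's samples -- the module's function
composition scaled by the module's total abundance. Because the exact
normalisation behind published heatmaps of this kind is ambiguous,
three display normalisations are provided (`none`,
`per_group_fraction`, `min_max_per_function`) and none is claimed to
reproduce any particular figure. The package ships a small toy map of
ten entries for tests and examples; a real FAPROTAX file is accepted as
an external input and is not redistributed.

## The synthetic study emulation

`generate_dataset()` exists so every downstream stage is testable
without sequencing data. Its defaults mirror the motivating study
design: 3 sites × 2 depths sampled monthly for 15 months (June to the
following August), with roughly a fifth of the sample-months missing
(69 of 90 possible), a few hundred prevalent OTUs in 5 planted modules,
and 11 environmental variables.

The generative model is a latent log-linear factor model closed to
compositions:

* **Module drivers.** Seasonal harmonics of the calendar month (annual
  sine and cosine, semi-annual terms, and so on), centred and
  *orthogonalised* over the sampled months, one per module; the first
  module adds a Gaussian summer pulse and is the cyanobacterial bloom
  module. Orthogonalisation is a deliberate design choice: planted
  module membership is only meaningful ground truth if distinct modules
  are statistically distinguishable; phase-shifted copies of a single
  annual cycle would be linearly dependent and would make the "true"
  partition unidentifiable.
* **Loadings.** Each OTU loads on its module's driver with magnitude
  `within_module_coupling` (default 0.8). A small minority
  (`neg_loading_fraction`, default 0.05) load negatively, which yields
  a consensus network that is roughly 90--95% positive edges -- the
  balance reported for freshwater co-occurrence networks.
* **Planted pairwise couplings.** Consecutive module members are paired;
  each pair shares lagged noise (a one-month delay for a `lag_fraction`
  of pairs), giving every planted edge a sign (the loading-sign
  product) and a delay. These are the `planted_edges` of the ground
  truth.
* **Spurious site-specific couplings.** `n_spurious` cross-module pairs
  are overwritten with a strong coupling in exactly *one* (site, depth)
  series set each. They are detectable in that set's network but cannot
  reach a recurrence of 3, so the consensus provably excludes them.
* **Closure.** Latent values are exponentiated and closed to
  proportions, then resampled Dirichlet-style with concentration
  `dirichlet_concentration` (default 500) to emulate compositional
  counting noise. The designated bloom OTU follows a planted proportion
  trajectory peaking at `bloom_otu_peak_fraction` (default 0.4), and
  chlorophyll-a is an affine function of the realised bloom-module
  total plus noise, so bloom labelling can be exercised end to end
  against planted truth.

What the generator does *not* emulate: sequencing reads and their error
profiles, taxon-specific overdispersion, spatial autocorrelation
between sites beyond the shared planted structure, abundance-dependent
detection limits, and interactions that change sign over time. Passing
tests on this generator demonstrate that the pipeline recovers the
structure it is designed to recover under compositional noise; they do
not certify performance on real amplicon data.

One empirically important property of the closure is worth stating
plainly: when a bloom dominates the community, dividing by the total
imprints a shared seasonal component on every other taxon's relative
abundance. This *attenuates negative associations* between minor taxa
(their anti-correlated latent signals are partially masked by the
common divisor), so planted negative edges are recovered at a
substantially lower rate than positive ones. This is a property of
compositional data, not of the estimator, and it is the reason the
generator's default negative-loading fraction is small.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full pipeline on a
reduced emulation -- 50 OTUs + 11 environmental variables, 6 series
sets, 15 months, low latent noise (`noise_sd = 0.05`,
`dirichlet_concentration = 10000`), 2000 permutations per pair -- which
infers the consensus in well under a minute while leaving every stage's
behaviour visible: positive planted couplings are recovered essentially
completely, all site-specific spurious couplings are removed, Louvain
recovers the planted partition (adjusted Rand index 1 at this noise
level), and the null rejection rate of the permutation test sits at its
nominal level. Oracle checks (LS dynamic program vs exhaustive
enumeration, node roles vs brute-force counting, Louvain vs exhaustive
partition search on graphs of up to 8 nodes) are exact to floating
point.

Other conventions, in one place: relative abundances are computed per
sample over all OTUs before any filtering; the prevalence filter keeps
features whose occurrence fraction (value strictly above the detection
threshold, default 0) is at least `min_prevalence` (default 0.20) and
never renormalises; environmental features are always retained and are
exempt from closure; dates are truncated to year-month; degree-0 nodes
are excluded from role computation with a warning (their participation
coefficient is undefined); and all stochastic steps (generator,
permutations, Louvain shuffle, ER baselines) take explicit seeds and
are bit-reproducible given them.

## Known limitations

* Fifteen time points is very little data for association inference;
  the permutation floor means edge-level power is modest by design and
  the inference leans on recurrence, not on per-edge certainty.
* Negative associations are attenuated under compositional closure
  (above); counts of negative edges should be read qualitatively.
* The recurrence rule treats the six series sets as independent
  replicates; real spatial dependence between sites would make the
  effective replication smaller than 6.
* Louvain is a greedy heuristic; the seeded shuffle makes it
  reproducible, not optimal, although it attains the exhaustive
  optimum on all small graphs we test.
* Function collapse is only as good as the taxon→function map and the
  taxonomy; exact-string matching is deliberate (no fuzzy matching),
  so rank-name mismatches silently unmap taxa -- check the warning.
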