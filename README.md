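# mran — microbial recurrent association networks

`mran` infers interaction networks between cyanobacteria, the
surrounding bacterial community and environmental variables from
**replicated** monthly time series, as sampled at several sites and
depths of the same water body. It is aimed at microbial ecologists who
have OTU relative-abundance tables plus environmental measurements and
want a co-occurrence network they can defend at a dozen time points per
series — a regime where any single-series network is mostly noise.

## The method in brief

For each (site, depth) series set, every feature pair (OTUs and
environmental variables alike) is scored by time-lagged **local
similarity analysis**: series are gap-filled by linear interpolation,
rank-transformed to normal scores x̂, and scored by

    LS = (1/n) · max over |d| ≤ D, over contiguous aligned segments s of
         | Σ_{i∈s} x̂_i ŷ_{i+d} |

(dynamic program in C++), with a whole-series permutation p-value.
Edges with p < 0.001 whose alignment spans more than 6 months form one
association network per series set. The **MRAN** is the consensus of
those networks: an edge (pair + sign) is kept iff it recurs in ≥ 3 of
the 6 networks. Site-specific artefacts cannot recur and are provably
removed.

The consensus is then characterised: a topology panel against
Erdős–Rényi G(n, m) baselines including the small-world coefficient
SW = (C/C_R)/(L/L_R); Louvain modules with modularity Q; node roles
from within-module connectivity Z_i and participation coefficient
P_i = 1 − Σ_s (k_is/k_i)² (thresholds 2.5 / 0.62: peripherals, module
hubs, connectors, network hubs); module monthly patterns on min-max
scaled abundances; bloom-period labelling (OTU > 10% and chl-a >
15 µg/L, or OTU > 80% dominance); and FAPROTAX-style collapse into
functional groups.

A synthetic multi-site generator with planted modules, lagged
couplings, blooms and compositional noise (`generate_dataset()`) makes
every stage testable without sequencing data; the `analysis/` scripts
run the whole workflow on it.

## Worked example

```r
library(mran)

cfg <- generator_config(n_otus = 50, n_spurious = 6, noise_sd = 0.05,
                        dirichlet_concentration = 10000, seed = 1)
ds  <- generate_dataset(cfg)
ds$table
#> abundance_table: 72 samples x 61 features (10 cyano, 40 non-cyano OTUs, 11 environmental)
#> sites: S1,S2,S3 | depths: 0,2 | months: 2016-06..2017-08

res <- infer_mran(ds$table, D = 1, n_perm = 2000, alpha = 0.001,
                  min_span = 6, min_recurrence = 3, seed = 2)
res$consensus
#> consensus_network (>=3/6): 50 nodes, 233 edges

topology_summary(res$consensus, random_reps = 100, seed = 3)
#> Topology panel
#>   nodes 50 | edges 233 | diameter    3 | positive edges 0.974
#>   density 0.19 | avg neighbors 9.32 | heterogeneity 0.161 | centralization 0.142
#>   C 0.971 (random 0.191) | L 1.47 (random 1.95) | modularity 0.762 (random 0.237)
#>   C/C_R 5.07 | L/L_R 0.757 | SW  6.7  (small-world)

part <- louvain_partition(res$consensus, seed = 4)
part
#> module_partition: 5 modules over 50 nodes, Q = 0.762
#>   major modules: M1, M2, M3, M4, M5
```

Reading the panel: the consensus keeps 233 of the 1830 scanned feature
pairs, 97% of them positive associations; clustering is five times the
Erdős–Rényi baseline at a comparable path length, so SW = 6.7 > 1
flags small-world structure. The five inferred modules are exactly the
five planted ones (adjusted Rand index 1 at this noise level), and the
six site-specific spurious couplings all fail the ≥ 3/6 recurrence
rule while all six contaminate the pooled single-network union. `compute_roles(res$consensus, part)`
returns the Z_i–P_i table behind the role census, and
`label_blooms(ds$table, ds$truth$target_otu)` recovers the planted
bloom months from the realised abundances and chlorophyll.

The numbered scripts in `analysis/` run the same study as a narrative
workflow (simulate → per-set LSA networks → consensus + topology →
modules/roles/blooms → function profiles), writing tables under
`results/`.

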