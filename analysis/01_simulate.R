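#!/usr/bin/env Rscript
# Step 1: simulate the multi-site monthly study (3 sites x 2 depths x 15
# months; 50 prevalent OTUs in 5 planted modules + 11 environmental
# variables; summer cyanobacterial bloom; site-specific spurious
# couplings) and write the fixture files consumed by the later steps.

library(mran)

out <- "results/fixtures"
cfg <- generator_config(n_otus = 50, n_spurious = 6, noise_sd = 0.05,
                        dirichlet_concentration = 10000, seed = 20160601)
ds <- generate_dataset(cfg)
files <- write_fixture(ds, out)

bm <- ds$truth$bloom_months
write.table(bm, file.path(out, "bloom_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sp <- ds$truth$spurious_edges
write.table(sp, file.path(out, "spurious_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("samples: ", nrow(ds$table$values),
        " | OTUs: ", length(features(ds$table, c("cyano", "non_cyano"))),
        " | env vars: ", length(features(ds$table, "env")))
message("planted edges: ", nrow(ds$truth$planted_edges),
        " | spurious (single-set) edges: ", nrow(sp))
message("planted bloom sample-months: ", nrow(bm))
message("fixtures under ", out)
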