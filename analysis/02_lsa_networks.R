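#!/usr/bin/env Rscript
# Step 2: per-(site, depth) all-pairs local similarity analysis with
# permutation p-values, and screening into six association networks
# (p < 0.001, alignment > 6 months).

library(mran)

fix <- "results/fixtures"
tab <- read_abundance_table(
  file.path(fix, "abundance.tsv"),
  taxonomy = read_taxonomy(file.path(fix, "taxonomy.tsv")),
  env_features = c("temperature", "pH", "DO", "TN", "TDN", "TP", "TDP",
                   "chl_a", "precipitation", "discharge", "turbidity"))
sets <- split_series(tab)
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

for (i in seq_along(sets)) {
  id <- names(sets)[i]
  assoc <- all_pairs_lsa(sets[[i]], D = 1, n_perm = 2000, seed = 100 + i)
  nw <- build_network(assoc, alpha = 0.001, min_span = 6, network_id = id)
  safe <- gsub("[^A-Za-z0-9]", "_", id)
  write.table(assoc, sprintf("results/networks/assoc_%s.tsv", safe),
              sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(nw, sprintf("results/networks/network_%s.tsv", safe),
                 "edge_list_tsv")
  message(sprintf("%s: %d significant edges over %d nodes (of %d pairs)",
                  id, nrow(nw$edges), length(nw$nodes), nrow(assoc)))
}
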