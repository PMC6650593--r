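#!/usr/bin/env Rscript
# Step 4: Louvain modules of the consensus network, planted-module
# recovery, Zi-Pi node roles, module monthly patterns, the
# cyanobacteria-centred subnetwork and bloom labelling.

library(mran)

e <- read.delim("results/mran_edges.tsv", stringsAsFactors = FALSE)
cons <- structure(list(edges = e,
                       nodes = sort(unique(c(e$feature_a, e$feature_b))),
                       n_networks = 6, min_recurrence = 3),
                  class = "consensus_network")
fix <- "results/fixtures"
env <- c("temperature", "pH", "DO", "TN", "TDN", "TP", "TDP", "chl_a",
         "precipitation", "discharge", "turbidity")
tab <- read_abundance_table(file.path(fix, "abundance.tsv"),
                            taxonomy = read_taxonomy(file.path(fix, "taxonomy.tsv")),
                            env_features = env)

part <- louvain_partition(cons, seed = 17)
print(part)
write.table(data.frame(node = names(part$membership),
                       module = unname(part$membership)),
            "results/partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim(file.path(fix, "planted_modules.tsv"))
truth_mod <- setNames(truth$module, truth$otu_id)
common <- intersect(names(part$membership), names(truth_mod))
message("adjusted Rand index vs planted modules: ",
        round(mclust::adjustedRandIndex(part$membership[common],
                                        truth_mod[common]), 3))

roles <- compute_roles(cons, part)
write.table(roles, "results/zi_pi_roles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
census <- role_census(roles)
message("role census: ",
        paste(sprintf("%s %.1f%%", names(census$fractions),
                      100 * census$fractions), collapse = ", "),
        " | Pi = 0: ", sprintf("%.1f%%", 100 * census$pi_zero_fraction))

pat <- module_monthly_pattern(tab, part)
write.table(data.frame(module = rownames(pat), pat, check.names = FALSE),
            "results/module_monthly_patterns.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# ego subnetwork around the cyanobacterial OTUs present in the MRAN
cyano <- intersect(features(tab, "cyano"), cons$nodes)
if (length(cyano)) {
  sub <- extract_subnetwork(cons, cyano)
  export_network(sub, "results/cyano_subnetwork.tsv", "edge_list_tsv")
  message("cyanobacteria-centred subnetwork: ", length(sub$nodes),
          " nodes, ", nrow(sub$edges), " edges")
}

target <- intersect(features(tab, "cyano"), colnames(tab$values))[1]
calls <- label_blooms(tab, target)
write.table(calls, "results/bloom_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
bt <- read.delim(file.path(fix, "bloom_truth.tsv"))
truth_key <- paste(bt$site, bt$depth, bt$date)
call_key <- paste(calls$site, calls$depth, calls$date)
message("bloom calls for ", target, ": ", sum(calls$is_bloom),
        " sample-months; agreement with planted truth: ",
        sprintf("%.1f%%",
                100 * mean(calls$is_bloom == (call_key %in% truth_key))))
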