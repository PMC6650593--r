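# End-to-end convenience driver: series splitting -> per-set LSA ->
# per-set networks -> recurrence consensus.

#' Infer a recurrent association network from a multi-site table
#'
#' Splits the table into (site, depth) series sets, runs all-pairs local
#' similarity analysis with permutation p-values in each set, screens
#' edges (p < `alpha`, alignment longer than `min_span` months), and
#' merges the per-set networks into the recurrence consensus.
#'
#' @param table an [abundance_table()] covering all sites and depths.
#' @param D delay limit in months (default 1).
#' @param n_perm permutations per pair (default 2000).
#' @param alpha significance level on raw permutation p (default 0.001).
#' @param min_span minimum alignment length, strict (default 6 months).
#' @param min_recurrence consensus recurrence threshold (default 3).
#' @param seed RNG seed; each series set derives its own sub-seed.
#' @return list: `consensus` (a `consensus_network`), `networks`
#'   (per-set `assoc_network`s), `associations` (per-set raw association
#'   tables).
#' @export
infer_mran <- function(table, D = 1, n_perm = 2000, alpha = 0.001,
                       min_span = 6, min_recurrence = 3, seed = 1) {
  sets <- split_series(table)
  assoc <- vector("list", length(sets))
  nets <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    assoc[[i]] <- all_pairs_lsa(sets[[i]], D = D, n_perm = n_perm,
                                seed = seed + i)
    nets[[i]] <- build_network(assoc[[i]], alpha = alpha,
                               min_span = min_span,
                               network_id = names(sets)[i])
  }
  names(assoc) <- names(nets) <- names(sets)
  list(consensus = build_consensus(nets, min_recurrence = min_recurrence),
       networks = nets, associations = assoc)
}
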