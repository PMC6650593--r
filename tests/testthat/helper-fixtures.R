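# Shared in-code fixtures.

# Small abundance table: counts are closed to proportions on construction.
tiny_table <- function(values, sites = NULL, dates = NULL,
                       feature_class = NULL, normalize = TRUE) {
  n <- nrow(values)
  samples <- data.frame(
    site = if (is.null(sites)) rep("S1", n) else sites,
    depth = 0,
    date = if (is.null(dates))
      sprintf("2016-%02d", seq_len(n)) else dates)
  abundance_table(values, samples, feature_class, normalize = normalize)
}

# Consensus network assembled by hand from an edge data.frame.
manual_consensus <- function(edges, nodes = NULL, n_networks = 6,
                             min_recurrence = 3) {
  if (is.null(edges$consensus_delay)) edges$consensus_delay <- 0L
  if (is.null(edges$member_networks)) edges$member_networks <- ""
  if (is.null(edges$recurrence)) edges$recurrence <- min_recurrence
  structure(list(edges = edges,
                 nodes = if (is.null(nodes))
                   sort(unique(c(edges$feature_a, edges$feature_b)))
                 else nodes,
                 n_networks = n_networks,
                 min_recurrence = min_recurrence),
            class = "consensus_network")
}

edge_df <- function(a, b, sign = "+", ...) {
  data.frame(feature_a = a, feature_b = b, sign = sign, ...,
             stringsAsFactors = FALSE)
}

# One assoc_network with the given significant edges.
manual_network <- function(id, a, b, sign = "+", delay = 0L) {
  edges <- data.frame(feature_a = a, feature_b = b, sign = sign,
                      delay = delay, ls = 0.5, p = 1e-4,
                      start_a = 1L, start_b = 1L, length = 10L,
                      stringsAsFactors = FALSE)
  structure(list(network_id = id, edges = edges,
                 nodes = sort(unique(c(a, b)))),
            class = "assoc_network")
}

# The low-noise reduced-size study emulation used by the end-to-end
# checks: computed once per test session and cached.
.mran_fixture_cache <- new.env(parent = emptyenv())
mran_fixture <- function() {
  if (!is.null(.mran_fixture_cache$res)) return(.mran_fixture_cache$res)
  cfg <- generator_config(n_otus = 50, n_spurious = 6, noise_sd = 0.05,
                          dirichlet_concentration = 10000, seed = 20160601)
  ds <- generate_dataset(cfg)
  res <- infer_mran(ds$table, D = 1, n_perm = 2000, alpha = 0.001,
                    min_span = 6, min_recurrence = 3, seed = 99)
  .mran_fixture_cache$res <- list(dataset = ds, mran = res)
  .mran_fixture_cache$res
}

edge_key <- function(a, b, sign) paste(pmin(a, b), pmax(a, b), sign)
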