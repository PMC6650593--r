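# Topology panel for an undirected network and its Erdos-Renyi G(n, m)
# baselines, including the small-world coefficient. Sign is ignored for
# all topological metrics; the fraction of positive edges is reported
# separately.

as_simple_graph <- function(network) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the local coefficient 2T / (k(k-1)); nodes of
#' degree < 2 contribute 0.
#'
#' @param network an `assoc_network`, `consensus_network` or igraph.
#' @return C in [0, 1].
#' @export
clustering_coefficient <- function(network) {
  g <- as_simple_graph(network)
  if (igraph::vcount(g) == 0) stop("empty graph")
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Characteristic path length and diameter
#'
#' Breadth-first shortest paths; both statistics are taken over connected
#' node pairs only, with a `disconnected` flag when the graph has more
#' than one component.
#'
#' @param network network or igraph with at least one edge.
#' @return `list(L = , diameter = , disconnected = )`.
#' @export
characteristic_path_length <- function(network) {
  g <- as_simple_graph(network)
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes")
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  list(L = mean(d), diameter = max(d),
       disconnected = !igraph::is_connected(g))
}

#' Network density and average neighbour count
#'
#' @param network network or igraph with N >= 2 nodes.
#' @return `list(density = 2E / (N(N-1)), avg_neighbors = 2E / N)`.
#' @export
density_and_neighbors <- function(network) {
  g <- as_simple_graph(network)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n < 2) stop("need at least 2 nodes")
  list(density = 2 * m / (n * (n - 1)), avg_neighbors = 2 * m / n)
}

#' Degree heterogeneity and Freeman degree centralization
#'
#' Heterogeneity is the coefficient of variation of the degree sequence
#' (population variance); centralization is
#' \eqn{\sum_i (k_{max} - k_i) / ((N-1)(N-2))}.
#'
#' @param network network or igraph with N >= 3 nodes.
#' @return `list(heterogeneity = , centralization = )`.
#' @export
heterogeneity_and_centralization <- function(network) {
  g <- as_simple_graph(network)
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes")
  k <- igraph::degree(g)
  pvar <- mean(k^2) - mean(k)^2
  list(heterogeneity = sqrt(pvar) / mean(k),
       centralization = igraph::centr_degree(g, loops = FALSE)$centralization)
}

#' Erdos-Renyi G(n, m) baseline metrics
#'
#' Uniform random graphs with exactly the observed numbers of nodes and
#' edges; each metric is averaged over `reps` replicates, with
#' Monte-Carlo standard errors. Path metrics use connected pairs;
#' modularity is the Louvain optimum per replicate.
#'
#' @param n_nodes,n_edges size of the graphs.
#' @param reps replicates (default 100).
#' @param seed RNG seed.
#' @return list of means `C_R`, `L_R`, `modularity_R`, `heterogeneity_R`,
#'   `centralization_R` plus per-metric standard errors in `se`.
#' @export
er_baseline <- function(n_nodes, n_edges, reps = 100, seed = 1) {
  if (n_edges > choose(n_nodes, 2)) stop("too many edges for ", n_nodes,
                                         " nodes")
  stopifnot(reps >= 1)
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    d <- igraph::distances(g)
    d <- d[upper.tri(d)]
    d <- d[is.finite(d)]
    k <- igraph::degree(g)
    pvar <- mean(k^2) - mean(k)^2
    c(C = mean(igraph::transitivity(g, type = "local", isolates = "zero")),
      L = mean(d),
      Q = igraph::modularity(g, igraph::membership(igraph::cluster_louvain(g))),
      het = if (mean(k) > 0) sqrt(pvar) / mean(k) else 0,
      centr = igraph::centr_degree(g, loops = FALSE)$centralization)
  }, numeric(5))
  m <- rowMeans(vals)
  se <- apply(vals, 1, stats::sd) / sqrt(reps)
  list(C_R = m[["C"]], L_R = m[["L"]], modularity_R = m[["Q"]],
       heterogeneity_R = m[["het"]], centralization_R = m[["centr"]],
       se = setNames(se, c("C_R", "L_R", "modularity_R",
                           "heterogeneity_R", "centralization_R")),
       reps = reps)
}

#' Small-world coefficient
#'
#' SW = (C / C_R) / (L / L_R); values above 1 indicate small-world
#' structure (more clustered than random at comparable path length).
#'
#' @param C,C_R,L,L_R clustering and path length of the network and the
#'   random baseline; all must be positive.
#' @return `list(C_ratio = , L_ratio = , SW = , small_world = )`.
#' @export
small_world <- function(C, C_R, L, L_R) {
  if (any(c(C, C_R, L, L_R) <= 0)) stop("all inputs must be positive")
  C_ratio <- C / C_R
  L_ratio <- L / L_R
  list(C_ratio = C_ratio, L_ratio = L_ratio, SW = C_ratio / L_ratio,
       small_world = (C_ratio / L_ratio) > 1)
}

#' Full topology panel with random baselines
#'
#' Computes node/edge counts, diameter, positive-edge fraction, average
#' neighbours, density, heterogeneity, centralization, Louvain
#' modularity, clustering, path length, the G(n, m) baseline means and
#' the small-world coefficient.
#'
#' @param network an `assoc_network` or `consensus_network` (the edge
#'   `sign` column feeds the positive-edge fraction).
#' @param random_reps baseline replicates (default 100).
#' @param seed RNG seed for the baseline and Louvain.
#' @return `topology_summary` list mirroring the panel above.
#' @export
topology_summary <- function(network, random_reps = 100, seed = 1) {
  g <- as_simple_graph(network)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  dn <- density_and_neighbors(g)
  hc <- heterogeneity_and_centralization(g)
  pl <- characteristic_path_length(g)
  C <- clustering_coefficient(g)
  part <- louvain_partition(g, seed = seed)
  base <- er_baseline(n, m, reps = random_reps, seed = seed)
  sw <- small_world(C, base$C_R, pl$L, base$L_R)
  pos_frac <- if (!is.null(network$edges$sign))
    mean(network$edges$sign == "+") else NA_real_
  structure(c(list(n_nodes = n, n_edges = m, diameter = pl$diameter,
                   pos_fraction = pos_frac,
                   avg_neighbors = dn$avg_neighbors, density = dn$density,
                   heterogeneity = hc$heterogeneity,
                   centralization = hc$centralization,
                   modularity = part$Q, C = C, L = pl$L,
                   disconnected = pl$disconnected),
              base[c("C_R", "L_R", "modularity_R", "heterogeneity_R",
                     "centralization_R", "se")],
              sw[c("C_ratio", "L_ratio", "SW", "small_world")],
              list(random_reps = random_reps, seed = seed)),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  fmt <- function(v) formatC(v, digits = 3, format = "fg")
  cat("Topology panel\n")
  cat(sprintf("  nodes %d | edges %d | diameter %s | positive edges %s\n",
              x$n_nodes, x$n_edges, fmt(x$diameter), fmt(x$pos_fraction)))
  cat(sprintf("  density %s | avg neighbors %s | heterogeneity %s | centralization %s\n",
              fmt(x$density), fmt(x$avg_neighbors), fmt(x$heterogeneity),
              fmt(x$centralization)))
  cat(sprintf("  C %s (random %s) | L %s (random %s) | modularity %s (random %s)\n",
              fmt(x$C), fmt(x$C_R), fmt(x$L), fmt(x$L_R), fmt(x$modularity),
              fmt(x$modularity_R)))
  cat(sprintf("  C/C_R %s | L/L_R %s | SW %s%s\n", fmt(x$C_ratio),
              fmt(x$L_ratio), fmt(x$SW),
              if (isTRUE(x$small_world)) "  (small-world)" else ""))
  invisible(x)
}
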