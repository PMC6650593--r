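# Louvain module detection, Zi-Pi node roles, module monthly abundance
# patterns and bloom-period labelling.

#' Louvain module partition
#'
#' Greedy modularity optimisation on the unsigned, unweighted graph
#' (weights can be supplied explicitly). Louvain depends on vertex
#' order, so the vertices are shuffled under `seed` before clustering;
#' the result is deterministic for a fixed seed.
#'
#' @param network network object or igraph.
#' @param resolution resolution parameter (default 1).
#' @param seed RNG seed for the vertex shuffle.
#' @param weights optional edge weights (default NULL = unweighted).
#' @param major_coverage modules are ranked by size and flagged "major"
#'   until this fraction of nodes is covered (default 0.85).
#' @return `module_partition` list: `membership` (named `"M<k>"` labels,
#'   modules numbered by decreasing size), `Q`, `module_sizes`,
#'   `major_modules`.
#' @export
louvain_partition <- function(network, resolution = 1.0, seed = 1,
                              weights = NULL, major_coverage = 0.85) {
  g <- as_simple_graph(network)
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  cl <- igraph::cluster_louvain(gp, weights = weights,
                                resolution = resolution)
  memb <- igraph::membership(cl)[igraph::V(g)$name]
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(paste0("M", seq_along(sizes)), names(sizes))
  membership <- setNames(unname(relabel[as.character(memb)]), names(memb))
  module_sizes <- setNames(as.integer(sizes), relabel[names(sizes)])
  cum <- cumsum(module_sizes) / sum(module_sizes)
  n_major <- which(cum >= major_coverage)[1]
  Q <- igraph::modularity(g, as.integer(factor(membership)))
  structure(list(membership = membership, Q = Q,
                 module_sizes = module_sizes,
                 major_modules = names(module_sizes)[seq_len(n_major)],
                 resolution = resolution, seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.3f\n",
              length(x$module_sizes), length(x$membership), x$Q))
  cat("  major modules:", paste(x$major_modules, collapse = ", "), "\n")
  invisible(x)
}

#' Within-module (Zi) and among-module (Pi) connectivity of each node
#'
#' Zi is the z-score of a node's within-module degree against the other
#' nodes of its module (population standard deviation; Zi = 0 when the
#' module is degree-homogeneous). Pi is the participation coefficient
#' \eqn{1 - \sum_s (k_{is}/k_i)^2}. Thresholds Zi = 2.5 and Pi = 0.62
#' split nodes into peripherals, module hubs, connectors and network
#' hubs.
#'
#' @param network network object or igraph.
#' @param partition a [louvain_partition()] (or any list with a named
#'   `membership` vector covering the network's nodes).
#' @return data.frame: `node`, `module`, `degree`, `Zi`, `Pi`,
#'   `category`.
#' @export
compute_roles <- function(network, partition) {
  g <- as_simple_graph(network)
  nodes <- igraph::V(g)$name
  memb <- partition$membership[nodes]
  if (any(is.na(memb))) stop("partition does not cover all network nodes")
  deg <- igraph::degree(g)
  if (any(deg == 0)) {
    warning("excluding ", sum(deg == 0), " node(s) of degree 0")
    g <- igraph::delete_vertices(g, which(deg == 0))
    nodes <- igraph::V(g)$name
    memb <- memb[nodes]
    deg <- igraph::degree(g)
  }
  mods <- sort(unique(memb))
  el <- igraph::as_edgelist(g)
  # k_is: links from node i into module s
  kis <- matrix(0L, length(nodes), length(mods),
                dimnames = list(nodes, mods))
  ma <- memb[el[, 1]]; mb <- memb[el[, 2]]
  for (r in seq_len(nrow(el))) {
    kis[el[r, 1], mb[r]] <- kis[el[r, 1], mb[r]] + 1L
    kis[el[r, 2], ma[r]] <- kis[el[r, 2], ma[r]] + 1L
  }
  k_own <- kis[cbind(nodes, memb)]
  Zi <- numeric(length(nodes))
  for (s in mods) {
    i <- memb == s
    mu <- mean(k_own[i])
    sdev <- sqrt(mean((k_own[i] - mu)^2))   # population sd
    Zi[i] <- if (sdev > 0) (k_own[i] - mu) / sdev else 0
  }
  Pi <- 1 - rowSums((kis / deg)^2)
  category <- ifelse(Zi > 2.5,
                     ifelse(Pi > 0.62, "network hub", "module hub"),
                     ifelse(Pi > 0.62, "connector", "peripheral"))
  data.frame(node = nodes, module = unname(memb), degree = unname(deg),
             Zi = Zi, Pi = unname(Pi), category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Census of node role categories
#'
#' @param roles output of [compute_roles()].
#' @return list: `fractions` over the four categories (summing to 1) and
#'   `pi_zero_fraction`, the share of nodes with no links outside their
#'   own module.
#' @export
role_census <- function(roles) {
  cats <- c("peripheral", "module hub", "connector", "network hub")
  frac <- table(factor(roles$category, levels = cats)) / nrow(roles)
  list(fractions = setNames(as.numeric(frac), cats),
       pi_zero_fraction = mean(roles$Pi == 0))
}

#' Average monthly abundance pattern of each module
#'
#' Each non-cyanobacterial member OTU's relative-abundance series is
#' min-max scaled to [0, 1] across all samples (constant series map to
#' 0), then averaged per module over member OTUs and over the samples of
#' each month.
#'
#' @param table an [abundance_table()].
#' @param partition a [louvain_partition()].
#' @param modules which modules to profile (default: the partition's
#'   major modules).
#' @return modules x months numeric matrix; a module with no
#'   non-cyanobacterial members yields an `NaN` row with a warning.
#' @export
module_monthly_pattern <- function(table, partition,
                                   modules = partition$major_modules) {
  months <- sort(unique(table$samples$date))
  scaled <- apply(table$values, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })
  out <- matrix(NA_real_, length(modules), length(months),
                dimnames = list(modules, months))
  for (mod in modules) {
    mem <- names(partition$membership)[partition$membership == mod]
    mem <- intersect(mem, features(table, "non_cyano"))
    if (length(mem) == 0) {
      warning("module ", mod, " has no non-cyanobacterial members")
      out[mod, ] <- NaN
      next
    }
    for (mth in months) {
      rows <- table$samples$date == mth
      out[mod, mth] <- mean(scaled[rows, mem])
    }
  }
  out
}

#' Label cyanobacterial bloom periods
#'
#' A sample is a bloom for a target OTU when its relative abundance
#' strictly exceeds `prop_threshold` and chlorophyll-a strictly exceeds
#' `chl_threshold`, or - as the dominance exception - when the OTU alone
#' strictly exceeds `dominance_override` of the community regardless of
#' chlorophyll.
#'
#' @param table an [abundance_table()].
#' @param target_otus OTU feature names to test.
#' @param chl_a per-sample chlorophyll-a (ug/L); defaults to the table's
#'   `chl_a` environmental column. Samples with missing chlorophyll are
#'   skipped with a warning.
#' @param prop_threshold relative-abundance threshold (default 0.10).
#' @param chl_threshold chlorophyll threshold in ug/L (default 15).
#' @param dominance_override abundance above which a bloom is called
#'   regardless of chlorophyll (default 0.80).
#' @return data.frame: `site`, `depth`, `date`, `target_otu`,
#'   `proportion`, `chl_a`, `is_bloom`, `rule_fired` in
#'   `{"proportion+chl", "dominance_override", "none"}`.
#' @export
label_blooms <- function(table, target_otus, chl_a = NULL,
                         prop_threshold = 0.10, chl_threshold = 15,
                         dominance_override = 0.80) {
  if (is.null(chl_a)) {
    if (!"chl_a" %in% colnames(table$values))
      stop("no chl_a column in the table; supply `chl_a`")
    chl_a <- table$values[, "chl_a"]
  }
  stopifnot(length(chl_a) == nrow(table$values))
  if (any(chl_a < 0, na.rm = TRUE)) stop("negative chl-a concentration")
  missing_otus <- setdiff(target_otus, colnames(table$values))
  if (length(missing_otus))
    stop("target OTUs not in table: ", paste(missing_otus, collapse = ", "))
  keep <- !is.na(chl_a)
  if (!all(keep)) warning("skipping ", sum(!keep),
                          " sample(s) without chl-a")
  out <- do.call(rbind, lapply(target_otus, function(otu) {
    prop <- table$values[keep, otu]
    chl <- chl_a[keep]
    main <- prop > prop_threshold & chl > chl_threshold
    dom <- prop > dominance_override
    data.frame(table$samples[keep, , drop = FALSE], target_otu = otu,
               proportion = unname(prop), chl_a = unname(chl),
               is_bloom = main | dom,
               rule_fired = ifelse(main, "proportion+chl",
                                   ifelse(dom, "dominance_override", "none")),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
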