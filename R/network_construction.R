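# Per-(site, depth) association networks, the recurrence-based consensus
# network, subnetwork extraction and export.

canonicalize_edges <- function(edges) {
  swap <- edges$feature_a > edges$feature_b
  if (any(swap)) {
    tmp <- edges$feature_a[swap]
    edges$feature_a[swap] <- edges$feature_b[swap]
    edges$feature_b[swap] <- tmp
    edges$delay[swap] <- -edges$delay[swap]
    if (all(c("start_a", "start_b") %in% names(edges))) {
      tmp <- edges$start_a[swap]
      edges$start_a[swap] <- edges$start_b[swap]
      edges$start_b[swap] <- tmp
    }
  }
  edges
}

#' Build one association network from screened associations
#'
#' Keeps associations significant at `alpha` whose aligned segment lasts
#' strictly more than `min_span` months (the default operationalises
#' "continuously for more than 6 months" on a monthly grid), then takes
#' as nodes every feature incident to a surviving edge.
#'
#' @param assocs association data.frame from [all_pairs_lsa()].
#' @param alpha significance level on the raw permutation p (default
#'   0.001).
#' @param min_span minimum alignment length in months (default 6).
#' @param network_id identifier, e.g. `"MG1|0"`.
#' @param span_comparator `">"` (default, strict) or `">="`.
#' @return An `assoc_network`: list with `network_id`, `edges`, `nodes`.
#' @export
build_network <- function(assocs, alpha = 0.001, min_span = 6,
                          network_id = "net", span_comparator = c(">", ">=")) {
  span_comparator <- match.arg(span_comparator)
  cmp <- match.fun(span_comparator)
  keep <- assocs$p < alpha & cmp(assocs$length, min_span)
  edges <- canonicalize_edges(assocs[keep, , drop = FALSE])
  edges <- edges[edges$feature_a != edges$feature_b, , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0) warning("network '", network_id, "' is empty")
  structure(list(network_id = network_id, edges = edges,
                 nodes = sort(unique(c(edges$feature_a, edges$feature_b)))),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network '%s': %d nodes, %d edges\n",
              x$network_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Merge association networks into a recurrence consensus network
#'
#' An edge (unordered pair + sign) enters the consensus iff it appears
#' with that sign in at least `min_recurrence` of the input networks.
#' Recurrence is counted per (pair, sign): opposite-signed associations
#' between the same pair never pool evidence. Delay equality is not
#' required; the consensus delay is the most frequent member delay (ties
#' towards smaller |delay|, then positive).
#'
#' @param networks list of `assoc_network` objects with distinct ids.
#' @param min_recurrence minimum number of networks (default 3).
#' @return A `consensus_network`: list with `edges` (`feature_a`,
#'   `feature_b`, `sign`, `recurrence`, `consensus_delay`,
#'   `member_networks`), `nodes`, `n_networks`, `min_recurrence`.
#' @export
build_consensus <- function(networks, min_recurrence = 3) {
  ids <- vapply(networks, `[[`, "", "network_id")
  if (anyDuplicated(ids)) stop("duplicate network ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  stopifnot(length(networks) >= min_recurrence)
  all_edges <- do.call(rbind, lapply(networks, function(nw) {
    e <- nw$edges
    if (nrow(e) == 0) return(NULL)
    cbind(e[, c("feature_a", "feature_b", "sign", "delay")],
          network_id = nw$network_id)
  }))
  if (is.null(all_edges) || nrow(all_edges) == 0)
    stop("no edges in any input network")
  key <- paste(all_edges$feature_a, all_edges$feature_b, all_edges$sign,
               sep = "\r")
  groups <- split(all_edges, key)
  rows <- lapply(groups, function(g) {
    nets <- unique(g$network_id)
    if (length(nets) < min_recurrence) return(NULL)
    # modal delay; ties -> smaller |delay|, then positive
    tab <- table(g$delay)
    d <- as.integer(names(tab))
    d <- d[order(-as.integer(tab), abs(d), -sign(d))]
    data.frame(feature_a = g$feature_a[1], feature_b = g$feature_b[1],
               sign = g$sign[1], recurrence = length(nets),
               consensus_delay = d[1],
               member_networks = paste(sort(nets), collapse = ","),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges)) {
    warning("no edge reaches min_recurrence = ", min_recurrence)
    edges <- data.frame(feature_a = character(0), feature_b = character(0),
                        sign = character(0), recurrence = integer(0),
                        consensus_delay = integer(0),
                        member_networks = character(0))
  }
  edges <- edges[order(edges$feature_a, edges$feature_b, edges$sign), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$feature_a, edges$feature_b))),
                 n_networks = length(networks),
                 min_recurrence = min_recurrence),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network (>=%d/%d): %d nodes, %d edges\n",
              x$min_recurrence, x$n_networks, length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Fraction of consensus edges per recurrence level
#'
#' @param consensus a `consensus_network`.
#' @return Named numeric vector over recurrence levels
#'   `min_recurrence..n_networks`, summing to 1.
#' @export
recurrence_histogram <- function(consensus) {
  lev <- seq(consensus$min_recurrence, consensus$n_networks)
  cnt <- table(factor(consensus$edges$recurrence, levels = lev))
  setNames(as.numeric(cnt) / sum(cnt), lev)
}

#' Extract the first-neighbourhood subnetwork around seed nodes
#'
#' Induced subgraph on the seeds and all their direct neighbours, with
#' edge attributes preserved.
#'
#' @param network a `consensus_network`.
#' @param seed_nodes feature ids; seeds missing from the network are
#'   reported with a warning, not an error.
#' @return A `consensus_network` restricted to the closed neighbourhood.
#' @export
extract_subnetwork <- function(network, seed_nodes) {
  if (length(seed_nodes) == 0) stop("empty seed set")
  missing <- setdiff(seed_nodes, network$nodes)
  if (length(missing))
    warning("seeds not in network: ", paste(missing, collapse = ", "))
  seeds <- intersect(seed_nodes, network$nodes)
  if (length(seeds) == 0) stop("no seed node present in the network")
  e <- network$edges
  nb <- unique(c(e$feature_b[e$feature_a %in% seeds],
                 e$feature_a[e$feature_b %in% seeds]))
  keep_nodes <- union(seeds, nb)
  keep <- e$feature_a %in% keep_nodes & e$feature_b %in% keep_nodes
  out <- network
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$nodes <- sort(unique(c(out$edges$feature_a, out$edges$feature_b,
                             seeds)))
  out
}

#' Convert a network to an igraph object
#'
#' Signs, delays and other edge columns become edge attributes; optional
#' feature classes become the vertex attribute `class`.
#'
#' @param network an `assoc_network` or `consensus_network`.
#' @param feature_class optional named vector of feature classes.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(network, feature_class = NULL) {
  e <- network$edges
  verts <- data.frame(name = network$nodes, stringsAsFactors = FALSE)
  if (!is.null(feature_class))
    verts$class <- unname(feature_class[verts$name])
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = verts)
}

#' Export a network to GraphML, TSV edge list or SIF
#'
#' GraphML exports round-trip through [igraph::read_graph()] with all
#' attributes; SIF encodes the sign as the interaction type (`pos`/`neg`).
#'
#' @param network an `assoc_network` or `consensus_network`.
#' @param path output file.
#' @param format `"graphml"`, `"edge_list_tsv"` or `"sif"`.
#' @param feature_class optional vertex classes (see [as_igraph()]).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "edge_list_tsv", "sif"),
                           feature_class = NULL) {
  format <- match.arg(format)
  if (nrow(network$edges) == 0) stop("refusing to export an empty network")
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network, feature_class), path,
                        format = "graphml")
  } else if (format == "edge_list_tsv") {
    write.table(network$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    inter <- ifelse(network$edges$sign == "+", "pos", "neg")
    writeLines(paste(network$edges$feature_a, inter,
                     network$edges$feature_b, sep = "\t"), path)
  }
  invisible(path)
}
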