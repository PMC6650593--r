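# Independent brute-force oracles, kept free of the code paths they check.

# Exhaustive local-similarity: maximum |segment sum| / n over every
# contiguous aligned segment with offset |d| <= D.
brute_ls <- function(x, y, D) {
  n <- length(x)
  best <- list(raw = 0, sign = 1L, delay = 0L)
  for (d in -D:D) {
    i0 <- max(1, 1 - d); i1 <- min(n, n - d)
    for (s in i0:i1) {
      acc <- 0
      for (e in s:i1) {
        acc <- acc + x[e] * y[e + d]
        if (abs(acc) > best$raw) {
          best <- list(raw = abs(acc), sign = if (acc > 0) 1L else -1L,
                       delay = d)
        }
      }
    }
  }
  best$ls <- best$raw / n
  best
}

# Direct edge-count implementation of within/among-module connectivity.
brute_roles <- function(edges, membership) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  mods <- sort(unique(membership[nodes]))
  adj <- lapply(setNames(nodes, nodes), function(v)
    c(edges$b[edges$a == v], edges$a[edges$b == v]))
  k_own <- sapply(nodes, function(v)
    sum(membership[adj[[v]]] == membership[v]))
  Zi <- sapply(nodes, function(v) {
    peers <- nodes[membership[nodes] == membership[v]]
    mu <- mean(k_own[peers])
    sdev <- sqrt(mean((k_own[peers] - mu)^2))
    if (sdev > 0) (k_own[v] - mu) / sdev else 0
  })
  Pi <- sapply(nodes, function(v) {
    k <- length(adj[[v]])
    1 - sum((table(factor(membership[adj[[v]]], levels = mods)) / k)^2)
  })
  data.frame(node = nodes, Zi = unname(Zi), Pi = unname(Pi),
             category = ifelse(Zi > 2.5,
                               ifelse(Pi > 0.62, "network hub", "module hub"),
                               ifelse(Pi > 0.62, "connector", "peripheral")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# All set partitions of 1..n as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    k <- length(a) + 1
    if (k > n) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (g in seq_len(mx + 1)) rec(c(a, g), max(mx, g))
  }
  rec(integer(0), 0L)
  out
}

# Brute-force maximum modularity over every partition (n <= 8).
brute_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- igraph::modularity(g, p)
    if (q > best) best <- q
  }
  best
}

# Floyd-Warshall shortest paths on an adjacency matrix.
brute_path_stats <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  up <- d[upper.tri(d)]
  up <- up[is.finite(up)]
  list(L = mean(up), diameter = max(up))
}

# Local clustering by triple enumeration.
brute_clustering <- function(adj) {
  n <- nrow(adj)
  loc <- sapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  })
  mean(loc)
}
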