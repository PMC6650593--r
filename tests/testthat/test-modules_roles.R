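named_graph <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}

test_that("Louvain recovers closed-form partitions of disjoint cliques", {
  g <- named_graph(igraph::disjoint_union(igraph::make_full_graph(5),
                                          igraph::make_full_graph(5)))
  part <- louvain_partition(g, seed = 2)
  expect_equal(part$Q, 0.5)
  expect_length(part$module_sizes, 2)
  one <- named_graph(igraph::make_full_graph(6))
  p1 <- louvain_partition(one, seed = 2)
  expect_length(p1$module_sizes, 1)
  expect_equal(p1$Q, 0)
})

test_that("Louvain attains the brute-force modularity optimum on small graphs", {
  set.seed(41)
  for (i in 1:10) {
    g <- igraph::sample_gnp(sample(5:8, 1), 0.5)
    if (igraph::ecount(g) < 2) next
    g <- named_graph(g)
    part <- louvain_partition(g, seed = 7)
    expect_equal(part$Q, brute_max_modularity(g), tolerance = 1e-9)
  }
})

test_that("a ring of four cliques resolves into the four cliques", {
  k5 <- lapply(1:4, function(i) igraph::make_full_graph(5))
  g <- do.call(igraph::disjoint_union, k5)
  g <- igraph::add_edges(g, c(1, 6, 10, 11, 15, 16, 20, 1))
  g <- named_graph(g)
  part <- louvain_partition(g, seed = 3)
  expect_length(part$module_sizes, 4)
  truth <- rep(1:4, each = 5)
  expect_equal(part$Q, igraph::modularity(g, truth), tolerance = 1e-9)
})

test_that("Louvain is deterministic per seed and labels modules by size", {
  set.seed(42)
  g <- named_graph(igraph::sample_gnm(30, 60))
  p1 <- louvain_partition(g, seed = 5)
  p2 <- louvain_partition(g, seed = 5)
  expect_identical(p1$membership, p2$membership)
  expect_equal(names(p1$module_sizes)[1], "M1")
  expect_true(all(diff(p1$module_sizes) <= 0))
  expect_true(p1$Q >= -0.5 && p1$Q <= 1)
})

test_that("major modules cover the requested node fraction", {
  sizes <- c(40, 30, 20, 6, 4)
  g <- do.call(igraph::disjoint_union,
               lapply(sizes, igraph::make_full_graph))
  g <- named_graph(g)
  part <- louvain_partition(g, seed = 1, major_coverage = 0.85)
  expect_equal(part$major_modules, c("M1", "M2", "M3"))
})

test_that("participation and within-module degree follow the formulas", {
  # A-B-C-D clique pair structure: two modules {A,B}, {C,D}
  edges <- edge_df(c("A", "C", "B"), c("B", "D", "C"))
  cons <- manual_consensus(edges)
  part <- list(membership = c(A = "m1", B = "m1", C = "m2", D = "m2"))
  roles <- compute_roles(cons, part)
  rb <- roles[roles$node == "B", ]
  expect_equal(rb$Pi, 1 - (0.5^2 + 0.5^2))  # one link in each module
  ra <- roles[roles$node == "A", ]
  expect_equal(ra$Pi, 0)                     # all links inside own module
  # equal within-degrees => population sd 0 => Zi = 0 for all
  expect_true(all(roles$Zi == 0))
  expect_true(all(roles$category == "peripheral"))
})

test_that("node roles equal the brute-force edge-count implementation", {
  set.seed(43)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    g <- igraph::sample_gnm(n, sample(n:(3 * n), 1))
    g <- named_graph(g)
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    if (igraph::vcount(g) < 4 || igraph::ecount(g) < 3) next
    part <- louvain_partition(g, seed = i)
    roles <- compute_roles(g, part)
    el <- igraph::as_edgelist(g)
    bf <- brute_roles(data.frame(a = el[, 1], b = el[, 2]),
                      part$membership)
    ord <- match(bf$node, roles$node)
    expect_equal(roles$Zi[ord], bf$Zi, tolerance = 1e-12)
    expect_equal(roles$Pi[ord], bf$Pi, tolerance = 1e-12)
    expect_identical(roles$category[ord], bf$category)
  }
})

test_that("a dominant star hub is classified a module hub", {
  leaves <- paste0("L", 1:30)
  edges <- rbind(edge_df(rep("hub", 30), leaves),
                 edge_df("o1", "o2"))
  cons <- manual_consensus(edges)
  part <- list(membership = c(setNames(rep("m1", 31), c("hub", leaves)),
                              o1 = "m2", o2 = "m2"))
  roles <- compute_roles(cons, part)
  hub <- roles[roles$node == "hub", ]
  # Zi by hand: within-degrees are (30, 1 x 30); mean = 31/31, sd population
  k <- c(30, rep(1, 30))
  zi_hand <- (30 - mean(k)) / sqrt(mean((k - mean(k))^2))
  expect_equal(hub$Zi, zi_hand)
  expect_gt(hub$Zi, 2.5)
  expect_equal(hub$category, "module hub")
  census <- role_census(roles)
  expect_equal(sum(census$fractions), 1)
  expect_equal(census$fractions[["module hub"]], 1 / 33)
  expect_equal(census$pi_zero_fraction, 1)  # every link stays in-module
})

test_that("monthly module patterns are min-max scaled means", {
  v <- cbind(A = c(2, 4, 6), B = c(6, 4, 2), C = c(5, 5, 5),
             X = c(1, 2, 3))
  fc <- c(A = "non_cyano", B = "non_cyano", C = "non_cyano", X = "cyano")
  tab <- tiny_table(v, dates = c("2016-06", "2016-07", "2016-08"),
                    feature_class = fc, normalize = FALSE)
  part <- list(membership = c(A = "M1", B = "M2", C = "M3", X = "M1"),
               major_modules = c("M1", "M2", "M3"))
  pat <- module_monthly_pattern(tab, part)
  expect_equal(unname(pat["M1", ]), c(0, 0.5, 1))   # cyano member excluded
  expect_equal(unname(pat["M2", ]), c(1, 0.5, 0))
  expect_equal(unname(pat["M3", ]), c(0, 0, 0))     # constant series -> 0
  # mirrored ramps average to a flat 0.5
  part2 <- list(membership = c(A = "M", B = "M"), major_modules = "M")
  pat2 <- module_monthly_pattern(tab, part2)
  expect_equal(unname(pat2["M", ]), c(0.5, 0.5, 0.5))
  part3 <- list(membership = c(X = "Mx"), major_modules = "Mx")
  expect_warning(pat3 <- module_monthly_pattern(tab, part3),
                 "no non-cyanobacterial")
  expect_true(all(is.nan(pat3)))
})

test_that("bloom labelling applies the stated thresholds and the dominance override", {
  v <- cbind(OTUc = c(0.12, 0.12, 0.85), other = c(0.88, 0.88, 0.15),
             chl_a = c(20, 10, 10))
  fc <- c(OTUc = "cyano", other = "non_cyano", chl_a = "env")
  tab <- tiny_table(v, dates = c("2016-06", "2016-07", "2016-12"),
                    feature_class = fc, normalize = FALSE)
  calls <- label_blooms(tab, "OTUc")
  expect_equal(calls$is_bloom, c(TRUE, FALSE, TRUE))
  expect_equal(calls$rule_fired,
               c("proportion+chl", "none", "dominance_override"))
})

test_that("bloom thresholds are strict and labelling is monotone in them", {
  v <- cbind(OTUc = c(0.10, 0.101), other = c(0.9, 0.899),
             chl_a = c(15, 15.1))
  fc <- c(OTUc = "cyano", other = "non_cyano", chl_a = "env")
  tab <- tiny_table(v, dates = c("2016-06", "2016-07"),
                    feature_class = fc, normalize = FALSE)
  calls <- label_blooms(tab, "OTUc")
  expect_equal(calls$is_bloom, c(FALSE, TRUE))  # exactly-at-threshold fails
  for (pt in c(0.05, 0.2)) for (ct in c(10, 20)) {
    lo <- label_blooms(tab, "OTUc", prop_threshold = pt, chl_threshold = ct)
    hi <- label_blooms(tab, "OTUc", prop_threshold = pt + 0.1,
                       chl_threshold = ct + 5)
    expect_true(all(lo$is_bloom >= hi$is_bloom))
  }
  expect_error(label_blooms(tab, "OTUc", chl_a = c(-1, 5)), "negative chl")
  expect_warning(label_blooms(tab, "OTUc", chl_a = c(NA, 20)), "skipping")
})
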