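assoc_row <- function(a = "X", b = "Y", p = 5e-4, len = 8L, sign = "+",
                      delay = 0L) {
  data.frame(feature_a = a, feature_b = b, ls = 0.6, sign = sign,
             delay = delay, start_a = 1L, start_b = 1L, length = len,
             p = p, stringsAsFactors = FALSE)
}

test_that("edge screening applies both the significance and duration rules", {
  assocs <- rbind(assoc_row("A", "B", p = 5e-4, len = 8),   # kept
                  assoc_row("A", "C", p = 5e-4, len = 6),   # dropped: strict > 6
                  assoc_row("B", "C", p = 5e-3, len = 12))  # dropped: p
  nw <- build_network(assocs, alpha = 0.001, min_span = 6)
  expect_equal(nrow(nw$edges), 1)
  expect_setequal(nw$nodes, c("A", "B"))
  nw2 <- build_network(assocs, alpha = 0.001, min_span = 6,
                       span_comparator = ">=")
  expect_equal(nrow(nw2$edges), 2)
  expect_warning(build_network(assocs, alpha = 1e-9), "empty")
})

test_that("consensus includes a (pair, sign) only at min_recurrence networks", {
  nets <- list(manual_network("n1", "A", "B"),
               manual_network("n2", "A", "B"),
               manual_network("n3", c("A", "C"), c("C", "D")),
               manual_network("n4", "A", "B"),
               manual_network("n5", "C", "D", sign = "-"),
               manual_network("n6", "C", "D", sign = "-"))
  cons <- build_consensus(nets, min_recurrence = 3)
  # A-B positive in networks {1,2,4} -> included with recurrence 3
  expect_equal(nrow(cons$edges), 1)
  expect_equal(cons$edges$feature_a, "A")
  expect_equal(cons$edges$recurrence, 3)
  expect_equal(cons$edges$member_networks, "n1,n2,n4")
  # C-D: positive twice and negative twice -> neither sign reaches 3
  expect_false("C" %in% cons$nodes)
})

test_that("duplicate network ids are rejected", {
  nets <- list(manual_network("n1", "A", "B"), manual_network("n1", "A", "B"),
               manual_network("n2", "A", "B"))
  expect_error(build_consensus(nets), "duplicate network ids")
})

test_that("consensus delay is the modal member delay with deterministic ties", {
  nets <- list(manual_network("n1", "A", "B", delay = 1L),
               manual_network("n2", "A", "B", delay = 1L),
               manual_network("n3", "A", "B", delay = 0L),
               manual_network("n4", "A", "B", delay = 0L),
               manual_network("n5", "A", "B", delay = -1L))
  cons <- build_consensus(nets, min_recurrence = 3)
  expect_equal(cons$edges$consensus_delay, 0L)  # tie 2-2 -> smaller |delay|
  expect_equal(cons$edges$recurrence, 5)
})

test_that("edge orientation is canonical: delays flip when the pair is swapped", {
  a1 <- assoc_row("B", "A", delay = 2L)
  nw <- build_network(a1, alpha = 0.001, min_span = 6, network_id = "x")
  expect_equal(nw$edges$feature_a, "A")
  expect_equal(nw$edges$delay, -2L)
})

test_that("consensus edges shrink monotonically with min_recurrence and stay within the union", {
  set.seed(21)
  nets <- lapply(1:6, function(i) {
    pick <- which(runif(10) < 0.6)
    manual_network(paste0("n", i), LETTERS[pick], letters[pick])
  })
  sizes <- sapply(2:6, function(k)
    nrow(build_consensus(nets, min_recurrence = k)$edges))
  expect_true(all(diff(sizes) <= 0))
  cons <- build_consensus(nets, min_recurrence = 2)
  union_keys <- unique(unlist(lapply(nets, function(nw)
    edge_key(nw$edges$feature_a, nw$edges$feature_b, nw$edges$sign))))
  expect_true(all(edge_key(cons$edges$feature_a, cons$edges$feature_b,
                           cons$edges$sign) %in% union_keys))
  expect_true(all(cons$edges$recurrence <= 6))
})

test_that("the recurrence histogram reports fractions per level", {
  e <- edge_df(paste0("a", 1:100), paste0("b", 1:100),
               recurrence = c(rep(3L, 90), rep(6L, 10)))
  cons <- manual_consensus(e)
  h <- recurrence_histogram(cons)
  expect_equal(sum(h), 1)
  expect_equal(unname(h[c("3", "6")]), c(0.9, 0.1))
  expect_equal(unname(h[c("4", "5")]), c(0, 0))
  h2 <- recurrence_histogram(manual_consensus(edge_df("a", "b",
                                                      recurrence = 3L)))
  expect_equal(unname(h2["3"]), 1)
})

test_that("subnetwork extraction returns the closed first neighbourhood", {
  star <- edge_df(rep("hub", 4), paste0("leaf", 1:4))
  cons <- manual_consensus(star)
  sub <- extract_subnetwork(cons, "hub")
  expect_setequal(sub$nodes, c("hub", paste0("leaf", 1:4)))
  expect_equal(nrow(sub$edges), 4)
  # two seeds sharing a neighbour: the neighbour appears once
  tri <- edge_df(c("s1", "s2", "x"), c("n", "n", "y"))
  sub2 <- extract_subnetwork(manual_consensus(tri), c("s1", "s2"))
  expect_setequal(sub2$nodes, c("s1", "s2", "n"))
  expect_equal(nrow(sub2$edges), 2)
  # isolated seed
  iso <- manual_consensus(star, nodes = c("hub", paste0("leaf", 1:4), "alone"))
  sub3 <- extract_subnetwork(iso, "alone")
  expect_equal(sub3$nodes, "alone")
  expect_equal(nrow(sub3$edges), 0)
  expect_warning(extract_subnetwork(cons, c("hub", "ghost")), "ghost")
  expect_error(extract_subnetwork(cons, character(0)), "empty seed")
})

test_that("graphml export round-trips nodes, edges and attributes", {
  e <- edge_df(c("A", "B"), c("B", "C"), sign = c("+", "-"),
               recurrence = c(3L, 5L), consensus_delay = c(0L, 1L))
  cons <- manual_consensus(e)
  f <- tempfile(fileext = ".graphml")
  export_network(cons, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  ea <- igraph::as_data_frame(g)
  expect_setequal(ea$sign, c("+", "-"))
  expect_setequal(ea$recurrence, c(3, 5))
})

test_that("edge-list and SIF exports encode the expected rows", {
  e <- edge_df(c("A", "B"), c("B", "C"), sign = c("+", "-"))
  cons <- manual_consensus(e)
  f1 <- tempfile(fileext = ".tsv")
  export_network(cons, f1, "edge_list_tsv")
  expect_equal(nrow(read.delim(f1)), 2)
  f2 <- tempfile(fileext = ".sif")
  export_network(cons, f2, "sif")
  lines <- readLines(f2)
  expect_equal(lines, c("A\tpos\tB", "B\tneg\tC"))
  expect_error(export_network(cons, f1, "gexf"))
})
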