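test_that("compartment importance is the exact reciprocal of size", {
  ann <- compartment_annotation(list(P1 = "C1"), sizes = c(C1 = 1))
  expect_equal(compute_isc(ann), c(C1 = 1.0))
  ann4 <- compartment_annotation(list(P1 = "C1"), sizes = c(C1 = 4))
  expect_equal(compute_isc(ann4), c(C1 = 0.25))

  two <- compartment_annotation(list(P1 = c("C1", "C2")),
                                sizes = c(C1 = 5, C2 = 2))
  isc <- compute_isc(two)
  expect_true(isc[["C2"]] > isc[["C1"]])  # smaller compartment, larger ISC
  expect_error(compartment_annotation(list(P1 = "C1"), sizes = c(C1 = 0)))
})

test_that("edge weights follow the shared-max / union-min rule", {
  ann <- toy_annotation()  # sizes C1=10, C2=5, C3=2
  # shared compartment C2 -> max ISC over the intersection = 1/5
  expect_equal(edge_colocalization_weight("P1", "P2", ann), 0.2)
  # disjoint localization -> min ISC over the union = min(1/10, 1/2)
  expect_equal(edge_colocalization_weight("P3", "P4", ann), 0.1)
  # symmetric in the arguments
  expect_equal(edge_colocalization_weight("P2", "P1", ann),
               edge_colocalization_weight("P1", "P2", ann))
  # singleton shared compartment of size 1 gives weight 1
  one <- compartment_annotation(list(A = "C1", B = "C1"), sizes = c(C1 = 1))
  expect_equal(edge_colocalization_weight("A", "B", one), 1.0)
})

test_that("intersection branch always dominates the union branch", {
  set.seed(42)
  for (i in 1:50) {
    comps <- paste0("C", 1:6)
    sizes <- stats::setNames(sample(1:20, 6, replace = TRUE), comps)
    ann <- compartment_annotation(
      list(A = sample(comps, sample(1:4, 1)),
           B = sample(comps, sample(1:4, 1))),
      sizes = sizes)
    isc <- compute_isc(ann)
    shared <- intersect(ann$scl$A, ann$scl$B)
    if (length(shared) > 0L) {
      w <- edge_colocalization_weight("A", "B", ann)
      union_min <- min(isc[union(ann$scl$A, ann$scl$B)])
      expect_gte(w, union_min)
      expect_true(w > 0 && w <= 1)
    }
  }
})

test_that("network weighting covers every edge and handles the unannotated", {
  ann <- toy_annotation()
  g <- graph_from_pairs("P1", "P2", "P3", "P4", "P1", "P5")
  wg <- suppressMessages(weight_network(g, ann))
  w <- igraph::E(wg)$weight
  expect_length(w, 3L)
  expect_true(all(w > 0))
  # P5 has no annotation: union branch over P1's set, min(1/10, 1/5) = 0.1
  e15 <- igraph::get_edge_ids(wg, c("P1", "P5"))
  expect_equal(w[e15], 0.1)
  # a fully unannotated pair receives the fallback (min ISC = 1/10)
  g2 <- graph_from_pairs("P5", "P6")
  wg2 <- suppressMessages(weight_network(g2, ann))
  expect_equal(igraph::E(wg2)$weight, 0.1)
  expect_message(weight_network(g2, ann), "fallback")
  # node and edge sets unchanged
  expect_identical(igraph::V(wg)$name, igraph::V(g)$name)
})

test_that("per-protein prior sums incident weights; handshake holds", {
  star <- graph_from_pairs("A", "B", "A", "C", "A", "D")
  igraph::E(star)$weight <- rep(0.2, 3)
  ipsc <- compute_ipsc(star)
  expect_equal(ipsc[["A"]], 0.6)
  expect_equal(unname(ipsc[c("B", "C", "D")]), rep(0.2, 3))

  g <- igraph::add_vertices(star, 1, name = "E")  # isolated protein
  expect_equal(compute_ipsc(g)[["E"]], 0)

  set.seed(7)
  for (i in 1:10) {
    rg <- random_connected_graph(sample(10:30, 1))
    expect_equal(sum(compute_ipsc(rg)), 2 * sum(igraph::E(rg)$weight))
  }
  expect_error(compute_ipsc(graph_from_pairs("A", "B")), "weight")
})
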