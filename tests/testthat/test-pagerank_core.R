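test_that("transition model is stochastic with a normalized reset", {
  # path A-B-C with unit weights, row orientation: row B splits 0.5/0.5
  g <- graph_from_pairs("A", "B", "B", "C")
  igraph::E(g)$weight <- c(1, 1)
  m_row <- build_transition_model(g, ipsc = c(A = 1, B = 1, C = 1),
                                  alpha = 0.85, orientation = "row")
  M <- as.matrix(m_row$M1)
  expect_equal(M["A", "B"], 1.0)
  expect_equal(M["B", "A"], 0.5)
  expect_equal(M["B", "C"], 0.5)
  expect_equal(unname(rowSums(M)), rep(1, 3))
  # column orientation: columns sum to 1
  m_col <- build_transition_model(g, ipsc = c(A = 1, B = 1, C = 1))
  expect_equal(unname(colSums(as.matrix(m_col$M1))), rep(1, 3))
  # reset normalizes the prior
  expect_equal(unname(m_col$reset), rep(1 / 3, 3))
  expect_equal(sum(m_col$reset), 1)

  expect_error(build_transition_model(g, alpha = 1.5), "alpha")
  expect_error(build_transition_model(g, ipsc = c(A = 0, B = 0, C = 0)),
               "uniform")
})

test_that("symmetric fixed points are recovered exactly", {
  g2 <- graph_from_pairs("A", "B")
  igraph::E(g2)$weight <- 1
  fit <- mpr(build_transition_model(g2, c(A = 1, B = 1)))
  expect_equal(unname(fit$scores), c(0.5, 0.5))
  expect_true(fit$converged)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  igraph::E(k4)$weight <- rep(1, 6)
  fit4 <- mpr(build_transition_model(k4, stats::setNames(rep(1, 4),
                                                         LETTERS[1:4])))
  expect_equal(unname(fit4$scores), rep(0.25, 4))
})

test_that("power iteration matches the dense eigenvector oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    g <- random_connected_graph(n)
    ipsc <- compute_ipsc(g)
    for (orient in c("column", "row")) {
      model <- build_transition_model(g, ipsc, alpha = 0.85,
                                      orientation = orient)
      fit <- mpr(model, tol = 1e-14, max_iter = 5000)
      oracle <- dense_rank_oracle(g, ipsc, alpha = 0.85,
                                  orientation = orient)
      expect_lt(sum(abs(fit$scores - oracle)), 1e-8)
    }
  }
})

test_that("uniform weights and uniform reset degenerate to classic PageRank", {
  set.seed(202)
  for (i in 1:10) {
    g <- random_connected_graph(sample(10:40, 1), weighted = FALSE)
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
    fit_m <- mpr(build_transition_model(g, ipsc = NULL), tol = 1e-12)
    fit_c <- classic_pagerank(g, tol = 1e-12)
    expect_lt(sum(abs(fit_m$scores - fit_c$scores)), 1e-10)
  }
  # star graph: the hub outranks the leaves and both match the dense oracle
  star <- graph_from_pairs("H", "L1", "H", "L2", "H", "L3")
  fit <- classic_pagerank(star, tol = 1e-14, max_iter = 5000)
  expect_true(fit$scores[["H"]] > fit$scores[["L1"]])
  oracle <- dense_rank_oracle(star, alpha = 0.85)
  expect_lt(sum(abs(fit$scores - oracle)), 1e-8)
})

test_that("iterates stay normalized, non-negative and deterministic", {
  set.seed(303)
  g <- random_connected_graph(30)
  model <- build_transition_model(g, compute_ipsc(g))
  for (mi in c(1L, 3L, 10L, 200L)) {
    fit <- mpr(model, max_iter = mi)
    expect_equal(sum(fit$scores), 1, tolerance = 1e-12)
    expect_true(all(fit$scores >= 0))
  }
  expect_identical(mpr(model)$scores, mpr(model)$scores)
  # L2 norm option
  fit2 <- mpr(model, norm = "l2")
  expect_equal(sqrt(sum(fit2$scores^2)), 1, tolerance = 1e-12)
})

test_that("raising a protein's prior never lowers its converged score", {
  set.seed(404)
  for (i in 1:5) {
    g <- random_connected_graph(20)
    ipsc <- compute_ipsc(g)
    target <- sample(names(ipsc), 1)
    base <- mpr(build_transition_model(g, ipsc, alpha = 0.85),
                tol = 1e-12)$scores[[target]]
    ipsc2 <- ipsc
    ipsc2[[target]] <- ipsc2[[target]] * 3
    bumped <- mpr(build_transition_model(g, ipsc2, alpha = 0.85),
                  tol = 1e-12)$scores[[target]]
    expect_gte(bumped, base - 1e-12)
  }
})
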