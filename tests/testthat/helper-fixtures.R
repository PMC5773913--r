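# Shared fixtures and independent oracles for the test suite.

# Build an igraph PPI network from a two-column matrix of ID pairs.
graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Random connected graph with named vertices and optional random weights.
random_connected_graph <- function(n, p = 4 / n, weighted = TRUE) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0L) break
  }
  igraph::V(g)$name <- sprintf("P%03d", seq_len(n))
  if (weighted) igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.05, 1)
  g
}

# Dense dominant-eigenvector oracle for the power iteration: assembles the
# full combined operator and extracts its leading eigenvector directly.
dense_rank_oracle <- function(network, ipsc = NULL, alpha = 0.85,
                              orientation = "column") {
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  for (e in seq_len(nrow(el))) {
    A[el[e, 1L], el[e, 2L]] <- A[el[e, 1L], el[e, 2L]] + w[e]
    A[el[e, 2L], el[e, 1L]] <- A[el[e, 2L], el[e, 1L]] + w[e]
  }
  s <- rowSums(A)
  M1 <- if (orientation == "column") {
    sweep(A, 2L, ifelse(s > 0, s, 1), "/")
  } else {
    sweep(A, 1L, ifelse(s > 0, s, 1), "/")
  }
  r <- if (is.null(ipsc)) rep(1 / n, n) else {
    ri <- ipsc[nodes]
    ri / sum(ri)
  }
  M <- alpha * M1 + (1 - alpha) * outer(as.numeric(r), rep(1, n))
  ev <- eigen(M)
  v <- Re(ev$vectors[, which.max(Mod(ev$values))])
  if (sum(v) < 0) v <- -v
  stats::setNames(v / sum(abs(v)), nodes)
}

# From-first-principles Pearson correlation: explicit two-pass
# covariance / standard-deviation computation.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# Tiny annotation used across weighting tests.
toy_annotation <- function() {
  compartment_annotation(
    scl = list(P1 = c("C1", "C2"), P2 = c("C2", "C3"), P3 = "C1",
               P4 = "C3"),
    sizes = c(C1 = 10, C2 = 5, C3 = 2))
}

# Score the synthetic dataset with every ranker; returns named AUC vector.
auc_battery <- function(ds, lambda = 0.5) {
  wg <- suppressMessages(weight_network(ds$network, ds$annotation))
  fit <- mpr(build_transition_model(wg, compute_ipsc(wg)))
  ipcc <- suppressMessages(compute_ipcc(ds$network, ds$expression))
  c(scp = roc_curve(scp_score(fit, ipcc, lambda), ds$essential)$auc,
    mpr_only = roc_curve(scp_score(fit, ipcc, 1), ds$essential)$auc,
    ipcc_only = roc_curve(scp_score(fit, ipcc, 0), ds$essential)$auc,
    dc = roc_curve(degree_centrality(ds$network), ds$essential)$auc)
}
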