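#' Importance of subcellular compartments (ISC)
#'
#' A compartment's importance is the reciprocal of its member count,
#' `ISC(C) = 1 / N_C`: interactions confined to a small compartment are
#' treated as more reliable evidence of functional association than those in
#' a large one.
#'
#' @param annotation A [compartment_annotation()] object.
#' @return Named numeric vector of per-compartment importances in `(0, 1]`.
#' @export
compute_isc <- function(annotation) {
  stopifnot(inherits(annotation, "compartment_annotation"))
  sizes <- annotation$sizes
  if (length(sizes) == 0L) stop("annotation has no compartments")
  if (any(sizes <= 0)) stop("compartment sizes must be positive")
  1 / sizes
}

#' Co-localization weight of one interaction
#'
#' If the two proteins share at least one compartment, the edge weight is the
#' maximum ISC over the shared compartments (the smallest shared compartment
#' dominates). Otherwise it is the minimum ISC over the union of their
#' compartments (the least informative localization either protein has).
#' The weight is symmetric in its arguments.
#'
#' When neither protein carries any annotation the configured fallback is
#' returned; the default fallback is the minimum ISC present in the table,
#' i.e. the importance of the largest compartment, treating fully
#' unannotated pairs as the least reliable.
#'
#' @param p_i,p_j Protein IDs.
#' @param annotation A [compartment_annotation()] object.
#' @param isc Named numeric vector from [compute_isc()]; recomputed when
#'   `NULL`.
#' @param fallback Weight used when both proteins lack annotations
#'   (default `min(isc)`).
#' @return A single positive weight.
#' @export
edge_colocalization_weight <- function(p_i, p_j, annotation, isc = NULL,
                                       fallback = NULL) {
  if (is.null(isc)) isc <- compute_isc(annotation)
  if (is.null(fallback)) fallback <- min(isc)
  scl_i <- annotation$scl[[p_i]]
  scl_j <- annotation$scl[[p_j]]
  pair_weight(scl_i, scl_j, isc, fallback)
}

# Core of the two-branch rule, on raw compartment-ID vectors.
pair_weight <- function(scl_i, scl_j, isc, fallback) {
  if (is.null(scl_i) && is.null(scl_j)) return(fallback)
  shared <- intersect(scl_i, scl_j)
  if (length(shared) > 0L) {
    max(isc[shared])
  } else {
    min(isc[union(scl_i, scl_j)])
  }
}

#' Weight every network edge by compartment co-localization
#'
#' Applies [edge_colocalization_weight()] to each edge of the network and
#' stores the result as the `weight` edge attribute. Node and edge sets are
#' unchanged. Edges between two unannotated proteins receive the fallback
#' weight; their count is reported once per call.
#'
#' @param network An undirected [igraph::igraph] PPI network.
#' @param annotation A [compartment_annotation()] object.
#' @param fallback Fallback weight for doubly-unannotated pairs
#'   (default: minimum ISC, the importance of the largest compartment).
#' @return The same graph with a positive `weight` attribute on every edge.
#' @export
weight_network <- function(network, annotation, fallback = NULL) {
  stopifnot(igraph::vcount(network) > 0L)
  isc <- compute_isc(annotation)
  if (is.null(fallback)) fallback <- min(isc)
  el <- igraph::as_edgelist(network, names = TRUE)
  scl <- annotation$scl
  n_fallback <- 0L
  w <- numeric(nrow(el))
  for (e in seq_len(nrow(el))) {
    si <- scl[[el[e, 1L]]]
    sj <- scl[[el[e, 2L]]]
    if (is.null(si) && is.null(sj)) n_fallback <- n_fallback + 1L
    w[e] <- pair_weight(si, sj, isc, fallback)
  }
  if (n_fallback > 0L) {
    message("weight_network: ", n_fallback,
            " edge(s) between unannotated proteins received the fallback ",
            "weight ", format(fallback))
  }
  igraph::E(network)$weight <- w
  network
}

#' Per-protein prior importance from co-localization weights (IPSC)
#'
#' Sums the co-localization weights of all interactions incident to each
#' protein. Isolated proteins score 0. Used downstream as the reset
#' (personalization) distribution of the modified PageRank.
#'
#' @param network A weighted [igraph::igraph] network (see
#'   [weight_network()]).
#' @return Named numeric vector of non-negative per-protein sums.
#' @export
compute_ipsc <- function(network) {
  if (is.null(igraph::E(network)$weight)) {
    stop("network has no edge weights; call weight_network() first")
  }
  igraph::strength(network, weights = igraph::E(network)$weight)
}
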