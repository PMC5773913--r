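#' Min-max normalization of an importance score (NIS)
#'
#' Affine rescale of a score vector to `[0, 1]`; order-preserving. When all
#' scores are equal the vector is mapped to all zeros: a constant score
#' carries no ranking information.
#'
#' @param scores Named numeric vector.
#' @return Named numeric vector on `[0, 1]`.
#' @export
nis <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  if (any(!is.finite(scores))) stop("scores must be finite")
  lo <- min(scores)
  hi <- max(scores)
  if (hi == lo) {
    return(stats::setNames(numeric(length(scores)), names(scores)))
  }
  (scores - lo) / (hi - lo)
}

#' Fused SCP importance score
#'
#' Convex combination of the two normalized channels,
#' `SCP = lambda * NIS(MPR) + (1 - lambda) * NIS(IPCC)`. At `lambda = 1`
#' the output equals `NIS(mpr_scores)` exactly; at `lambda = 0` it equals
#' `NIS(ipcc_scores)` exactly.
#'
#' @param mpr_scores Named numeric vector: modified-PageRank scores (the
#'   `scores` element of an [mpr()] fit, or any score vector).
#' @param ipcc_scores Named numeric vector: expression-correlation scores
#'   over the same protein set (see [compute_ipcc()]).
#' @param lambda Mixing weight in `[0, 1]` (default 0.5).
#' @return Named numeric vector of SCP scores in `[0, 1]`, ordered as
#'   `mpr_scores`.
#' @export
scp_score <- function(mpr_scores, ipcc_scores, lambda = 0.5) {
  if (inherits(mpr_scores, "scp_rank")) mpr_scores <- mpr_scores$scores
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  ids_m <- names(mpr_scores)
  ids_c <- names(ipcc_scores)
  if (is.null(ids_m) || is.null(ids_c)) stop("score vectors must be named")
  if (!setequal(ids_m, ids_c)) {
    diff <- c(setdiff(ids_m, ids_c), setdiff(ids_c, ids_m))
    stop("protein ID sets differ between the two score vectors; e.g. ",
         paste(utils::head(diff, 10L), collapse = ", "))
  }
  a <- nis(mpr_scores)
  b <- nis(ipcc_scores)[ids_m]
  lambda * a + (1 - lambda) * b
}

#' Rank proteins by score
#'
#' Orders proteins by score in descending order; ties are broken by
#' ascending protein ID so the ranking is a deterministic pure function of
#' the scores, independent of input order.
#'
#' @param scores Named numeric vector.
#' @return Data frame with columns `rank` (1-based), `protein`, `score`.
#' @export
rank_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  ids <- names(scores)
  if (is.null(ids)) stop("score vector must be named")
  ord <- order(-scores, ids, method = "radix")
  data.frame(rank = seq_along(scores),
             protein = ids[ord],
             score = as.numeric(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Degree centrality
#'
#' Node degree as an importance score: the simplest topological baseline
#' for essential-protein ranking (the centrality-lethality heuristic).
#'
#' @param network An undirected [igraph::igraph] network.
#' @return Named numeric vector of degrees.
#' @export
degree_centrality <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty network")
  igraph::degree(network)
}
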