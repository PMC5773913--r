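#' @keywords internal
as_ranking <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "scp_rank")) x <- x$scores
  if (is.numeric(x) && !is.null(names(x))) return(rank_scores(x)$protein)
  stop("expected a named score vector or an ordered character vector of IDs")
}

#' Confusion counts at a ranking cutoff
#'
#' The top `k` proteins of the ranking are predicted positive, the rest
#' negative; counts are computed against the essential set restricted to
#' proteins present in the ranking.
#'
#' @param ranking Ordered character vector of protein IDs (best first), or a
#'   named score vector (ranked via [rank_scores()]).
#' @param essential Character vector of essential-protein IDs.
#' @param k Cutoff, `0 <= k <= length(ranking)`.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_at_k <- function(ranking, essential, k) {
  ranking <- as_ranking(ranking)
  n <- length(ranking)
  if (k < 0 || k > n) stop("k must be between 0 and ", n)
  pos <- ranking %in% essential
  tp <- sum(pos[seq_len(k)])
  fp <- k - tp
  fn <- sum(pos) - tp
  tn <- (n - k) - fn
  c(tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn))
}

# Shared threshold sweep over a (possibly truncated) ranking.
sweep_ranking <- function(scores, essential, restrict_top = NULL) {
  ranking <- as_ranking(scores)
  essential <- intersect(essential, ranking)
  n <- length(ranking)
  n_pos <- length(essential)
  n_neg <- n - n_pos
  if (n_pos == 0L) stop("no essential proteins among the scored proteins")
  if (n_neg == 0L) stop("no non-essential proteins among the scored proteins")
  k_max <- if (is.null(restrict_top)) n else restrict_top
  if (k_max < 1L || k_max > n) stop("restrict_top must be in [1, ", n, "]")
  hits <- cumsum(ranking[seq_len(k_max)] %in% essential)
  list(tp = hits, k = seq_len(k_max), n_pos = n_pos, n_neg = n_neg)
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

scp_curve <- function(points, auc, kind) {
  structure(list(points = points, auc = auc, kind = kind),
            class = "scp_curve")
}

#' @export
print.scp_curve <- function(x, ...) {
  cat("scp_curve (", x$kind, "): ", nrow(x$points), " points, AUC = ",
      format(x$auc), "\n", sep = "")
  invisible(x)
}

#' ROC curve over a ranking
#'
#' Sweeps the cutoff k over the ranking: the top k are predicted positive.
#' When `restrict_top` is given, only the first `restrict_top` positions are
#' swept (the protocol of evaluating only the top `|essential set|`
#' proteins); the curve is then closed with a final segment to (1, 1),
#' equivalent to a last threshold that predicts everything positive, so the
#' unranked tail contributes a straight chord rather than curve detail.
#' AUC is the trapezoidal area over the resulting points.
#'
#' @param scores Named score vector or ordered character ranking.
#' @param essential Character vector of essential-protein IDs; restricted to
#'   scored proteins before any count is formed.
#' @param restrict_top Optional cutoff limit (e.g. the number of known
#'   essential proteins).
#' @return An `scp_curve` with `points` (columns `x` = FPR, `y` = TPR) and
#'   trapezoidal `auc`.
#' @export
roc_curve <- function(scores, essential, restrict_top = NULL) {
  sw <- sweep_ranking(scores, essential, restrict_top)
  fpr <- c(0, (sw$k - sw$tp) / sw$n_neg)
  tpr <- c(0, sw$tp / sw$n_pos)
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  scp_curve(data.frame(x = fpr, y = tpr), trapezoid(fpr, tpr), "roc")
}

#' Precision-recall curve over a ranking
#'
#' Same sweep as [roc_curve()] with precision/recall coordinates:
#' at each cutoff k, precision = TP/k and recall = TP/P.
#'
#' @inheritParams roc_curve
#' @return An `scp_curve` with `points` (columns `x` = recall,
#'   `y` = precision) and trapezoidal `auc`.
#' @export
pr_curve <- function(scores, essential, restrict_top = NULL) {
  sw <- sweep_ranking(scores, essential, restrict_top)
  recall <- sw$tp / sw$n_pos
  precision <- sw$tp / sw$k
  scp_curve(data.frame(x = recall, y = precision),
            trapezoid(recall, precision), "pr")
}

#' Jackknife curve: cumulative essential count by rank
#'
#' x is the rank position 1..`top_n`; y is the cumulative number of true
#' essential proteins found up to that position. The trapezoidal area is
#' reported for method comparison.
#'
#' @inheritParams roc_curve
#' @param top_n Number of top positions to sweep.
#' @return An `scp_curve` with integer-valued non-decreasing `y`.
#' @export
jackknife_curve <- function(scores, essential, top_n) {
  ranking <- as_ranking(scores)
  if (top_n < 1L || top_n > length(ranking)) {
    stop("top_n must be in [1, ", length(ranking), "]")
  }
  essential <- intersect(essential, ranking)
  y <- cumsum(ranking[seq_len(top_n)] %in% essential)
  scp_curve(data.frame(x = seq_len(top_n), y = y),
            trapezoid(seq_len(top_n), y), "jackknife")
}

#' Essential-protein counts in the top percentage slices of a ranking
#'
#' For each percentage p the cutoff is `k = round-half-up(p/100 * N)` and
#' the count of true essentials among the top k is returned.
#'
#' @inheritParams roc_curve
#' @param percents Numeric vector of percentages in `(0, 100]`
#'   (default `c(1, 5, 10, 15, 20, 25)`).
#' @return Named integer vector, one count per percentage.
#' @export
top_percent_counts <- function(scores, essential,
                               percents = c(1, 5, 10, 15, 20, 25)) {
  if (any(percents <= 0 | percents > 100)) {
    stop("percents must lie in (0, 100]")
  }
  ranking <- as_ranking(scores)
  n <- length(ranking)
  pos <- ranking %in% essential
  counts <- vapply(percents, function(p) {
    k <- floor(p / 100 * n + 0.5)  # round half up
    as.integer(sum(pos[seq_len(k)]))
  }, integer(1))
  stats::setNames(counts, paste0(percents, "%"))
}

#' Link proportions within the top-k induced subnetwork
#'
#' Takes the subgraph induced by the top `top_k` ranked proteins on the full
#' network's edges and classifies each edge by the essentiality of its
#' endpoints: Ess-Ess, Ess-Noness or Noness-Noness. Fractions sum to 1
#' whenever the induced subgraph has at least one edge; with no edges all
#' fractions are reported as 0 and `n_edges` flags the situation.
#'
#' @param network The full undirected [igraph::igraph] PPI network.
#' @param ranking Ordered character vector or named score vector.
#' @param essential Character vector of essential-protein IDs.
#' @param top_k Number of top-ranked proteins to induce on (`>= 2`).
#' @return One-row data frame: `top_k`, `n_edges`, `ess_ess`, `ess_noness`,
#'   `noness_noness`.
#' @export
link_proportions <- function(network, ranking, essential, top_k) {
  ranking <- as_ranking(ranking)
  if (top_k < 2L) stop("top_k must be >= 2")
  top <- ranking[seq_len(min(top_k, length(ranking)))]
  sub <- igraph::induced_subgraph(network,
                                  intersect(top, igraph::V(network)$name))
  el <- igraph::as_edgelist(sub, names = TRUE)
  n_edges <- nrow(el)
  if (n_edges == 0L) {
    return(data.frame(top_k = top_k, n_edges = 0L,
                      ess_ess = 0, ess_noness = 0, noness_noness = 0))
  }
  ea <- el[, 1L] %in% essential
  eb <- el[, 2L] %in% essential
  n_ee <- sum(ea & eb)
  n_nn <- sum(!ea & !eb)
  n_en <- n_edges - n_ee - n_nn
  data.frame(top_k = top_k, n_edges = n_edges,
             ess_ess = n_ee / n_edges,
             ess_noness = n_en / n_edges,
             noness_noness = n_nn / n_edges)
}
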