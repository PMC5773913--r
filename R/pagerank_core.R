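#' Build the transition model for the modified PageRank
#'
#' The iteration matrix is a convex combination of two operators: a sparse
#' walk matrix over the weighted network and a rank-one reset whose
#' distribution is the normalized per-protein prior (IPSC). Only the sparse
#' part and the reset vector are stored; the rank-one operator acts as
#' `(reset %o% 1) v = reset * sum(v)`.
#'
#' @param network A weighted undirected [igraph::igraph] network.
#' @param ipsc Named numeric vector of per-protein priors (see
#'   [compute_ipsc()]). `NULL` requests a uniform reset distribution, which
#'   is also the documented fallback when all priors are zero.
#' @param alpha Dampening factor in `[0, 1]`: the probability mass following
#'   network links rather than the reset distribution. Default 0.85.
#' @param orientation Normalization of the walk matrix. `"column"` (default)
#'   divides the weight of edge (i, j) by the total incident weight of the
#'   *source* column j, the standard PageRank convention: with unit weights
#'   and a uniform reset the model degenerates exactly to classic PageRank.
#'   `"row"` divides by the total incident weight of row i instead
#'   (a row-stochastic operator); on an undirected network both yield a
#'   well-defined dominant eigenvector but generally different rankings.
#' @return An object of class `scp_transition_model`: list with the sparse
#'   walk matrix `M1` (a [Matrix::dgCMatrix]), the reset distribution
#'   `reset` (sums to 1), `alpha`, `nodes` and `orientation`.
#' @export
build_transition_model <- function(network, ipsc = NULL, alpha = 0.85,
                                   orientation = c("column", "row")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  n <- length(nodes)
  if (n == 0L) stop("empty network")

  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(network))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("edge weights must be finite and positive")
  }

  el <- igraph::as_edgelist(network, names = FALSE)
  i <- c(el[, 1L], el[, 2L])
  j <- c(el[, 2L], el[, 1L])
  x <- c(w, w)
  s <- igraph::strength(network, weights = w)  # total incident weight
  if (orientation == "column") {
    x <- x / s[j]
  } else {
    x <- x / s[i]
  }
  M1 <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                             dimnames = list(nodes, nodes))

  if (is.null(ipsc)) {
    reset <- rep(1 / n, n)
  } else {
    r <- ipsc[nodes]
    r[is.na(r)] <- 0
    if (any(r < 0)) stop("ipsc values must be non-negative")
    tot <- sum(r)
    if (tot == 0) {
      stop("all IPSC priors are zero; pass ipsc = NULL for a uniform reset")
    }
    reset <- as.numeric(r) / tot
  }
  names(reset) <- nodes
  structure(list(M1 = M1, reset = reset, alpha = alpha, nodes = nodes,
                 orientation = orientation),
            class = "scp_transition_model")
}

#' @export
print.scp_transition_model <- function(x, ...) {
  cat("scp_transition_model:", length(x$nodes), "proteins, alpha =", x$alpha,
      ",", x$orientation, "-normalized walk\n")
  invisible(x)
}

#' Modified PageRank by power iteration
#'
#' Iterates `v <- alpha * M1 v + (1 - alpha) * reset * sum(v)` followed by
#' renormalization, until the L1 distance between successive normalized
#' iterates drops below `tol` or `max_iter` is reached. The result is the
#' dominant eigenvector of the combined operator, normalized to sum 1.
#'
#' @param model An `scp_transition_model` from [build_transition_model()].
#' @param tol Convergence tolerance on the L1 distance between successive
#'   normalized iterates (default 1e-10).
#' @param max_iter Maximum number of iterations (default 1000).
#' @param init Starting vector: `"uniform"` (default) or `"reset"` (the
#'   model's reset distribution).
#' @param norm Norm used in the per-step renormalization: `"l1"` (default;
#'   scores behave like a probability distribution) or `"l2"`.
#' @return A list of class `scp_rank`: `scores` (named, non-negative,
#'   L1-normalized when `norm = "l1"`), `iterations`, `converged`,
#'   `residual`.
#' @export
mpr <- function(model, tol = 1e-10, max_iter = 1000L,
                init = c("uniform", "reset"), norm = c("l1", "l2")) {
  stopifnot(inherits(model, "scp_transition_model"))
  init <- match.arg(init)
  norm <- match.arg(norm)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  if (max_iter < 1L) stop("max_iter must be >= 1")

  n <- length(model$nodes)
  v <- if (init == "uniform") rep(1 / n, n) else as.numeric(model$reset)
  normalize <- function(u) {
    nv <- if (norm == "l1") sum(abs(u)) else sqrt(sum(u * u))
    u / nv
  }
  v <- normalize(v)
  alpha <- model$alpha
  converged <- FALSE
  resid <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    v_new <- alpha * as.numeric(model$M1 %*% v) +
      (1 - alpha) * model$reset * sum(v)
    if (any(!is.finite(v_new))) {
      stop("non-finite values in iteration ", it,
           "; check edge weights and priors")
    }
    v_new <- normalize(v_new)
    resid <- sum(abs(v_new - v))
    v <- v_new
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  scores <- stats::setNames(as.numeric(v), model$nodes)
  structure(list(scores = scores, iterations = it, converged = converged,
                 residual = resid),
            class = "scp_rank")
}

#' @export
print.scp_rank <- function(x, ...) {
  cat("scp_rank:", length(x$scores), "proteins;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(residual %.3g)\n", x$residual))
  invisible(x)
}

#' Classic PageRank on an unweighted network
#'
#' The unweighted-uniform special case of the modified PageRank: walk
#' probabilities `1/degree` and a uniform reset distribution `1/N`. Kept as
#' an explicit baseline and as the degeneracy reference for [mpr()].
#'
#' @param network An undirected [igraph::igraph] network (edge weights, if
#'   present, are ignored).
#' @param alpha Dampening factor (default 0.85).
#' @inheritParams mpr
#' @return An `scp_rank` list (see [mpr()]).
#' @export
classic_pagerank <- function(network, alpha = 0.85, tol = 1e-10,
                             max_iter = 1000L,
                             init = c("uniform", "reset"),
                             norm = c("l1", "l2")) {
  g <- network
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  model <- build_transition_model(g, ipsc = NULL, alpha = alpha,
                                  orientation = "column")
  mpr(model, tol = tol, max_iter = max_iter, init = match.arg(init),
      norm = match.arg(norm))
}
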