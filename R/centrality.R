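#' Topology-only centrality baselines
#'
#' Standard centrality measures computed on the interaction network alone,
#' used as comparison baselines for OGN. All downstream evaluation is
#' rank-based, so any fixed monotone normalization variant is acceptable;
#' the conventions used here are documented per measure.
#'
#' * `degree_centrality()`: number of interaction partners.
#' * `betweenness_centrality()`: unnormalized shortest-path betweenness with
#'   each unordered source/target pair counted once (Brandes).
#' * `closeness_centrality()`: component-local (Wasserman–Faust) closeness,
#'   `(n_c - 1) / sum of distances` within the node's component; isolated
#'   nodes score 0.
#' * `eigenvector_centrality()`: entry of the principal eigenvector of the
#'   adjacency matrix, computed by power iteration on `A + I` (same
#'   eigenvectors as `A`; the shift makes the Perron eigenvalue strictly
#'   dominant so bipartite networks converge too) from a uniform positive
#'   start, returned with unit Euclidean norm. A network with no edges gets
#'   the uniform vector.
#' * `subgraph_centrality()`: `(e^A)_vv`, the closed-walk count of the node
#'   weighted by inverse factorial of walk length, via the spectral
#'   decomposition of the adjacency matrix.
#'
#' @param net Undirected igraph network with named vertices.
#' @param tol Power-iteration convergence tolerance (max absolute change).
#' @param max_iter Power-iteration cap; exceeding it is an error naming the cap.
#' @return Named numeric vector of scores, one per vertex.
#' @name centrality_baselines
NULL

score_vector <- function(values, proteins, measure) {
  stats::setNames(as.numeric(values), proteins)
}

#' @rdname centrality_baselines
#' @export
degree_centrality <- function(net) {
  score_vector(igraph::degree(net), igraph::V(net)$name, "DC")
}

#' @rdname centrality_baselines
#' @export
betweenness_centrality <- function(net) {
  score_vector(igraph::betweenness(net, directed = FALSE, normalized = FALSE),
               igraph::V(net)$name, "BC")
}

#' @rdname centrality_baselines
#' @export
closeness_centrality <- function(net) {
  cc <- suppressWarnings(igraph::closeness(net, normalized = TRUE))
  cc[!is.finite(cc)] <- 0  # isolated nodes
  score_vector(cc, igraph::V(net)$name, "CC")
}

#' @rdname centrality_baselines
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 1000L) {
  n <- igraph::vcount(net)
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  if (igraph::ecount(net) == 0L)
    return(score_vector(rep(1 / sqrt(n), n), igraph::V(net)$name, "EC"))
  x <- rep(1 / sqrt(n), n)
  # iterate on A + I: same eigenvectors, but the Perron eigenvalue becomes
  # strictly dominant in magnitude, so bipartite graphs cannot oscillate
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% x) + x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) stop("power iteration hit the zero vector; the adjacency ",
                       "matrix has no positive dominant eigenpair")
    y <- y / nrm
    if (max(abs(y - x)) < tol)
      return(score_vector(y, igraph::V(net)$name, "EC"))
    x <- y
  }
  stop("eigenvector centrality did not converge within max_iter = ", max_iter)
}

#' @rdname centrality_baselines
#' @export
subgraph_centrality <- function(net) {
  a <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  es <- eigen(a, symmetric = TRUE)
  sc <- as.numeric((es$vectors^2) %*% exp(es$values))
  score_vector(sc, igraph::V(net)$name, "SC")
}

#' Compute a centrality baseline by name
#'
#' @param net Undirected igraph network.
#' @param measure One of `"dc"`, `"bc"`, `"cc"`, `"ec"`, `"sc"`.
#' @return Named score vector (see [centrality_baselines]).
#' @export
centrality <- function(net, measure = c("dc", "bc", "cc", "ec", "sc")) {
  measure <- match.arg(measure)
  switch(measure,
         dc = degree_centrality(net),
         bc = betweenness_centrality(net),
         cc = closeness_centrality(net),
         ec = eigenvector_centrality(net),
         sc = subgraph_centrality(net))
}
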