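#' Pearson correlation between two expression profiles
#'
#' Standard sample Pearson correlation. If either profile has zero variance
#' the correlation is undefined; the convention used throughout the package
#' is to return `zero_variance_value` (default 0: a flat profile carries no
#' co-expression evidence).
#'
#' @param x,y Numeric vectors of equal length (>= 2), finite values.
#' @param zero_variance_value Value returned when either profile is constant.
#' @return A number in `[-1, 1]` (or `zero_variance_value`).
#' @export
pearson_correlation <- function(x, y, zero_variance_value = 0) {
  if (length(x) != length(y))
    stop("profile length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("profiles must have length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(zero_variance_value)
  min(1, max(-1, stats::cor(x, y)))
}

#' Local clustering coefficient of a protein
#'
#' The fraction of a node's neighbour pairs that are themselves connected:
#' `Co(v) = 2 * t(v) / (k_v * (k_v - 1))` with `t(v)` the number of edges
#' among the neighbours of `v` and `k_v` its degree. Nodes with `k_v <= 1`
#' score 0 (a neighbourhood of fewer than two nodes cannot form a clique and
#' the denominator vanishes).
#'
#' @param net Undirected igraph network with named vertices.
#' @param v Protein identifier(s); defaults to every node.
#' @return Named numeric vector of clustering coefficients in `[0, 1]`.
#' @export
local_clustering <- function(net, v = igraph::V(net)$name) {
  if (!all(v %in% igraph::V(net)$name))
    stop("unknown node(s): ", paste(setdiff(v, igraph::V(net)$name), collapse = ", "))
  co <- igraph::transitivity(net, type = "local", vids = v, isolates = "NaN")
  co[!is.finite(co)] <- 0  # degree <= 1
  stats::setNames(co, v)
}

# Pairwise PCC for the endpoints of every edge, computed from standardized
# profiles so only the O(m) needed pairs are touched. Rows with zero variance
# yield `zero_variance_value` for every pair containing them.
edge_pcc <- function(universe, zero_variance_value = 0) {
  expr <- universe$expression
  s <- ncol(expr)
  mu <- rowMeans(expr)
  sd <- apply(expr, 1L, stats::sd)
  z <- (expr - mu) / ifelse(sd > 0, sd, 1)
  el <- igraph::as_edgelist(universe$graph)
  if (nrow(el) == 0L) return(numeric(0))
  pcc <- rowSums(z[el[, 1L], , drop = FALSE] * z[el[, 2L], , drop = FALSE]) / (s - 1)
  pcc <- pmin(1, pmax(-1, pcc))
  flat <- sd == 0
  if (any(flat)) {
    hit <- flat[el[, 1L]] | flat[el[, 2L]]
    pcc[hit] <- zero_variance_value
  }
  pcc
}

#' Co-expression-weighted neighbourhood clustering score (TPN)
#'
#' The topological term of OGN: for each protein `u`,
#' `TPN(u) = sum over neighbours v of PCC(u, v) * Co(v)`,
#' where `PCC` is the Pearson correlation of the two expression profiles and
#' `Co` the local clustering coefficient of the neighbour. Summing the
#' neighbours' (rather than the node's own) cliquishness, weighted by
#' co-expression, scores date hubs and party hubs on a common footing.
#' Isolated proteins score 0 (empty sum).
#'
#' @param universe An `"ogn_universe"` (see [build_universe()]).
#' @param pcc_policy `"raw"` (default) uses signed correlations as the score
#'   definition prescribes; `"clamp_nonnegative"` floors negative
#'   correlations at 0, treating PCC as a co-expression probability.
#' @param zero_variance_pcc PCC value assigned to pairs involving a constant
#'   expression profile.
#' @return Named numeric vector of TPN values over the universe.
#' @export
tpn <- function(universe, pcc_policy = c("raw", "clamp_nonnegative"),
                zero_variance_pcc = 0) {
  pcc_policy <- match.arg(pcc_policy)
  stopifnot(inherits(universe, "ogn_universe"))
  pcc <- edge_pcc(universe, zero_variance_pcc)
  if (pcc_policy == "clamp_nonnegative") pcc <- pmax(0, pcc)
  co <- local_clustering(universe$graph)
  el <- igraph::as_edgelist(universe$graph)
  out <- stats::setNames(numeric(length(universe$proteins)), universe$proteins)
  if (nrow(el) > 0L) {
    # each edge contributes PCC(u,v)*Co(v) to u and PCC(u,v)*Co(u) to v
    contrib_u <- pcc * co[el[, 2L]]
    contrib_v <- pcc * co[el[, 1L]]
    add_u <- tapply(contrib_u, el[, 1L], sum)
    add_v <- tapply(contrib_v, el[, 2L], sum)
    out[names(add_u)] <- out[names(add_u)] + add_u
    out[names(add_v)] <- out[names(add_v)] + add_v
  }
  out
}

#' Normalized orthology conservation score (OS)
#'
#' The raw score of a protein is the number of reference organisms containing
#' an ortholog of it divided by the total number of reference organisms;
#' proteins absent from the orthology table score 0. Raw scores are then
#' max-normalized across the universe, so the most conserved protein scores
#' exactly 1. If every count is zero the scores are all 0.
#'
#' @param orth An `"orthology_table"`.
#' @param universe Character vector of protein identifiers to score.
#' @return Named numeric vector of normalized scores in `[0, 1]`.
#' @export
orthology_score <- function(orth, universe) {
  stopifnot(inherits(orth, "orthology_table"), length(universe) > 0L)
  counts <- stats::setNames(numeric(length(universe)), universe)
  hit <- intersect(names(orth$counts), universe)
  counts[hit] <- orth$counts[hit]
  raw <- counts / orth$n_reference
  m <- max(raw)
  if (m == 0) return(raw)
  raw / m
}

#' Fit the OGN essentiality score on an analysis universe
#'
#' Scores every protein in the universe with the OGN centrality
#' `OGN(u) = alpha * OS(u) + (1 - alpha) * TPN(u) / max TPN`,
#' a convex blend of evolutionary conservation ([orthology_score()]) and the
#' co-expression-weighted neighbourhood clustering score ([tpn()]). `alpha`
#' shifts the weight from pure topology/co-expression (`alpha = 0`) to pure
#' conservation (`alpha = 1`).
#'
#' If the maximal TPN is not positive (possible with signed correlations on
#' pathological data) its normalization is undefined; the topological term is
#' then set to 0 for every protein and a message records the convention.
#'
#' @param universe An `"ogn_universe"` from [build_universe()], or an
#'   `"ogn_synthetic"` dataset (its universe is built automatically).
#' @param alpha Blend weight in `[0, 1]`; the default 0.3 leans on topology
#'   while retaining conservation evidence.
#' @param pcc_policy,zero_variance_pcc Passed to [tpn()].
#' @return An object of class `"ogn"`: a list with `scores` (named vector,
#'   the OGN values), `components` (data.frame with per-protein `ogn`,
#'   `os_norm`, `tpn`, `tpn_norm`, `co`, `degree`), `alpha`, `pcc_policy`,
#'   `universe`, and `call`. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, and `plot()`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_proteins = 60, n_essential = 20,
#'                                       module_size = 5, seed = 1))
#' fit <- ogn(ds, alpha = 0.3)
#' head(predict(fit, n = 10))
#' @export
ogn <- function(universe, alpha = 0.3,
                pcc_policy = c("raw", "clamp_nonnegative"),
                zero_variance_pcc = 0) {
  if (inherits(universe, "ogn_synthetic"))
    universe <- build_universe(universe$network, universe$expression,
                               universe$orthology)
  stopifnot(inherits(universe, "ogn_universe"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  pcc_policy <- match.arg(pcc_policy)
  orth <- orthology_table(universe$orth_counts, universe$n_reference)
  os_norm <- orthology_score(orth, universe$proteins)
  tpn_raw <- tpn(universe, pcc_policy, zero_variance_pcc)
  max_tpn <- max(tpn_raw)
  if (max_tpn > 0) {
    tpn_norm <- tpn_raw / max_tpn
  } else {
    message("ogn: max(TPN) <= 0; topological term set to 0 for all proteins")
    tpn_norm <- stats::setNames(numeric(length(tpn_raw)), names(tpn_raw))
  }
  scores <- alpha * os_norm + (1 - alpha) * tpn_norm
  stopifnot(all(is.finite(scores)))
  components <- data.frame(
    protein  = universe$proteins,
    ogn      = unname(scores),
    os_norm  = unname(os_norm),
    tpn      = unname(tpn_raw),
    tpn_norm = unname(tpn_norm),
    co       = unname(local_clustering(universe$graph)),
    degree   = unname(igraph::degree(universe$graph)),
    row.names = NULL
  )
  structure(list(scores = scores, components = components, alpha = alpha,
                 pcc_policy = pcc_policy, universe = universe,
                 call = match.call()),
            class = "ogn")
}

#' @export
print.ogn <- function(x, ...) {
  cat("OGN essentiality score fit\n")
  cat("  alpha = ", x$alpha, " (PCC policy: ", x$pcc_policy, ")\n", sep = "")
  cat("  ", length(x$scores), " proteins scored; top-ranked: ",
      paste(utils::head(rank_scores(x$scores), 5L), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.ogn <- function(object, n = 10L, ...) {
  ord <- rank_scores(object$scores)
  top <- object$components[match(utils::head(ord, n), object$components$protein), ]
  structure(list(alpha = object$alpha, pcc_policy = object$pcc_policy,
                 n_proteins = length(object$scores),
                 score_quartiles = stats::quantile(object$scores),
                 top = top),
            class = "summary.ogn")
}

#' @export
print.summary.ogn <- function(x, ...) {
  cat("OGN fit over", x$n_proteins, "proteins (alpha =", x$alpha, ")\n")
  cat("Score quartiles:\n")
  print(round(x$score_quartiles, 4))
  cat("Top-ranked proteins:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.ogn <- function(object, ...) object$scores

#' Predict essential-protein candidates from an OGN fit
#'
#' @param object An `"ogn"` fit.
#' @param n Number of top-ranked proteins to return as candidates.
#' @param ... Unused.
#' @return Character vector: the top-`n` protein identifiers, best first
#'   (ties broken by ascending identifier).
#' @export
predict.ogn <- function(object, n = 100L, ...) {
  top_n(rank_scores(object$scores), n)
}

#' Plot an OGN fit
#'
#' Without labels, plots the sorted score profile. With essentiality labels,
#' plots the Jackknife curve: cumulative true essentials among the top-x
#' ranked proteins against x, with the random-ranking diagonal for reference.
#'
#' @param x An `"ogn"` fit.
#' @param labels Optional character vector of essential-protein identifiers.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ogn <- function(x, labels = NULL, ...) {
  if (is.null(labels)) {
    graphics::plot(sort(x$scores, decreasing = TRUE), type = "l",
                   xlab = "rank", ylab = "OGN score",
                   main = sprintf("OGN score profile (alpha = %g)", x$alpha), ...)
  } else {
    jk <- jackknife(rank_scores(x$scores), labels)
    graphics::plot(jk$rank, jk$cumulative, type = "l",
                   xlab = "top n ranked candidates",
                   ylab = "true essential proteins",
                   main = sprintf("Jackknife curve (alpha = %g)", x$alpha), ...)
    n_ess <- max(jk$cumulative)
    graphics::abline(0, n_ess / nrow(jk), lty = 2, col = "grey50")
  }
  invisible(x)
}
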