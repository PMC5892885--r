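#' Rank proteins by score, best first
#'
#' Deterministic ranking: descending score, ties broken by ascending protein
#' identifier, so identical inputs always produce identical rankings.
#'
#' @param scores Named numeric vector with one finite score per protein.
#' @return Character vector: the protein identifiers in rank order.
#' @export
rank_scores <- function(scores) {
  if (is.null(names(scores)) || anyNA(names(scores)))
    stop("scores must be a named vector")
  if (!all(is.finite(scores))) stop("non-finite score for protein(s): ",
                                    paste(names(scores)[!is.finite(scores)],
                                          collapse = ", "))
  names(scores)[order(-scores, names(scores), method = "radix")]
}

#' Top-n ranked proteins
#'
#' @param ranking Character vector from [rank_scores()], best first.
#' @param n Positive integer, at most the universe size.
#' @return The first `n` identifiers of the ranking.
#' @export
top_n <- function(ranking, n) {
  if (n < 1L || n > length(ranking))
    stop("n must be in [1, ", length(ranking), "], got ", n)
  ranking[seq_len(n)]
}

#' Majority-voting ensemble of OGN over a grid of alpha values
#'
#' Fits OGN at each alpha in `alphas`, takes the top-`n` set of each ranking,
#' and gives every protein an ensemble score `ES(u)` = the number of top-`n`
#' sets containing it (0..M for a grid of M values). Proteins whose ensemble
#' score exceeds the majority threshold `T` are selected as essential
#' candidates, ordered by descending vote count and ascending identifier.
#' This removes the need to know the optimal alpha for a new organism: a
#' protein must rank highly under most blend weights to be selected.
#'
#' The default comparator is strict (`ES > T`). For a grid of `M` rankings a
#' majority threshold of at least `ceiling(M / 2)` is conventional; smaller
#' values are permitted with a warning.
#'
#' @param universe An `"ogn_universe"` or `"ogn_synthetic"` dataset.
#' @param alphas Numeric grid of blend weights in `[0, 1]`; default
#'   `seq(0, 1, by = 0.1)` (M = 11 rankings).
#' @param n Top-n cutoff applied to each ranking.
#' @param threshold Vote threshold `T` (`0 <= T <= M`).
#' @param comparator `"gt"` selects `ES > T` (default); `"ge"` selects
#'   `ES >= T`.
#' @param pcc_policy,zero_variance_pcc Passed to [ogn()].
#' @return An object of class `"ogn_ensemble"`: list with `es` (named integer
#'   vote counts over the whole universe), `candidates` (selected protein
#'   identifiers in order), `per_alpha_top` (list of the M top-n sets),
#'   `pool` (union of the top-n sets), `alphas`, `n`, `threshold`,
#'   `comparator`.
#' @export
ogn_ensemble <- function(universe, alphas = seq(0, 1, by = 0.1), n = 100L,
                         threshold = 5L, comparator = c("gt", "ge"),
                         pcc_policy = c("raw", "clamp_nonnegative"),
                         zero_variance_pcc = 0) {
  comparator <- match.arg(comparator)
  pcc_policy <- match.arg(pcc_policy)
  if (inherits(universe, "ogn_synthetic"))
    universe <- build_universe(universe$network, universe$expression,
                               universe$orthology)
  stopifnot(inherits(universe, "ogn_universe"))
  m <- length(alphas)
  if (m < 1L) stop("alpha grid must contain at least one value")
  if (any(alphas < 0 | alphas > 1)) stop("alpha values must lie in [0, 1]")
  if (threshold < 0L || threshold > m)
    stop("threshold must be in [0, M = ", m, "]")
  if (threshold < ceiling(m / 2))
    warning("threshold ", threshold, " is below the majority point ceiling(M/2) = ",
            ceiling(m / 2))
  per_alpha_top <- lapply(alphas, function(a) {
    fit <- ogn(universe, alpha = a, pcc_policy = pcc_policy,
               zero_variance_pcc = zero_variance_pcc)
    top_n(rank_scores(fit$scores), n)
  })
  es <- stats::setNames(integer(length(universe$proteins)), universe$proteins)
  for (set in per_alpha_top) es[set] <- es[set] + 1L
  selected <- if (comparator == "gt") es > threshold else es >= threshold
  cand <- names(es)[selected]
  cand <- cand[order(-es[cand], cand, method = "radix")]
  structure(list(es = es, candidates = cand, per_alpha_top = per_alpha_top,
                 pool = sort(unique(unlist(per_alpha_top))),
                 alphas = alphas, n = as.integer(n),
                 threshold = as.integer(threshold), comparator = comparator),
            class = "ogn_ensemble")
}

#' @export
print.ogn_ensemble <- function(x, ...) {
  cat("OGN majority-voting ensemble\n")
  cat("  M = ", length(x$alphas), " alpha values, top n = ", x$n,
      ", threshold T = ", x$threshold,
      " (", if (x$comparator == "gt") "ES > T" else "ES >= T", ")\n", sep = "")
  cat("  candidate pool |X| = ", length(x$pool), "; selected candidates = ",
      length(x$candidates), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ogn_ensemble <- function(object, ...) {
  tab <- table(factor(object$es[object$pool], levels = 0:length(object$alphas)))
  structure(list(vote_table = tab, n_candidates = length(object$candidates),
                 threshold = object$threshold, m = length(object$alphas)),
            class = "summary.ogn_ensemble")
}

#' @export
print.summary.ogn_ensemble <- function(x, ...) {
  cat("Ensemble vote distribution over the candidate pool (ES : #proteins):\n")
  print(x$vote_table)
  cat(x$n_candidates, "candidate(s) selected at threshold", x$threshold,
      "of", x$m, "\n")
  invisible(x)
}
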