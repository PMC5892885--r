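#' Count true essential proteins in a candidate list
#'
#' @param top Character vector of candidate protein identifiers.
#' @param labels Character vector of known essential-protein identifiers.
#' @return Integer: size of the intersection.
#' @export
count_true <- function(top, labels) {
  length(intersect(top, labels))
}

#' Jackknife cumulative-prediction curve
#'
#' For each rank cutoff x, the number of true essential proteins among the
#' top-x ranked candidates. The curve is non-decreasing with unit steps and
#' ends at the number of essential proteins present in the universe.
#'
#' @param ranking Character vector from [rank_scores()], best first, covering
#'   the universe.
#' @param labels Character vector of essential-protein identifiers; those
#'   outside the ranking are ignored (a message reports how many).
#' @return A data.frame with columns `rank` (1..N) and `cumulative`.
#' @export
jackknife <- function(ranking, labels) {
  outside <- setdiff(labels, ranking)
  if (length(outside) > 0L)
    message("jackknife: ", length(outside),
            " labelled essential protein(s) not in the universe")
  data.frame(rank = seq_along(ranking),
             cumulative = cumsum(ranking %in% labels))
}

#' Precision-recall curve of a ranked candidate list
#'
#' At each rank cutoff x: precision = (true essentials in top-x) / x and
#' recall = (true essentials in top-x) / (essential proteins in the
#' universe). Recall is non-decreasing and reaches 1 at the full cutoff.
#'
#' @inheritParams jackknife
#' @return A data.frame with columns `rank`, `precision`, `recall`.
#' @export
precision_recall <- function(ranking, labels) {
  n_ess <- length(intersect(labels, ranking))
  if (n_ess == 0L)
    stop("no labelled essential protein is present in the universe; ",
         "recall is undefined")
  jk <- jackknife(ranking, labels)
  data.frame(rank = jk$rank,
             precision = jk$cumulative / jk$rank,
             recall = jk$cumulative / n_ess)
}

#' Top-n performance report for one or more score vectors
#'
#' For each scoring method and each cutoff n, counts the true essential
#' proteins among the top-n ranked candidates and reports the precision with
#' denominator n (the fixed-budget protocol).
#'
#' @param scores A named numeric score vector, or a named list of them (names
#'   label the methods).
#' @param labels Character vector of essential-protein identifiers.
#' @param n_values Integer cutoffs.
#' @return A data.frame with columns `method`, `n`, `true_positives`,
#'   `precision`.
#' @export
top_n_report <- function(scores, labels, n_values = seq(100L, 600L, by = 100L)) {
  if (!is.list(scores)) scores <- list(score = scores)
  if (is.null(names(scores))) names(scores) <- paste0("method", seq_along(scores))
  rows <- lapply(names(scores), function(method) {
    ranking <- rank_scores(scores[[method]])
    data.frame(method = method, n = as.integer(n_values),
               true_positives = vapply(n_values, function(n)
                 count_true(top_n(ranking, n), labels), integer(1L)))
  })
  out <- do.call(rbind, rows)
  out$precision <- out$true_positives / out$n
  out
}

#' Ensemble performance table over top-n and threshold grids
#'
#' For every combination of top-n cutoff and vote threshold T, runs the
#' majority-voting ensemble and reports the number of selected candidates,
#' the number of true essential proteins among them, and the precision with
#' denominator #predicted (the ensemble protocol; `NA` when nothing is
#' selected).
#'
#' @param universe An `"ogn_universe"` or `"ogn_synthetic"` dataset.
#' @param labels Character vector of essential-protein identifiers.
#' @param alphas Alpha grid passed to [ogn_ensemble()].
#' @param n_values Top-n cutoffs.
#' @param t_values Vote thresholds.
#' @param ... Passed to [ogn_ensemble()].
#' @return A data.frame with columns `n`, `threshold`, `predicted`, `true`,
#'   `precision`.
#' @export
ensemble_table <- function(universe, labels, alphas = seq(0, 1, by = 0.1),
                           n_values = c(100L, 200L, 300L, 400L, 500L),
                           t_values = 5:10, ...) {
  if (inherits(universe, "ogn_synthetic"))
    universe <- build_universe(universe$network, universe$expression,
                               universe$orthology)
  rows <- list()
  for (n in n_values) {
    # one vote count per n; thresholding is then a cheap filter
    ens <- suppressWarnings(
      ogn_ensemble(universe, alphas = alphas, n = n,
                   threshold = ceiling(length(alphas) / 2), ...))
    for (t in t_values) {
      sel <- if (ens$comparator == "ge") ens$es >= t else ens$es > t
      cand <- names(ens$es)[sel]
      np <- length(cand)
      nt <- count_true(cand, labels)
      rows[[length(rows) + 1L]] <- data.frame(
        n = as.integer(n), threshold = as.integer(t),
        predicted = np, true = nt,
        precision = if (np > 0L) nt / np else NA_real_)
    }
  }
  do.call(rbind, rows)
}
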