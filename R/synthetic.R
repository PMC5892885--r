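#' Specification for a synthetic essential-protein benchmark
#'
#' Describes a seeded synthetic dataset with planted essential-protein
#' signal in all three evidence channels:
#'
#' * **Topology**: essential proteins are partitioned into cohesive modules
#'   (protein-complex analogues) wired densely (`p_within_module`), on top of
#'   a sparse background (`p_background`). `n_decoy_modules` additional
#'   modules of non-essential proteins share the same wiring and
#'   co-expression, so topology alone cannot separate the classes.
#' * **Co-expression**: members of a module share a latent expression factor
#'   with loading `sqrt(rho_within)` plus idiosyncratic Gaussian noise, so
#'   intra-module pairwise correlation targets `rho_within` exactly; all
#'   other pairs are uncorrelated in expectation.
#' * **Conservation**: ortholog counts are Binomial(`n_reference`,
#'   `p_orthology`) for non-essential and Binomial(`n_reference`,
#'   `p_orthology + orthology_enrichment`) for essential proteins.
#' * Optionally, `n_date_hubs` essential date-hub analogues are added:
#'   high-degree proteins whose partners are spread across modules (low
#'   neighbourhood clustering, staggered co-expression).
#'
#' @param n_proteins Total number of proteins.
#' @param n_essential Number of planted essential proteins.
#' @param n_samples Number of expression samples.
#' @param module_size Size of each planted module.
#' @param n_decoy_modules Number of non-essential modules with the same
#'   topology/co-expression signature as essential modules.
#' @param p_background Background edge probability.
#' @param p_within_module Intra-module edge probability.
#' @param rho_within Target intra-module pairwise expression correlation,
#'   in (-1, 1) and non-negative in this construction.
#' @param p_orthology Baseline per-reference-organism ortholog probability.
#' @param orthology_enrichment Added ortholog probability for essential
#'   proteins.
#' @param n_reference Number of reference organisms.
#' @param n_date_hubs Number of essential date-hub analogues (taken from
#'   `n_essential`; their partners span modules).
#' @param seed Integer seed; fixed seed gives a byte-identical dataset.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_proteins = 500L, n_essential = 100L,
                           n_samples = 36L, module_size = 10L,
                           n_decoy_modules = 5L,
                           p_background = 0.01, p_within_module = 0.9,
                           rho_within = 0.8,
                           p_orthology = 0.25, orthology_enrichment = 0.05,
                           n_reference = 99L, n_date_hubs = 0L,
                           seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               n_essential = as.integer(n_essential),
               n_samples = as.integer(n_samples),
               module_size = as.integer(module_size),
               n_decoy_modules = as.integer(n_decoy_modules),
               p_background = p_background,
               p_within_module = p_within_module,
               rho_within = rho_within,
               p_orthology = p_orthology,
               orthology_enrichment = orthology_enrichment,
               n_reference = as.integer(n_reference),
               n_date_hubs = as.integer(n_date_hubs),
               seed = as.integer(seed))
  probs <- c(spec$p_background, spec$p_within_module,
             spec$p_orthology, spec$p_orthology + spec$orthology_enrichment)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (spec$rho_within < 0 || spec$rho_within >= 1)
    stop("rho_within must lie in [0, 1)")
  if (spec$n_essential > spec$n_proteins)
    stop("n_essential exceeds n_proteins")
  if (spec$n_date_hubs > spec$n_essential)
    stop("n_date_hubs exceeds n_essential")
  if (spec$module_size > max(1L, spec$n_essential - spec$n_date_hubs) &&
      spec$n_essential > spec$n_date_hubs)
    stop("module_size exceeds the number of module-dwelling essentials")
  if (spec$n_samples < 2L) stop("need at least 2 expression samples")
  n_module_proteins <- (spec$n_essential - spec$n_date_hubs) +
    spec$n_decoy_modules * spec$module_size
  if (n_module_proteins > spec$n_proteins)
    stop("modules require more proteins than n_proteins provides")
  class(spec) <- "synthetic_spec"
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic benchmark spec: ", x$n_proteins, " proteins (",
      x$n_essential, " essential, ", x$n_date_hubs, " date hubs), ",
      x$n_decoy_modules, " decoy module(s) of ", x$module_size, "\n", sep = "")
  cat("  p_within = ", x$p_within_module, ", p_background = ", x$p_background,
      ", rho_within = ", x$rho_within, ", orthology ", x$p_orthology, " +",
      x$orthology_enrichment, " on ", x$n_reference,
      " reference organisms, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic essential-protein benchmark dataset
#'
#' Deterministic for a fixed `spec$seed`: the generator seeds R's RNG
#' (Mersenne-Twister) at entry and restores the previous RNG state on exit.
#'
#' @param spec A `"synthetic_spec"` (see [synthetic_spec()]).
#' @return An object of class `"ogn_synthetic"`: list with `network`
#'   (igraph), `expression` (matrix, rows = proteins), `orthology`
#'   (`"orthology_table"`), `labels` (character vector of planted
#'   essentials), `modules` (named integer vector: module index per protein,
#'   0 = background, negative = decoy module), and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  ids <- sprintf("P%04d", seq_len(spec$n_proteins))
  n_mod_ess <- spec$n_essential - spec$n_date_hubs
  essential <- ids[seq_len(spec$n_essential)]
  date_hubs <- if (spec$n_date_hubs > 0L)
    essential[seq.int(n_mod_ess + 1L, spec$n_essential)] else character(0)

  # module assignment: essential modules get positive indices, decoys negative
  modules <- stats::setNames(integer(spec$n_proteins), ids)
  if (n_mod_ess > 0L)
    modules[seq_len(n_mod_ess)] <-
      as.integer(ceiling(seq_len(n_mod_ess) / spec$module_size))
  if (spec$n_decoy_modules > 0L) {
    decoy_ids <- seq.int(spec$n_essential + 1L,
                         spec$n_essential + spec$n_decoy_modules * spec$module_size)
    modules[decoy_ids] <-
      -as.integer(ceiling(seq_along(decoy_ids) / spec$module_size))
  }

  # edges: dense within modules, sparse elsewhere
  pairs <- utils::combn(spec$n_proteins, 2L)
  same_module <- modules[pairs[1L, ]] == modules[pairs[2L, ]] &
    modules[pairs[1L, ]] != 0L
  p_edge <- ifelse(same_module, spec$p_within_module, spec$p_background)
  keep <- stats::runif(ncol(pairs)) < p_edge
  el <- cbind(ids[pairs[1L, keep]], ids[pairs[2L, keep]])

  # date hubs: connect each to partners sampled across distinct modules
  if (spec$n_date_hubs > 0L) {
    module_list <- split(ids[modules != 0L], modules[modules != 0L])
    for (h in date_hubs) {
      partners <- unlist(lapply(module_list, function(m)
        m[sample.int(length(m), min(2L, length(m)))]), use.names = FALSE)
      el <- rbind(el, cbind(h, partners))
    }
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing) > 0L) g <- g + igraph::vertices(missing)
  g <- igraph::permute(g, match(igraph::V(g)$name, ids))

  # expression: one latent factor per module, loading sqrt(rho)
  expr <- matrix(stats::rnorm(spec$n_proteins * spec$n_samples),
                 nrow = spec$n_proteins,
                 dimnames = list(ids, sprintf("S%02d", seq_len(spec$n_samples))))
  lambda <- sqrt(spec$rho_within)
  mods <- setdiff(unique(modules), 0L)
  factors <- stats::setNames(
    lapply(mods, function(m) stats::rnorm(spec$n_samples)), mods)
  for (m in mods) {
    members <- names(modules)[modules == m]
    expr[members, ] <- lambda * matrix(factors[[as.character(m)]],
                                       nrow = length(members),
                                       ncol = spec$n_samples, byrow = TRUE) +
      sqrt(1 - spec$rho_within) *
      matrix(stats::rnorm(length(members) * spec$n_samples),
             nrow = length(members))
  }
  # date hubs load weakly on every module factor (staggered co-expression):
  # correlated a little with many partners instead of strongly with one module
  if (spec$n_date_hubs > 0L && length(mods) > 0L) {
    w <- lambda / sqrt(length(mods))
    for (h in date_hubs) {
      shared <- colSums(do.call(rbind, factors)) / sqrt(length(mods))
      expr[h, ] <- w * shared +
        sqrt(max(0, 1 - w^2)) * stats::rnorm(spec$n_samples)
    }
  }

  p_orth <- ifelse(ids %in% essential,
                   spec$p_orthology + spec$orthology_enrichment,
                   spec$p_orthology)
  counts <- stats::rbinom(spec$n_proteins, spec$n_reference, p_orth)
  counts <- pmin(pmax(counts, 0L), spec$n_reference)
  orth <- orthology_table(stats::setNames(as.integer(counts), ids),
                          spec$n_reference)

  structure(list(network = g, expression = expr, orthology = orth,
                 labels = essential, modules = modules, spec = spec),
            class = "ogn_synthetic")
}

#' @export
print.ogn_synthetic <- function(x, ...) {
  cat("Synthetic benchmark dataset: ", length(igraph::V(x$network)),
      " proteins, ", igraph::ecount(x$network), " interactions, ",
      length(x$labels), " essential (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset in the package's input formats
#'
#' Emits `network.tsv` (edge list), `expression.tsv`, `orthology.tsv` (with
#' the `#n_reference` directive), and `labels.txt` into `dir`; reading them
#' back with the `read_*` functions round-trips to an equal dataset.
#'
#' @param ds An `"ogn_synthetic"` dataset.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ogn_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             orthology = file.path(dir, "orthology.tsv"),
             labels = file.path(dir, "labels.txt"))
  write_network(ds$network, paths[["network"]])
  write_expression(ds$expression, paths[["expression"]])
  write_orthology(ds$orthology, paths[["orthology"]])
  write_labels(ds$labels, paths[["labels"]])
  invisible(paths)
}
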