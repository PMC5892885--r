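#' Read a protein-protein interaction network from an edge list
#'
#' Reads an undirected PPI network from either a plain two-column edge list or
#' a BioGRID TAB 2.0 export. Self-loops are dropped and duplicate edges are
#' collapsed; both events are counted and reported via [message()].
#'
#' Protein identifiers are compared verbatim (case-sensitive).
#'
#' @param path Path to the edge-list file.
#' @param dialect `"plain_tsv"` (default): two whitespace/tab-separated
#'   identifier columns per line, `#`-prefixed comment lines allowed.
#'   `"biogrid_tab"`: the BioGRID TAB 2.0 column layout; the two interactor
#'   systematic-name columns (6 and 7) are used. Rows whose systematic name is
#'   the `"-"` placeholder are skipped with a reported count.
#' @param physical_only For the BioGRID dialect, keep only rows whose
#'   Experimental System Type column equals `"physical"`. Default `FALSE`
#'   (both physical and genetic interactions are accepted).
#' @return An undirected, simple [igraph::igraph] graph whose vertices are
#'   named by protein identifier.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "A A", "B C"), f)
#' g <- read_network(f)
#' igraph::vcount(g) # 3
#' igraph::ecount(g) # 2
#' @export
read_network <- function(path, dialect = c("plain_tsv", "biogrid_tab"),
                         physical_only = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  isolated <- character(0)
  if (dialect == "plain_tsv") {
    # '#node <id>' directive lines declare vertices without interactions,
    # so networks with isolated proteins survive a write/read round trip;
    # other tools see them as plain comments
    node_directive <- grepl("^#node\\s+\\S+\\s*$", lines)
    isolated <- sub("^#node\\s+(\\S+)\\s*$", "\\1", lines[node_directive])
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 2L)) {
      bad <- idx[which(nf != 2L)[1L]]
      stop("malformed edge line ", bad, ": expected 2 columns, got ",
           nf[which(nf != 2L)[1L]])
    }
    ends <- do.call(rbind, fields)
  } else {
    keep <- !grepl("^\\s*(#|$)", lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 13L)) {
      bad <- which(keep)[which(nf < 13L)[1L]]
      stop("malformed BioGRID line ", bad,
           ": expected >= 13 tab-separated columns, got ", nf[which(nf < 13L)[1L]])
    }
    tab <- do.call(rbind, lapply(fields, function(f) f[c(6L, 7L, 13L)]))
    if (physical_only) {
      dropped <- sum(tab[, 3L] != "physical")
      if (dropped > 0L)
        message("read_network: dropped ", dropped, " non-physical interaction(s)")
      tab <- tab[tab[, 3L] == "physical", , drop = FALSE]
    }
    placeholder <- tab[, 1L] == "-" | tab[, 2L] == "-"
    if (any(placeholder))
      message("read_network: skipped ", sum(placeholder),
              " row(s) with '-' systematic names")
    ends <- tab[!placeholder, 1:2, drop = FALSE]
  }
  if (is.null(ends) || nrow(ends) == 0L)
    stop("empty network: no edges after filtering in ", path)
  self <- ends[, 1L] == ends[, 2L]
  n_self <- sum(self)
  ends <- ends[!self, , drop = FALSE]
  if (nrow(ends) == 0L) stop("empty network: no edges after filtering in ", path)
  key <- paste(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]), sep = "\r")
  n_dup <- sum(duplicated(key))
  ends <- ends[!duplicated(key), , drop = FALSE]
  if (n_self > 0L || n_dup > 0L)
    message("read_network: removed ", n_self, " self-loop(s) and ",
            n_dup, " duplicate edge(s)")
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  stopifnot(igraph::is_simple(g))
  extra <- setdiff(isolated, igraph::V(g)$name)
  if (length(extra) > 0L) g <- g + igraph::vertices(extra)
  g
}

#' Write a network as a plain two-column edge list
#'
#' Isolated vertices are recorded as `#node <id>` directive lines so that
#' [read_network()] can reconstruct the full vertex set; other tools treat
#' those lines as comments.
#'
#' @param net An undirected igraph network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  iso <- igraph::V(net)$name[igraph::degree(net) == 0L]
  writeLines(c(paste(el[, 1L], el[, 2L], sep = "\t"),
               if (length(iso) > 0L) paste("#node", iso)), path)
  invisible(path)
}

#' Read raw gene-expression records
#'
#' Reads a tab-separated expression table: a header row of sample names, then
#' one row per profile with the protein identifier in the first column and
#' numeric expression values in the remaining columns. Several rows may share
#' a protein identifier at this stage (e.g. multiple probes per gene);
#' [select_profile()] collapses them.
#'
#' @param path Path to the expression TSV.
#' @return A list with elements `ids` (character vector, one per row) and
#'   `values` (numeric matrix, rows in file order, columns named by sample).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) stop("expression file has no profiles: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  s <- length(samples)
  if (s < 2L) stop("expression file must have at least 2 samples (Pearson ",
                   "correlation is undefined otherwise), got ", s)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != s + 1L)) {
    bad <- which(nf != s + 1L)[1L]
    stop("ragged expression row ", bad + 1L, ": expected ", s + 1L,
         " columns, got ", nf[bad])
  }
  ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(s)))
  vals <- matrix(vals, ncol = s, byrow = TRUE,
                 dimnames = list(NULL, samples))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop("non-numeric expression value at row ", bad + 1L, " (protein ",
         ids[bad], ")")
  }
  list(ids = ids, values = vals)
}

#' Collapse duplicate expression profiles to one per protein
#'
#' When a protein has several expression profiles, the profile with the
#' maximal mean expression level across samples is kept. Ties are broken
#' deterministically in favour of the first occurrence in file order.
#'
#' @param records Raw records as returned by [read_expression()].
#' @return A numeric matrix with one row per protein (rownames = protein
#'   identifiers) and one column per sample.
#' @export
select_profile <- function(records) {
  stopifnot(is.list(records), length(records$ids) == nrow(records$values))
  if (length(records$ids) == 0L) stop("no expression records to select from")
  means <- rowMeans(records$values)
  # stable order: decreasing mean, original row order breaks ties
  ord <- order(-means, seq_along(means))
  first <- ord[!duplicated(records$ids[ord])]
  first <- sort(first)
  out <- records$values[first, , drop = FALSE]
  rownames(out) <- records$ids[first]
  out
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix, rownames = protein identifiers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  header <- paste(c("protein", colnames(expr)), collapse = "\t")
  rows <- paste(rownames(expr),
                apply(expr, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                                  collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an orthology table
#'
#' Reads a tab-separated table of per-protein ortholog counts: one row per
#' protein with columns `protein <TAB> count`, where `count` is the number of
#' reference organisms containing an ortholog of the protein. The total number
#' of reference organisms is given either by a `#n_reference=<int>` directive
#' line in the file or by the `n_reference` argument (the argument wins).
#'
#' @param path Path to the orthology TSV.
#' @param n_reference Total number of reference organisms; overrides the file
#'   directive when supplied.
#' @return An object of class `"orthology_table"`: a list with `counts`
#'   (named integer vector) and `n_reference`.
#' @export
read_orthology <- function(path, n_reference = NULL) {
  if (!file.exists(path)) stop("orthology file not found: ", path)
  lines <- readLines(path)
  directive <- grep("^#\\s*n_reference\\s*=", lines, value = TRUE)
  if (is.null(n_reference)) {
    if (length(directive) == 0L)
      stop("n_reference not given: supply the argument or a ",
           "'#n_reference=<int>' directive line")
    n_reference <- as.integer(sub("^#\\s*n_reference\\s*=\\s*", "", directive[1L]))
  }
  if (is.na(n_reference) || n_reference < 1L)
    stop("n_reference must be a positive integer")
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (length(body) > 0L && any(nf != 2L))
    stop("malformed orthology line: expected 2 columns, got ", nf[nf != 2L][1L])
  ids <- vapply(fields, `[[`, character(1L), 1L)
  counts <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  if (anyNA(counts)) stop("non-integer ortholog count for protein ",
                          ids[which(is.na(counts))[1L]])
  if (any(counts < 0L)) stop("negative ortholog count for protein ",
                             ids[which(counts < 0L)[1L]])
  if (any(counts > n_reference))
    stop("ortholog count exceeds n_reference (", n_reference, ") for protein ",
         ids[which(counts > n_reference)[1L]])
  orthology_table(stats::setNames(counts, ids), n_reference)
}

#' Construct an orthology table
#' @param counts Named non-negative integer vector: per-protein number of
#'   reference organisms with an ortholog.
#' @param n_reference Total number of reference organisms.
#' @return An object of class `"orthology_table"`.
#' @export
orthology_table <- function(counts, n_reference) {
  stopifnot(n_reference >= 1, all(counts >= 0), all(counts <= n_reference),
            !is.null(names(counts)) || length(counts) == 0L)
  structure(list(counts = counts, n_reference = as.integer(n_reference)),
            class = "orthology_table")
}

#' @export
print.orthology_table <- function(x, ...) {
  cat("Orthology table:", length(x$counts), "protein(s),",
      x$n_reference, "reference organisms\n")
  invisible(x)
}

#' Write an orthology table as TSV with an n_reference directive
#' @param orth An `"orthology_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orthology <- function(orth, path) {
  writeLines(c(paste0("#n_reference=", orth$n_reference),
               paste(names(orth$counts), orth$counts, sep = "\t")), path)
  invisible(path)
}

#' Read essentiality labels
#'
#' One protein identifier per line; `#` comments and blank lines ignored.
#' Labelled proteins need not all appear in the analysis universe.
#'
#' @param path Path to the label file.
#' @return Character vector of essential-protein identifiers (unique).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  ids <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  unique(ids)
}

#' Write essentiality labels, one identifier per line
#' @param labels Character vector of essential-protein identifiers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Build the analysis universe shared by network and expression data
#'
#' The analysis universe is the set of proteins present in both the
#' interaction network and the expression matrix, sorted lexicographically.
#' The network is induced on that set (edges with an endpoint outside it are
#' dropped) and the expression matrix restricted likewise. Proteins without an
#' orthology entry keep an ortholog count of zero rather than being dropped,
#' so conservation evidence can only add to — never shrink — the universe.
#'
#' @param net Undirected igraph network (vertices named by protein).
#' @param expr Numeric expression matrix, one row per protein
#'   (see [select_profile()]).
#' @param orth An `"orthology_table"`, or `NULL` for no conservation data
#'   (all counts zero).
#' @param n_reference Required when `orth` is `NULL`.
#' @return An object of class `"ogn_universe"`: list with `proteins` (sorted
#'   identifiers), `graph` (induced igraph), `expression` (restricted matrix,
#'   rows ordered as `proteins`), `orth_counts` (integer vector aligned to
#'   `proteins`), `n_reference`, and `dropped` (counts of discarded nodes and
#'   edges).
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' expr <- matrix(rnorm(6), 3, 2, dimnames = list(c("B", "C", "D"), NULL))
#' u <- build_universe(g, expr, orthology_table(c(B = 3L), 10))
#' u$proteins # "B" "C"
#' @export
build_universe <- function(net, expr, orth = NULL, n_reference = NULL) {
  stopifnot(igraph::is_igraph(net), is.matrix(expr), !is.null(rownames(expr)))
  if (is.null(orth)) {
    if (is.null(n_reference)) stop("n_reference required when orth is NULL")
    orth <- orthology_table(stats::setNames(integer(0), character(0)), n_reference)
  }
  stopifnot(inherits(orth, "orthology_table"))
  net_nodes <- igraph::V(net)$name
  common <- sort(intersect(net_nodes, rownames(expr)))
  if (length(common) == 0L)
    stop("empty universe: network and expression data share no proteins")
  sub <- igraph::induced_subgraph(net, common)
  # igraph may permute vertices; re-order canonically
  sub <- igraph::permute(sub, match(igraph::V(sub)$name, common))
  dropped_nodes <- length(net_nodes) - length(common)
  dropped_edges <- igraph::ecount(net) - igraph::ecount(sub)
  if (dropped_nodes > 0L || dropped_edges > 0L)
    message("build_universe: dropped ", dropped_nodes, " node(s) and ",
            dropped_edges, " edge(s) outside the shared universe")
  counts <- stats::setNames(integer(length(common)), common)
  hit <- intersect(names(orth$counts), common)
  counts[hit] <- orth$counts[hit]
  structure(list(
    proteins    = common,
    graph       = sub,
    expression  = expr[common, , drop = FALSE],
    orth_counts = counts,
    n_reference = orth$n_reference,
    dropped     = c(nodes = dropped_nodes, edges = dropped_edges)
  ), class = "ogn_universe")
}

#' @export
print.ogn_universe <- function(x, ...) {
  cat("Analysis universe: ", length(x$proteins), " proteins, ",
      igraph::ecount(x$graph), " interactions, ",
      ncol(x$expression), " expression samples, n_reference = ",
      x$n_reference, "\n", sep = "")
  invisible(x)
}

#' Write a ranked score table as TSV
#'
#' Output columns: protein, score, rank (1 = best). The rank column freezes
#' the package's tie rule (descending score, ascending identifier) so
#' downstream consumers never re-sort with a different one.
#'
#' @param scores Named numeric score vector.
#' @param path Output file path.
#' @param score_name Column label for the score.
#' @return `path`, invisibly.
#' @export
write_ranked_scores <- function(scores, path, score_name = "score") {
  ord <- rank_scores(scores)
  df <- data.frame(protein = ord,
                   score = unname(scores[ord]),
                   rank = seq_along(ord))
  names(df)[2L] <- score_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
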