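# Independent brute-force oracles used to cross-check the package's
# implementations. They work from the raw adjacency matrix only and share no
# algorithmic code with the functions they check.

adjacency_of <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
}

# all-pairs shortest-path distances by breadth-first matrix powering
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  p <- diag(1, n)
  for (k in seq_len(max(n - 1L, 1L))) {
    p <- p %*% a
    newly <- (p > 0) & !is.finite(d)
    if (!any(newly)) break
    d[newly] <- k
  }
  d
}

# number of shortest paths between every pair, by dynamic programming on
# distance layers
oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  s <- diag(1, n)
  finite <- d[is.finite(d)]
  if (max(finite) < 1) return(s)
  for (k in seq_len(max(finite))) {
    for (src in seq_len(n)) {
      for (dst in which(d[src, ] == k)) {
        pred <- which(a[, dst] > 0 & d[src, ] == k - 1)
        s[src, dst] <- sum(s[src, pred])
      }
    }
  }
  s
}

# betweenness with each unordered pair counted once
oracle_betweenness <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  d <- oracle_distances(a)
  sig <- oracle_path_counts(a, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
          bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
  }
  stats::setNames(bc, rownames(a))
}

# component-local closeness: (n_c - 1) / sum of within-component distances
oracle_closeness <- function(net) {
  a <- adjacency_of(net)
  d <- oracle_distances(a)
  cc <- apply(d, 1L, function(row) {
    comp <- is.finite(row)
    if (sum(comp) <= 1L) return(0)
    (sum(comp) - 1L) / sum(row[comp])
  })
  stats::setNames(cc, rownames(a))
}

# principal eigenvector via dense symmetric eigendecomposition
oracle_eigenvector <- function(net) {
  a <- adjacency_of(net)
  es <- eigen(a, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  v <- abs(v) / sqrt(sum(v^2))
  stats::setNames(v, rownames(a))
}

# subgraph centrality by truncated power series sum_k diag(A^k) / k!
oracle_subgraph <- function(net, k_max = 40L) {
  a <- adjacency_of(net)
  n <- nrow(a)
  acc <- diag(1, n)
  pw <- diag(1, n)
  for (k in seq_len(k_max)) {
    pw <- pw %*% a
    acc <- acc + pw / factorial(k)
  }
  stats::setNames(diag(acc), rownames(a))
}

# clustering coefficient by explicit neighbour-pair enumeration
oracle_clustering <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  co <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k <= 1L) next
    links <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (a[nb[i], nb[j]] > 0) links <- links + 1L
      }
    }
    co[v] <- 2 * links / (k * (k - 1))
  }
  stats::setNames(co, rownames(a))
}

# textbook covariance / (sd * sd) Pearson correlation
oracle_pcc <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# seeded Erdos-Renyi graph with named vertices
random_graph <- function(n, p, seed, connected = FALSE) {
  set.seed(seed)
  repeat {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    dimnames(a) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (!connected || igraph::is_connected(g)) return(g)
  }
}

# five-node worked fixture: network, expression, orthology with values the
# per-protein scores were derived from by hand (see test-ogn.R)
fixture_five_node <- function() {
  g <- igraph::make_graph(~ A - B, A - C, B - C, C - D, D - E)
  expr <- rbind(A = c(1, 2, 3, 4),
                B = c(2, 4, 6, 8),
                C = c(4, 3, 2, 1),
                D = c(1, 3, 2, 4),
                E = c(5, 5, 5, 5))
  colnames(expr) <- paste0("S", 1:4)
  orth <- orthology_table(c(A = 10L, B = 5L, D = 2L), 10L)
  suppressMessages(build_universe(g, expr, orth))
}

# small universe built from a synthetic dataset, messages silenced
build_synthetic_universe <- function(...) {
  ds <- generate_dataset(synthetic_spec(...))
  list(ds = ds,
       u = suppressMessages(build_universe(ds$network, ds$expression,
                                           ds$orthology)))
}
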